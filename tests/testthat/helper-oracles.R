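# Independent oracles and fixture builders. Everything here is written
# deliberately naively (loops, per-record if/else) and shares no code with
# the package implementation it cross-checks.

# type-7 quantile by direct order-statistic interpolation
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# per-record re-derivation of every cascade stage count
oracle_cascade <- function(calls) {
  n_included <- 0L; n_recognizable <- 0L
  n_recognized_overall <- 0L; n_recognized <- 0L; n_available <- 0L
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if (isTRUE(r$alive_during_call)) next
    if (!isTRUE(r$audio_available)) next
    n_included <- n_included + 1L
    if (isTRUE(r$recognized)) n_recognized_overall <- n_recognized_overall + 1L
    if (isTRUE(r$cpr_in_progress)) next
    if (r$recognizability_barrier != "NONE") next
    n_recognizable <- n_recognizable + 1L
    if (!isTRUE(r$recognized)) next
    n_recognized <- n_recognized + 1L
    if (r$dacpr_barrier == "NONE") n_available <- n_available + 1L
  }
  list(n_included = n_included, n_recognizable = n_recognizable,
       n_recognized_overall = n_recognized_overall,
       n_recognized = n_recognized, n_available = n_available)
}

# loop recount of a logical column
oracle_count_true <- function(x) {
  k <- 0
  for (v in x) if (isTRUE(v)) k <- k + 1
  k
}

# loop recount of times strictly below a threshold
oracle_count_below <- function(x, threshold) {
  k <- 0
  for (v in x) if (!is.na(v) && v < threshold) k <- k + 1
  k
}

# negative Bernoulli log-likelihood of a logistic model on a fixed design,
# for brute-force optimizer cross-checks
oracle_neg_loglik <- function(X, y) {
  function(beta) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
}

# minimal valid call table with overridable columns
call_tbl <- function(n = 1, ...) {
  base <- tibble::tibble(
    call_id = sprintf("T%04d", seq_len(n)),
    t_recognition_s = NA_real_,
    t_dispatch_s = NA_real_,
    t_cpr_instruction_s = NA_real_,
    t_first_compression_s = NA_real_,
    t_first_dacpr_compression_s = NA_real_,
    recognized = FALSE,
    alive_during_call = FALSE,
    audio_available = TRUE,
    cpr_in_progress = FALSE,
    recognizability_barrier = "NONE",
    dacpr_barrier = "NONE",
    any_compression_during_call = NA,
    dacpr_compressions_given = FALSE,
    survived_30d = NA,
    patient_age = NA_real_,
    patient_sex = NA_character_,
    caller_sex = NA_character_,
    caller_alone = NA,
    caller_hcp = NA,
    caller_knows_victim = NA,
    location = NA_character_,
    witnessed = NA,
    cause = NA_character_,
    shockable_rhythm = NA,
    aed_addressed = NA,
    call_continued_until_ems = NA
  )
  over <- list(...)
  for (col in names(over)) base[[col]] <- over[[col]]
  base
}

# stage cohorts assembled from the exported classifiers only
stage_cohorts_for_tests <- function(calls) {
  included <- apply_study_exclusions(calls)$included
  marked <- classify_recognizable(included)
  recognizable <- marked[marked$recognizable, ]
  recognized <- recognizable[!is.na(recognizable$recognized) &
                               recognizable$recognized, ]
  available <- classify_dacpr_available(recognized)
  list(included = included, recognizable = recognizable,
       recognized = recognized,
       dacpr_available = available[available$dacpr_available, ])
}
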