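# Seeded generator of synthetic OHCA call cohorts with the statistical
# structure of a national dispatch audit: stage and barrier frequencies,
# log-normal event times matched to published median/IQR triples, Table-1
# style covariate marginals, survival that decays with time to first
# compression, and explicit missingness.
#
# Event-chain times (recognition -> CPR instructions -> first DA-CPR
# compression, and first compression by anyone) are coupled through one
# shared log-normal latent per call (comonotone quantile coupling): a call
# that is slow at one step is slow at every step. This preserves each
# marginal distribution exactly while keeping the chain ordered; the rare
# tail crossings that remain (the distributions' spreads differ) are
# clamped to the preceding event plus one second, which touches only the
# far upper tail and leaves medians and quartiles intact.

#' Default generator parameters
#'
#' All frequencies, time models and missingness rates default to the
#' structure of a 1000-call national audit sample: 3.5% of calls with the
#' patient alive during the call and 2.9% with no voice log; recognizability
#' barriers at the audit frequencies (CPR already in progress 97/936,
#' third-party caller 23/936, ...); recognition probability 645/760 for
#' recognizable calls; DA-CPR barriers at 49/13/5/5/13 per 645; directed
#' compressions for 343/560 available calls; log-normal event times matched
#' by quartiles to the audit's median \[IQR\] triples (recognition 113
#' \[62, 204\] s, dispatch 88 \[64, 131\] s, instructions 201 \[137, 300\] s,
#' DA-CPR compression 240 \[176, 332\] s, any compression 214 \[146, 315\] s);
#' and a logistic survival model on time to first compression calibrated to
#' an overall 30-day survival of 66/936.
#'
#' @return A nested list of parameters accepted by [generate_cohort()].
#' @export
cohort_params <- function() {
  list(
    stage = list(
      p_alive_during_call = 35 / 1000,
      p_missing_audio = 29 / 1000,
      # categorical over recognizability status, frequencies per 936
      recognizability = c(
        CPR_IN_PROGRESS = 97, THIRD_PARTY = 23, HYSTERICAL = 10,
        HANG_UP = 9, LANGUAGE = 4, OTHER = 33, NONE = 760
      ) / 936,
      p_recognized_recognizable = 645 / 760,
      p_recognized_cpr_in_progress = 1,
      p_recognized_other_barrier = 0,
      # categorical over DA-CPR barriers among recognized recognizable calls
      dacpr = c(
        CANNOT_MOVE = 49, REFUSES = 13, HANG_UP = 5,
        NOT_WITH_PATIENT = 5, OTHER = 13, NONE = 560
      ) / 645,
      p_dacpr_given = 343 / 560,
      p_spontaneous_compression = 161 / 217
    ),
    time_models = list(
      recognition      = c(median = 113, q1 = 62, q3 = 204),
      dispatch         = c(median = 88, q1 = 64, q3 = 131),
      instruction      = c(median = 201, q1 = 137, q3 = 300),
      dacpr_compression = c(median = 240, q1 = 176, q3 = 332),
      any_compression  = c(median = 214, q1 = 146, q3 = 315)
    ),
    survival = list(
      slope_per_s = -0.004,
      target_overall = 66 / 936,
      no_compression_delay_s = 600
    ),
    covariates = list(
      p_patient_female = 0.34,
      p_caller_female = 0.59,
      p_caller_alone = 0.37,
      p_caller_hcp = 0.28,
      p_knows_victim = 780 / 901,
      location = c(RESIDENTIAL = 677, PUBLIC = 176, OTHER = 79) / 932,
      p_witnessed = 531 / 907,
      cause = c(
        CARDIAC = 512, OVERDOSE = 21, TRAUMA = 19, RESPIRATORY = 46,
        ASPHYXIA = 28, SUICIDE = 38, SUBMERSION = 19, SIDS = 7, OTHER = 189
      ) / 879,
      p_shockable = 170 / 924,
      p_aed_addressed = 68 / 854,
      p_call_continued = 488 / 835,
      age = c(median = 72, q1 = 61, q3 = 81)
    ),
    missingness = list(
      survival = 47 / 936,
      recognition_time = 117 / 645,
      dispatch_time = 1 / 936,
      compression_time = 136 / 504,
      dacpr_time = 40 / 343,
      instruction_time = 7 / 343,
      patient_sex = 7 / 936, caller_sex = 30 / 936,
      caller_alone = 45 / 936, caller_hcp = 34 / 936,
      knows_victim = 35 / 936, location = 4 / 936,
      witnessed = 29 / 936, cause = 57 / 936,
      shockable = 12 / 936, aed = 82 / 936,
      call_continued = 101 / 936
    )
  )
}

#' Calibrate a log-normal distribution to a median/quartile triple
#'
#' `mu = log(median)`; `sigma` is the mean of the two one-sided estimates
#' `log(q3/median)/z` and `log(median/q1)/z` with `z` the standard-normal
#' 0.75 quantile — exact when the triple is log-symmetric, a compromise
#' otherwise.
#'
#' @param median,q1,q3 Target median and quartiles, `0 < q1 < median < q3`.
#' @return Named numeric vector `c(mu, sigma)` (log scale).
#' @examples
#' calibrate_lognormal(113, 62, 204)
#' @export
calibrate_lognormal <- function(median, q1, q3) {
  if (!(0 < q1 && q1 < median && median < q3)) {
    abort("need 0 < q1 < median < q3")
  }
  z <- qnorm(0.75)
  sigma <- mean(c(log(q3 / median), log(median / q1))) / z
  c(mu = log(median), sigma = sigma)
}

q_time <- function(u, triple) {
  par <- calibrate_lognormal(triple[["median"]], triple[["q1"]],
                             triple[["q3"]])
  qlnorm(u, par[["mu"]], par[["sigma"]])
}

sample_categorical <- function(n, probs) {
  if (abs(sum(probs) - 1) > 1e-8) abort("category probabilities must sum to 1")
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

mask_missing <- function(x, where, rate) {
  x[where & runif(length(x)) < rate] <- NA
  x
}

check_probs <- function(p) {
  bad <- unlist(p)[unlist(p) < 0 | unlist(p) > 1]
  if (length(bad) > 0) abort("all probabilities must lie in [0, 1]")
}

#' Generate a synthetic OHCA call cohort
#'
#' Samples `n` calls per the generative order: study-exclusion flags, then
#' recognizability status and barriers, recognition, DA-CPR barriers and
#' delivery, event times (log-normal, only where the event occurs, coupled
#' through a shared latent so the chain is ordered), 30-day survival
#' (Bernoulli with log-odds linear in time to first compression; calls with
#' no compression use a fixed late effective delay), covariates, and
#' finally the missingness masks. Deterministic for a fixed seed.
#'
#' @param n Cohort size.
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @param params Parameter list as from [cohort_params()].
#' @return A call tibble of `n` rows (see [call_columns()]), valid under
#'   [validate_calls()].
#' @examples
#' cohort <- generate_cohort(500, seed = 7)
#' build_cascade_report(cohort)$n_included
#' @export
generate_cohort <- function(n, seed = NULL, params = cohort_params()) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  check_probs(params$stage[c("p_alive_during_call", "p_missing_audio",
                             "p_recognized_recognizable", "p_dacpr_given",
                             "p_spontaneous_compression")])
  check_probs(params$stage$recognizability)
  check_probs(params$stage$dacpr)
  if (n == 0) return(empty_call_table())

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  st <- params$stage
  tm <- params$time_models
  cv <- params$covariates
  ms <- params$missingness

  alive <- runif(n) < st$p_alive_during_call
  audio_available <- runif(n) >= st$p_missing_audio

  status <- sample_categorical(n, st$recognizability)
  cpr_in_progress <- status == "CPR_IN_PROGRESS"
  barrier <- ifelse(status %in% c("CPR_IN_PROGRESS", "NONE"), "NONE", status)
  recognizable <- status == "NONE"

  p_rec <- ifelse(recognizable, st$p_recognized_recognizable,
                  ifelse(cpr_in_progress, st$p_recognized_cpr_in_progress,
                         st$p_recognized_other_barrier))
  recognized <- runif(n) < p_rec

  dacpr_barrier <- rep("NONE", n)
  pool <- recognized & recognizable
  dacpr_barrier[pool] <- sample_categorical(sum(pool), st$dacpr)
  available <- pool & dacpr_barrier == "NONE"

  dacpr_given <- available & runif(n) < st$p_dacpr_given
  spontaneous <- available & !dacpr_given &
    runif(n) < st$p_spontaneous_compression
  any_compression <- dacpr_given | spontaneous | cpr_in_progress

  # event-chain latent: one severity quantile per call
  u <- runif(n)
  t_recognition <- ifelse(recognized, q_time(u, tm$recognition), NA_real_)
  t_dispatch <- q_time(runif(n), tm$dispatch)
  t_instruction <- ifelse(dacpr_given, q_time(u, tm$instruction), NA_real_)
  t_instruction <- pmax(t_instruction, t_recognition + 1, na.rm = FALSE)
  t_dacpr <- ifelse(dacpr_given, q_time(u, tm$dacpr_compression), NA_real_)
  t_dacpr <- pmax(t_dacpr, t_instruction + 1)
  t_first <- rep(NA_real_, n)
  t_first[dacpr_given] <- pmin(q_time(u[dacpr_given], tm$any_compression),
                               t_dacpr[dacpr_given])
  t_first[spontaneous] <- q_time(u[spontaneous], tm$any_compression)
  t_first[cpr_in_progress] <- 30 * u[cpr_in_progress]

  # survival: logistic in effective delay, intercept calibrated so the
  # included cohort hits the target overall survival
  sv <- params$survival
  delay <- ifelse(any_compression & !is.na(t_first), t_first,
                  sv$no_compression_delay_s)
  included <- !alive & audio_available
  calib <- if (any(included)) delay[included] else delay
  intercept <- uniroot(
    function(a) mean(plogis(a + sv$slope_per_s * calib)) - sv$target_overall,
    interval = c(-20, 10), tol = 1e-10
  )$root
  survived <- runif(n) < plogis(intercept + sv$slope_per_s * delay)

  age_sd <- (cv$age[["q3"]] - cv$age[["q1"]]) / (2 * qnorm(0.75))
  age <- round(pmin(pmax(rnorm(n, cv$age[["median"]], age_sd), 1), 105))
  draw <- function(p) runif(n) < p
  patient_sex <- ifelse(draw(cv$p_patient_female), "FEMALE", "MALE")
  caller_sex <- ifelse(draw(cv$p_caller_female), "FEMALE", "MALE")

  calls <- tibble::tibble(
    call_id = sprintf("S%06d", seq_len(n)),
    t_recognition_s = mask_missing(t_recognition, recognized,
                                   ms$recognition_time),
    t_dispatch_s = mask_missing(t_dispatch, TRUE, ms$dispatch_time),
    t_cpr_instruction_s = mask_missing(t_instruction, dacpr_given,
                                       ms$instruction_time),
    t_first_compression_s = mask_missing(t_first, any_compression,
                                         ms$compression_time),
    t_first_dacpr_compression_s = mask_missing(t_dacpr, dacpr_given,
                                               ms$dacpr_time),
    recognized = recognized,
    alive_during_call = alive,
    audio_available = audio_available,
    cpr_in_progress = cpr_in_progress,
    recognizability_barrier = barrier,
    dacpr_barrier = dacpr_barrier,
    any_compression_during_call = any_compression,
    dacpr_compressions_given = dacpr_given,
    survived_30d = mask_missing(survived, TRUE, ms$survival),
    patient_age = age,
    patient_sex = mask_missing(patient_sex, TRUE, ms$patient_sex),
    caller_sex = mask_missing(caller_sex, TRUE, ms$caller_sex),
    caller_alone = mask_missing(draw(cv$p_caller_alone), TRUE,
                                ms$caller_alone),
    caller_hcp = mask_missing(draw(cv$p_caller_hcp), TRUE, ms$caller_hcp),
    caller_knows_victim = mask_missing(draw(cv$p_knows_victim), TRUE,
                                       ms$knows_victim),
    location = mask_missing(sample_categorical(n, cv$location), TRUE,
                            ms$location),
    witnessed = mask_missing(draw(cv$p_witnessed), TRUE, ms$witnessed),
    cause = mask_missing(sample_categorical(n, cv$cause), TRUE, ms$cause),
    shockable_rhythm = mask_missing(draw(cv$p_shockable), TRUE,
                                    ms$shockable),
    aed_addressed = mask_missing(draw(cv$p_aed_addressed), TRUE, ms$aed),
    call_continued_until_ems = mask_missing(draw(cv$p_call_continued), TRUE,
                                            ms$call_continued)
  )
  calls[call_columns()]
}
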