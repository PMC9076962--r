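# Counterfactual additional-survivors estimator: stratify a cohort by a
# delay target, difference the 30-day survival rates between the
# target-meeting and target-missing strata, multiply by the number of
# target-missing patients, and floor to a whole number of lives.

#' Survival rates stratified by a time target
#'
#' Splits a stage cohort at a delay threshold: the target-meeting stratum
#' has the time recorded and strictly below the threshold; every other call
#' (time at/above threshold, or time missing — a call with no recorded
#' event cannot have met the target) is target-missing. Survival
#' proportions are computed over calls with known 30-day outcome, while
#' `n_not_met` counts the whole target-missing stratum including calls with
#' unknown outcome, because the multiplier counts patients.
#'
#' @param calls Stage cohort appropriate to the delay (recognizable cohort
#'   for recognition time, included cohort for dispatch time,
#'   DA-CPR-available cohort for compression time).
#' @param time_col Name of the delay column (string).
#' @param threshold_s Target threshold in seconds.
#' @return A one-row tibble: `time_field`, `threshold_s`, `p_met`,
#'   `p_not_met`, `n_met`, `n_not_met`, `n_met_known`, `n_not_met_known`.
#' @seealso [estimate_additional_lives()]
#' @export
survival_rates_by_target <- function(calls, time_col, threshold_s) {
  check_columns(calls, c(time_col, "survived_30d"), "call table")
  stopifnot(is.numeric(threshold_s), length(threshold_s) == 1, threshold_s > 0)
  t <- calls[[time_col]]
  met <- !is.na(t) & t < threshold_s
  surv <- calls$survived_30d

  rate <- function(stratum, label) {
    known <- stratum & !is.na(surv)
    if (sum(known) == 0) {
      abort(sprintf(
        "no calls with known 30-day outcome in the %s stratum of %s < %g s",
        label, time_col, threshold_s
      ))
    }
    sum(surv[known]) / sum(known)
  }

  tibble::tibble(
    time_field = time_col,
    threshold_s = threshold_s,
    p_met = rate(met, "target-meeting"),
    p_not_met = rate(!met, "target-missing"),
    n_met = sum(met),
    n_not_met = sum(!met),
    n_met_known = sum(met & !is.na(surv)),
    n_not_met_known = sum(!met & !is.na(surv))
  )
}

#' Bundle explicit stratum rates as estimator input
#'
#' Convenience constructor for running the estimator from published stratum
#' survival rates rather than from a cohort.
#'
#' @param p_met,p_not_met Survival proportions (fractions in \[0, 1\]) of the
#'   target-meeting and target-missing strata.
#' @param n_not_met Number of target-missing patients.
#' @return A tibble suitable for [estimate_additional_lives()].
#' @export
lives_saved_input <- function(p_met, p_not_met, n_not_met) {
  tibble::tibble(p_met = p_met, p_not_met = p_not_met,
                 n_not_met = n_not_met)
}

#' Estimate additional 30-day survivors
#'
#' The estimator: `raw = (p_met - p_not_met) * n_not_met`, the expected
#' number of extra survivors if every target-missing patient had instead
#' experienced the target-meeting stratum's survival rate. The headline
#' integer is `floor(raw)` (truncation, not rounding); a negative `raw` is
#' reported as 0 additional lives with a `negative_effect` flag, since
#' "additional lives" is non-negative by construction.
#'
#' @param input A data frame with columns `p_met`, `p_not_met`, `n_not_met`
#'   (one row per target), e.g. from [survival_rates_by_target()] or
#'   [lives_saved_input()].
#' @return `input` with `raw`, `additional_lives` (integer) and
#'   `negative_effect` (logical) added.
#' @examples
#' estimate_additional_lives(lives_saved_input(0.1052, 0.07056, 727))
#' @export
estimate_additional_lives <- function(input) {
  check_columns(input, c("p_met", "p_not_met", "n_not_met"),
                "lives-saved input")
  with(input, {
    if (any(p_met < 0 | p_met > 1 | p_not_met < 0 | p_not_met > 1,
            na.rm = TRUE)) {
      abort("survival proportions must lie in [0, 1]")
    }
    if (any(n_not_met < 0, na.rm = TRUE)) {
      abort("n_not_met must be nonnegative")
    }
  })
  dplyr::mutate(tibble::as_tibble(input),
    raw = (.data$p_met - .data$p_not_met) * .data$n_not_met,
    additional_lives = as.integer(floor(pmax(.data$raw, 0))),
    negative_effect = .data$raw < 0
  )
}

#' Extrapolate additional lives to a national case load
#'
#' Scales a sample-level additional-survivors count to a national annual
#' OHCA count, assuming similar patient characteristics. Returned unrounded
#' and to be read as an approximation — the sample estimate itself carries
#' no confidence interval.
#'
#' @param additional_lives Additional survivors estimated in the sample.
#' @param sample_n Size of the audited sample the estimate refers to.
#' @param national_n National annual OHCA count.
#' @return `additional_lives * national_n / sample_n`, unrounded.
#' @examples
#' extrapolate_national(25, 1000, 6135)
#' @export
extrapolate_national <- function(additional_lives, sample_n, national_n) {
  stopifnot(is.numeric(additional_lives), is.numeric(sample_n),
            is.numeric(national_n))
  if (any(sample_n <= 0)) abort("sample_n must be positive")
  additional_lives * national_n / sample_n
}
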