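# The five AHA DA-CPR performance measures: three recognition/delivery
# proportions (goals 1-3) and two median-time measures with threshold
# attainment (goals 4-5), each compared against its benchmark.
#
# Conventions (surfaced because the source tables' arithmetic depends on
# them): quartiles are type-7 (linear interpolation of order statistics);
# threshold attainment uses strict "<"; attainment percentages use the full
# stage cohort as denominator, including calls whose time is missing;
# reported percentages are rounded half away from zero to whole percent,
# with raw values retained.

#' AHA benchmark thresholds for the five DA-CPR performance goals
#'
#' Defaults: goal 1 (OHCA recognized, all included calls) 75%; goal 2
#' (recognized among recognizable) 95%; goal 3 (recognized OHCA receiving
#' DA-CPR) 75%; goal 4 (time to recognition / EMS dispatch) < 60 s
#' high-performance, < 90 s minimal acceptable; goal 5 (time to first
#' DA-CPR-directed compression) < 90 s high-performance, < 150 s minimal.
#'
#' @return A tibble with columns `goal_id`, `kind`, `target_pct`,
#'   `high_perf_s`, `minimal_std_s`.
#' @seealso [benchmarks_from_yaml()] to override from a config file.
#' @export
aha_benchmarks <- function() {
  tibble::tibble(
    goal_id = 1:5,
    kind = c("PROPORTION", "PROPORTION", "PROPORTION", "TIME", "TIME"),
    target_pct = c(75, 95, 75, NA, NA),
    high_perf_s = c(NA, NA, NA, 60, 90),
    minimal_std_s = c(NA, NA, NA, 90, 150)
  )
}

#' Read benchmark overrides from a YAML config
#'
#' The file is keyed `goal1` .. `goal5`; each entry may set `target_pct`
#' (goals 1-3) or `high_perf_s` / `minimal_std_s` (goals 4-5). Unset fields
#' keep the AHA defaults.
#'
#' @param path YAML file path.
#' @return A benchmark tibble as from [aha_benchmarks()].
#' @export
benchmarks_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  bm <- aha_benchmarks()
  for (i in seq_len(nrow(bm))) {
    entry <- cfg[[paste0("goal", bm$goal_id[i])]]
    if (is.null(entry)) next
    for (field in c("target_pct", "high_perf_s", "minimal_std_s")) {
      if (!is.null(entry[[field]])) bm[[field]][i] <- as.numeric(entry[[field]])
    }
  }
  bad <- !is.na(bm$high_perf_s) & !is.na(bm$minimal_std_s) &
    bm$high_perf_s >= bm$minimal_std_s
  if (any(bad)) {
    abort("high_perf_s must be below minimal_std_s for every time goal")
  }
  bm
}

#' Median and interquartile range
#'
#' Median by the midpoint convention for even n; first and third quartiles
#' by linear interpolation of order statistics (quantile type 7).
#'
#' @param values Numeric vector of seconds; must be non-empty and finite.
#' @return A one-row tibble with `median_s`, `q1_s`, `q3_s`, `n`.
#' @examples
#' median_iqr(c(1, 2, 3, 4))
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) abort("median_iqr() needs at least one value")
  if (anyNA(values) || any(!is.finite(values))) {
    abort("median_iqr() requires finite, non-missing values")
  }
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(median_s = q[2], q1_s = q[1], q3_s = q[3],
                 n = length(values))
}

# shared constructor for the proportion goals
goal_result <- function(goal_id, measure, numerator, denominator, target_pct) {
  raw <- pct_of(numerator, denominator)
  tibble::tibble(
    goal_id = as.integer(goal_id),
    measure = measure,
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    pct = raw,
    pct_rounded = ifelse(is.na(raw), NA_integer_,
                         as.integer(round_half_up(raw))),
    target_pct = target_pct,
    met = !is.na(raw) & !is.na(target_pct) & raw >= target_pct,
    undefined = denominator == 0
  )
}

#' Goal 1: OHCA recognition in the included cohort
#'
#' Proportion of all included calls in which the dispatcher recognized the
#' OHCA, against the 75% benchmark.
#'
#' @param calls The included cohort (study-level exclusions applied).
#' @param target_pct Benchmark percentage; default 75.
#' @return A one-row goal-result tibble (`numerator`, `denominator`, `pct`,
#'   `pct_rounded`, `met`, `undefined`).
#' @export
goal1_recognition <- function(calls, target_pct = 75) {
  check_columns(calls, "recognized", "call table")
  goal_result(1, "recognized", sum(isTRUE_v(calls$recognized)), nrow(calls),
              target_pct)
}

#' Goal 2: recognition among recognizable OHCA
#'
#' Proportion of recognizable calls (AHA barriers excluded) that the
#' dispatcher recognized, against the 95% benchmark.
#'
#' @param calls The recognizable cohort ([classify_recognizable()] filter
#'   applied).
#' @param target_pct Benchmark percentage; default 95.
#' @return A one-row goal-result tibble.
#' @export
goal2_recognizable_recognition <- function(calls, target_pct = 95) {
  check_columns(calls, "recognized", "call table")
  goal_result(2, "recognized_of_recognizable",
              sum(isTRUE_v(calls$recognized)), nrow(calls), target_pct)
}

#' Goal 3: DA-CPR delivery among available calls
#'
#' Proportion of DA-CPR-available calls that received dispatch-directed
#' compressions (primary, 75% benchmark), plus the companion proportion
#' receiving any chest compression during the call (directed or
#' spontaneous; descriptive, no benchmark).
#'
#' @param calls The DA-CPR-available cohort ([classify_dacpr_available()]
#'   filter applied).
#' @param target_pct Benchmark percentage for the primary measure; default 75.
#' @return A two-row goal-result tibble (`dacpr_directed`,
#'   `any_compression`).
#' @export
goal3_dacpr_delivery <- function(calls, target_pct = 75) {
  check_columns(calls, c("dacpr_compressions_given",
                         "any_compression_during_call"), "call table")
  n <- nrow(calls)
  dplyr::bind_rows(
    goal_result(3, "dacpr_directed",
                sum(isTRUE_v(calls$dacpr_compressions_given)), n, target_pct),
    goal_result(3, "any_compression",
                sum(isTRUE_v(calls$any_compression_during_call)), n,
                NA_real_)
  )
}

#' Time metric: median, IQR and threshold attainment for one delay variable
#'
#' Summarizes one event-time column over a stage cohort. The median and IQR
#' are computed over calls with the time recorded. Threshold attainment
#' counts calls with time strictly below each threshold; its percentage
#' denominator is the *full* stage cohort (time-missing calls included),
#' matching how audit tables report attainment. Missingness is counted among
#' the calls to which the time applies (e.g. recognition time applies to
#' recognized calls only).
#'
#' @param calls Stage cohort tibble.
#' @param time_col Name of the time column (string).
#' @param thresholds_s Numeric thresholds in seconds.
#' @param applicable Logical vector marking rows to which the time applies;
#'   default all rows.
#' @param variable Label for the metric; defaults to `time_col`.
#' @return A one-row tibble: `variable`, `n_stage`, `n_applicable`,
#'   `n_with_time`, `n_missing`, `median_s`, `q1_s`, `q3_s`, and an
#'   `attainment` list-column holding a tibble of `threshold_s`, `n`, `pct`,
#'   `pct_rounded`.
#' @export
time_metric <- function(calls, time_col, thresholds_s,
                        applicable = rep(TRUE, nrow(calls)),
                        variable = time_col) {
  check_columns(calls, time_col, "call table")
  stopifnot(length(applicable) == nrow(calls))
  x <- calls[[time_col]]
  n_stage <- nrow(calls)
  n_app <- sum(applicable)
  with_time <- x[applicable & !is.na(x)]
  thresholds_s <- sort(thresholds_s)

  att <- tibble::tibble(
    threshold_s = thresholds_s,
    n = purrr::map_int(thresholds_s, function(th) sum(with_time < th)),
  )
  att$pct <- pct_of(att$n, n_stage)
  att$pct_rounded <- ifelse(is.na(att$pct), NA_integer_,
                            as.integer(round_half_up(att$pct)))

  if (length(with_time) > 0) {
    mq <- median_iqr(with_time)
  } else {
    mq <- tibble::tibble(median_s = NA_real_, q1_s = NA_real_,
                         q3_s = NA_real_, n = 0L)
  }
  tibble::tibble(
    variable = variable,
    n_stage = n_stage,
    n_applicable = as.integer(n_app),
    n_with_time = as.integer(length(with_time)),
    n_missing = as.integer(n_app - length(with_time)),
    median_s = mq$median_s, q1_s = mq$q1_s, q3_s = mq$q3_s,
    attainment = list(att)
  )
}

#' Goal 4: time to recognition and time to EMS dispatch
#'
#' Median/IQR and attainment at 60 s and 90 s over the recognizable cohort.
#' Recognition time applies to recognized calls (a non-recognized call has
#' no recognition moment), so time-missingness is counted among those;
#' dispatch time applies to every call. Attainment percentages use the full
#' recognizable cohort as denominator.
#'
#' @param calls The recognizable cohort.
#' @param thresholds_s Attainment thresholds; default `c(60, 90)`.
#' @return A two-row time-metric tibble (`recognition`, `dispatch`).
#' @export
goal4_times <- function(calls, thresholds_s = c(60, 90)) {
  dplyr::bind_rows(
    time_metric(calls, "t_recognition_s", thresholds_s,
                applicable = isTRUE_v(calls$recognized),
                variable = "recognition"),
    time_metric(calls, "t_dispatch_s", thresholds_s, variable = "dispatch")
  )
}

#' Goal 5: time to chest compressions
#'
#' Median/IQR and attainment at 90 s and 150 s over the DA-CPR-available
#' cohort, for three delays: first chest compression by anyone, first
#' DA-CPR-directed compression, and start of CPR instructions. Each time
#' applies to the calls where the event occurred (any compression /
#' directed compressions given); attainment denominators are the full
#' available cohort.
#'
#' @param calls The DA-CPR-available cohort.
#' @param thresholds_s Attainment thresholds; default `c(90, 150)`.
#' @return A three-row time-metric tibble (`any_compression`,
#'   `dacpr_compression`, `cpr_instruction`).
#' @export
goal5_times <- function(calls, thresholds_s = c(90, 150)) {
  dacpr_given <- isTRUE_v(calls$dacpr_compressions_given)
  dplyr::bind_rows(
    time_metric(calls, "t_first_compression_s", thresholds_s,
                applicable = isTRUE_v(calls$any_compression_during_call),
                variable = "any_compression"),
    time_metric(calls, "t_first_dacpr_compression_s", thresholds_s,
                applicable = dacpr_given, variable = "dacpr_compression"),
    time_metric(calls, "t_cpr_instruction_s", thresholds_s,
                applicable = dacpr_given, variable = "cpr_instruction")
  )
}

#' Benchmark verdicts for the proportion goals
#'
#' @param goals A goal-result tibble (rows from [goal1_recognition()],
#'   [goal2_recognizable_recognition()], [goal3_dacpr_delivery()]).
#' @param benchmarks Benchmark tibble; default [aha_benchmarks()]. The
#'   benchmark's `target_pct` overrides each benchmarked row's target;
#'   descriptive rows (target `NA`, like the any-compression companion
#'   measure) stay unbenchmarked.
#' @return `goals` with `target_pct` updated and `met` recomputed.
#' @export
benchmark_proportions <- function(goals, benchmarks = aha_benchmarks()) {
  check_columns(goals, c("goal_id", "pct"), "goal results")
  bm <- dplyr::select(benchmarks, "goal_id", bm_target = "target_pct")
  out <- dplyr::left_join(goals, bm, by = "goal_id")
  if ("target_pct" %in% names(goals)) {
    out$target_pct <- dplyr::if_else(
      is.na(out$target_pct), NA_real_,
      dplyr::coalesce(out$bm_target, out$target_pct)
    )
  } else {
    out$target_pct <- out$bm_target
  }
  out$bm_target <- NULL
  out$met <- !is.na(out$pct) & !is.na(out$target_pct) &
    out$pct >= out$target_pct
  out
}

#' Benchmark verdicts for the median-time goals
#'
#' Applies the strict time benchmarks to observed medians: a system is
#' high-performance when the median is strictly below `high_perf_s` and
#' meets the minimal acceptable standard when strictly below
#' `minimal_std_s` (the AHA wording is "< 60 s", so a median exactly at a
#' threshold does not meet it).
#'
#' @param medians A tibble with columns `goal_id` (4 or 5), `variable`, and
#'   `median_s` — either from [goal4_times()]/[goal5_times()] output with a
#'   `goal_id` column added, or entered directly from published medians.
#' @param benchmarks Benchmark tibble; default [aha_benchmarks()].
#' @return `medians` with `high_perf_s`, `minimal_std_s`, `met_high`,
#'   `met_minimal` added.
#' @examples
#' benchmark_medians(tibble::tibble(
#'   goal_id = c(4, 4, 5), variable = c("recognition", "dispatch", "dacpr"),
#'   median_s = c(113, 87, 240)
#' ))
#' @export
benchmark_medians <- function(medians, benchmarks = aha_benchmarks()) {
  check_columns(medians, c("goal_id", "median_s"), "median table")
  bm <- dplyr::select(benchmarks, "goal_id", "high_perf_s", "minimal_std_s")
  out <- dplyr::left_join(medians, bm, by = "goal_id")
  dplyr::mutate(out,
    met_high = !is.na(.data$median_s) & .data$median_s < .data$high_perf_s,
    met_minimal = !is.na(.data$median_s) &
      .data$median_s < .data$minimal_std_s
  )
}
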