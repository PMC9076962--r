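# Full audit driver: cascade -> goal metrics -> benchmark verdicts ->
# lives-saved estimates -> survival-vs-delay curves, assembled into one
# report object with JSON and text renderings.

#' Default lives-saved targets
#'
#' The three counterfactual targets the audit evaluates: OHCA recognition
#' within 60 s (recognizable cohort), EMS dispatch within 60 s (included
#' cohort), and first chest compression within 90 s (DA-CPR-available
#' cohort).
#'
#' @return A tibble with columns `time_field`, `threshold_s`, `cohort`.
#' @export
default_lives_saved_targets <- function() {
  tibble::tibble(
    time_field = c("t_recognition_s", "t_dispatch_s",
                   "t_first_compression_s"),
    threshold_s = c(60, 60, 90),
    cohort = c("recognizable", "included", "dacpr_available")
  )
}

stage_cohorts <- function(calls) {
  included <- apply_study_exclusions(calls)$included
  marked <- classify_recognizable(included)
  recognizable <- dplyr::filter(marked, .data$recognizable)
  recognized <- dplyr::filter(recognizable, isTRUE_v(.data$recognized))
  available <- dplyr::filter(classify_dacpr_available(recognized),
                             .data$dacpr_available)
  list(included = included, recognizable = recognizable,
       recognized = recognized, dacpr_available = available)
}

#' Run the full OHCA call audit
#'
#' Runs the pipeline end to end on a per-call table: exclusion cascade,
#' the five AHA performance goals with benchmark verdicts, the
#' additional-survivors estimates for the default (or supplied) targets,
#' and optionally the spline survival curves.
#'
#' @param calls A call tibble, or a path to a CSV in the
#'   [read_call_table()] schema.
#' @param benchmarks Benchmark tibble; default [aha_benchmarks()].
#' @param lives_targets Target table as in [default_lives_saved_targets()];
#'   `NULL` skips the estimates.
#' @param curves Logical: also fit survival-vs-delay spline curves for
#'   recognition, first compression and dispatch times on the included
#'   cohort? Default `FALSE` (the curves need enough events to fit).
#' @param validate Logical: stop if [validate_calls()] finds violations?
#'   Default `TRUE`.
#' @return An object of class `ohca_audit` with elements `cascade`,
#'   `goals`, `time_metrics`, `verdicts`, `lives_saved`, `overall_survival`,
#'   `curves`, `provenance`. See [audit_to_json()], [tidy.ohca_audit()].
#' @examples
#' report <- run_audit(reference_cohort())
#' report$goals
#' @export
run_audit <- function(calls, benchmarks = aha_benchmarks(),
                      lives_targets = default_lives_saved_targets(),
                      curves = FALSE, validate = TRUE) {
  input_path <- NULL
  if (is.character(calls) && length(calls) == 1) {
    input_path <- calls
    calls <- read_call_table(calls)
  }
  check_columns(calls, call_columns(), "call table")
  if (nrow(calls) == 0) abort("empty cohort: nothing to audit")
  if (validate) {
    viol <- validate_calls(calls)
    if (nrow(viol) > 0) {
      abort(sprintf(
        "call table fails validation (%d violation%s); first: row %d, %s: %s",
        nrow(viol), if (nrow(viol) > 1) "s" else "",
        viol$row[1], viol$field[1], viol$message[1]
      ))
    }
  }

  cascade <- build_cascade_report(calls)
  st <- stage_cohorts(calls)

  goals <- dplyr::bind_rows(
    goal1_recognition(st$included),
    goal2_recognizable_recognition(st$recognizable),
    goal3_dacpr_delivery(st$dacpr_available)
  )
  goals <- benchmark_proportions(goals, benchmarks)

  time_metrics <- dplyr::bind_rows(
    dplyr::mutate(goal4_times(st$recognizable), goal_id = 4L, .before = 1),
    dplyr::mutate(goal5_times(st$dacpr_available), goal_id = 5L, .before = 1)
  )
  verdicts <- benchmark_medians(
    dplyr::select(time_metrics, "goal_id", "variable", "median_s"),
    benchmarks
  )

  lives <- NULL
  if (!is.null(lives_targets)) {
    lives <- purrr::pmap_dfr(lives_targets, function(time_field, threshold_s,
                                                     cohort) {
      rates <- survival_rates_by_target(st[[cohort]], time_field, threshold_s)
      out <- estimate_additional_lives(rates)
      dplyr::mutate(out, cohort = cohort, .before = 1)
    })
  }

  surv_known <- st$included$survived_30d
  overall <- goal_result(NA_integer_, "overall_30d_survival",
                         sum(isTRUE_v(surv_known)), nrow(st$included),
                         NA_real_)

  curve_list <- NULL
  if (isTRUE(curves)) {
    curve_list <- purrr::map(
      c(recognition = "t_recognition_s",
        first_compression = "t_first_compression_s",
        dispatch = "t_dispatch_s"),
      function(col) survival_delay_curve(st$included, col)
    )
  }

  structure(list(
    cascade = cascade,
    goals = goals,
    time_metrics = time_metrics,
    verdicts = verdicts,
    lives_saved = lives,
    overall_survival = overall,
    curves = curve_list,
    provenance = list(
      n_input = nrow(calls),
      input_path = input_path,
      input_hash = rlang::hash(calls),
      package_version = as.character(utils::packageVersion("ohcaudit")),
      benchmarks = benchmarks
    )
  ), class = "ohca_audit")
}

#' Lives-saved table from a cohort or from explicit stratum rates
#'
#' Cohort mode stratifies the stage cohorts at each target and runs the
#' estimator; explicit-rates mode takes published stratum survival rates
#' directly (the audit's own stratum rates are printed in reports even when
#' raw data are not shared).
#'
#' @param calls A call tibble or CSV path (cohort mode), or `NULL`.
#' @param rates A data frame with `p_met`, `p_not_met`, `n_not_met`
#'   (explicit-rates mode), or `NULL`. Exactly one of `calls`/`rates` must
#'   be given.
#' @param targets Target table for cohort mode; default
#'   [default_lives_saved_targets()].
#' @param national_n Optional national annual OHCA count; adds an unrounded
#'   `national_extrapolation` column scaled by the audited sample size
#'   (cohort mode) or `sample_n`.
#' @param sample_n Sample size for the extrapolation in explicit-rates
#'   mode.
#' @return A tibble with one row per target: the estimator inputs, `raw`,
#'   `additional_lives`, and optionally `national_extrapolation`.
#' @examples
#' run_lives_saved(rates = lives_saved_input(
#'   p_met = c(0.1052, 0.08556, 0.20),
#'   p_not_met = c(0.07056, 0.07142, 0.0615),
#'   n_not_met = c(727, 749, 530)
#' ))
#' @export
run_lives_saved <- function(calls = NULL, rates = NULL,
                            targets = default_lives_saved_targets(),
                            national_n = NULL, sample_n = NULL) {
  if (is.null(calls) == is.null(rates)) {
    abort("supply exactly one of `calls` (cohort mode) or `rates`")
  }
  if (!is.null(rates)) {
    out <- estimate_additional_lives(rates)
    if (!is.null(national_n)) {
      if (is.null(sample_n)) {
        abort("explicit-rates extrapolation needs `sample_n`")
      }
      out$national_extrapolation <-
        extrapolate_national(out$additional_lives, sample_n, national_n)
    }
    return(out)
  }
  if (is.character(calls)) calls <- read_call_table(calls)
  st <- stage_cohorts(calls)
  out <- purrr::pmap_dfr(targets, function(time_field, threshold_s, cohort) {
    rates_i <- survival_rates_by_target(st[[cohort]], time_field,
                                        threshold_s)
    dplyr::mutate(estimate_additional_lives(rates_i),
                  cohort = cohort, .before = 1)
  })
  if (!is.null(national_n)) {
    out$national_extrapolation <- extrapolate_national(
      out$additional_lives, sample_n %||% nrow(calls), national_n
    )
  }
  out
}

#' @export
print.ohca_audit <- function(x, ...) {
  cat("== OHCA emergency-call audit ==\n\n")
  print(x$cascade)
  cat("\nPerformance goals (proportions)\n")
  g <- x$goals
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  goal %s %-26s %4d / %4d = %3s%%  target %s  [%s]\n",
      ifelse(is.na(g$goal_id[i]), "-", g$goal_id[i]), g$measure[i],
      g$numerator[i], g$denominator[i],
      ifelse(is.na(g$pct_rounded[i]), "NA", g$pct_rounded[i]),
      ifelse(is.na(g$target_pct[i]), "--", paste0(g$target_pct[i], "%")),
      ifelse(is.na(g$target_pct[i]), "descriptive",
             ifelse(g$met[i], "met", "NOT met"))
    ))
  }
  cat("\nTime metrics (median [IQR] s, attainment % of stage cohort)\n")
  tm <- x$time_metrics
  for (i in seq_len(nrow(tm))) {
    att <- tm$attainment[[i]]
    cat(sprintf(
      "  goal %d %-18s %s [%s, %s]  %s  (missing %d)\n",
      tm$goal_id[i], tm$variable[i],
      ifelse(is.na(tm$median_s[i]), "NA", round(tm$median_s[i])),
      ifelse(is.na(tm$q1_s[i]), "NA", round(tm$q1_s[i])),
      ifelse(is.na(tm$q3_s[i]), "NA", round(tm$q3_s[i])),
      paste(sprintf("<%gs: %d (%s%%)", att$threshold_s, att$n,
                    att$pct_rounded), collapse = ", "),
      tm$n_missing[i]
    ))
  }
  os <- x$overall_survival
  cat(sprintf("\nOverall 30-day survival: %d / %d (%d%%)\n",
              os$numerator, os$denominator, os$pct_rounded))
  if (!is.null(x$lives_saved)) {
    cat("\nAdditional survivors if targets were met\n")
    ls <- x$lives_saved
    for (i in seq_len(nrow(ls))) {
      cat(sprintf(
        "  %s < %g s: (%.4f - %.4f) x %d = %.2f -> %d lives\n",
        ls$time_field[i], ls$threshold_s[i], ls$p_met[i], ls$p_not_met[i],
        ls$n_not_met[i], ls$raw[i], ls$additional_lives[i]
      ))
    }
  }
  invisible(x)
}

#' Tidy an audit report
#'
#' @param x An `ohca_audit` object.
#' @param ... Unused.
#' @return The goal-result tibble, with the overall-survival row appended.
#' @method tidy ohca_audit
#' @export
tidy.ohca_audit <- function(x, ...) {
  dplyr::bind_rows(x$goals, x$overall_survival)
}

#' One-row summary of an audit report
#'
#' @param x An `ohca_audit` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline cohort counts and percentages.
#' @method glance ohca_audit
#' @export
glance.ohca_audit <- function(x, ...) {
  g <- function(measure) x$goals$pct_rounded[x$goals$measure == measure][1]
  tibble::tibble(
    n_input = x$cascade$n_input,
    n_included = x$cascade$n_included,
    n_recognizable = x$cascade$n_recognizable,
    n_recognized = x$cascade$n_recognized,
    n_dacpr_available = x$cascade$n_dacpr_available,
    pct_recognized = g("recognized"),
    pct_recognized_of_recognizable = g("recognized_of_recognizable"),
    pct_dacpr_directed = g("dacpr_directed"),
    pct_any_compression = g("any_compression"),
    pct_survival_30d = x$overall_survival$pct_rounded
  )
}

# tibble -> list of row-lists for stable JSON
rows_as_list <- function(df) {
  df <- df[!purrr::map_lgl(df, is.list)]
  purrr::transpose(as.list(df))
}

#' Serialize an audit report to JSON
#'
#' A pure function of the report content: re-running the audit on the same
#' input yields byte-identical JSON (no timestamps). Every number shown in
#' the printed report also appears here.
#'
#' @param report An `ohca_audit` object.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @seealso [validate_audit_json()]
#' @export
audit_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ohca_audit"))
  att <- purrr::map2_dfr(
    report$time_metrics$variable, report$time_metrics$attainment,
    function(v, a) dplyr::mutate(a, variable = v, .before = 1)
  )
  payload <- list(
    cascade = purrr::map(unclass(report$cascade), function(x) {
      if (length(names(x)) > 0) as.list(x) else x
    }),
    goals = rows_as_list(report$goals),
    time_metrics = rows_as_list(report$time_metrics),
    attainment = rows_as_list(att),
    verdicts = rows_as_list(report$verdicts),
    lives_saved = if (is.null(report$lives_saved)) list() else
      rows_as_list(report$lives_saved),
    overall_survival = rows_as_list(report$overall_survival)[[1]],
    provenance = list(
      n_input = report$provenance$n_input,
      input_hash = report$provenance$input_hash,
      package_version = report$provenance$package_version
    )
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Structurally validate audit-report JSON
#'
#' Checks a JSON document against the shipped report schema
#' (`inst/extdata/audit-report-schema.json`): required top-level sections,
#' required fields per section, and numeric/flag types.
#'
#' @param json A JSON string (or anything `jsonlite::fromJSON` accepts).
#' @return A character vector of problems; empty when the document
#'   conforms.
#' @export
validate_audit_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  problems <- character()
  need <- function(ok, msg) {
    if (!ok) problems <<- c(problems, msg)
  }
  sections <- c("cascade", "goals", "time_metrics", "attainment",
                "verdicts", "lives_saved", "overall_survival", "provenance")
  for (s in sections) need(s %in% names(doc), paste("missing section:", s))
  if (length(problems) > 0) return(problems)

  casc_fields <- c("n_input", "study_exclusions", "n_included",
                   "recognizability_exclusions", "n_recognizable",
                   "n_recognized_overall", "n_recognized",
                   "dacpr_exclusions", "n_dacpr_available")
  for (f in casc_fields) {
    need(f %in% names(doc$cascade), paste("cascade missing:", f))
  }
  counts <- unlist(doc$cascade[casc_fields])
  need(all(is.numeric(counts)) && all(counts >= 0),
       "cascade counts must be nonnegative numbers")
  for (g in doc$goals) {
    for (f in c("goal_id", "measure", "numerator", "denominator", "pct")) {
      need(f %in% names(g), paste("goal entry missing:", f))
    }
  }
  for (tmx in doc$time_metrics) {
    for (f in c("variable", "n_stage", "n_with_time", "n_missing")) {
      need(f %in% names(tmx), paste("time metric missing:", f))
    }
  }
  for (a in doc$attainment) {
    for (f in c("variable", "threshold_s", "n", "pct")) {
      need(f %in% names(a), paste("attainment entry missing:", f))
    }
  }
  need(is.numeric(doc$overall_survival$numerator %||% NA) ||
         is.null(doc$overall_survival$numerator),
       "overall_survival.numerator must be numeric")
  unique(problems)
}
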