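# Exclusion cascade: study-level exclusions, the AHA "recognizable OHCA"
# filter, and the AHA "available for DA-CPR" filter, with conservation
# accounting so included + excluded-by-reason always sums to the stage input.

study_exclusion_reasons <- function() c("ALIVE_DURING_CALL", "MISSING_AUDIO")

recognizability_exclusion_reasons <- function() {
  c("CPR_IN_PROGRESS", "THIRD_PARTY", "HYSTERICAL", "HANG_UP",
    "LANGUAGE", "OTHER")
}

dacpr_exclusion_reasons <- function() {
  c("CANNOT_MOVE", "REFUSES", "HANG_UP", "NOT_WITH_PATIENT", "OTHER")
}

count_reasons <- function(x, reasons) {
  tab <- table(factor(x, levels = reasons))
  setNames(as.integer(tab), reasons)
}

#' Apply the study-level exclusions
#'
#' Removes calls excluded before any performance goal is assessed: patients
#' alive during the call, then calls whose voice log is missing. Each
#' excluded call is attributed to exactly one reason, in that priority
#' order, so the counts conserve the input size.
#'
#' @param calls A validated call tibble.
#' @return A list with `included` (tibble of retained calls), `excluded`
#'   (tibble with an extra `exclusion_reason` column) and `counts` (named
#'   integer vector over `ALIVE_DURING_CALL`, `MISSING_AUDIO`).
#' @export
apply_study_exclusions <- function(calls) {
  check_columns(calls, c("alive_during_call", "audio_available"), "call table")
  reason <- dplyr::case_when(
    isTRUE_v(calls$alive_during_call) ~ "ALIVE_DURING_CALL",
    !isTRUE_v(calls$audio_available)  ~ "MISSING_AUDIO",
    TRUE                              ~ NA_character_
  )
  excluded <- calls[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  list(
    included = calls[is.na(reason), , drop = FALSE],
    excluded = excluded,
    counts = count_reasons(reason, study_exclusion_reasons())
  )
}

#' Classify calls as recognizable OHCA
#'
#' Flags each included call as recognizable or not under the AHA exclusion
#' criteria. A call is not recognizable iff bystander CPR was already in
#' progress (checked first) or a recognizability barrier was recorded; the
#' reason is `CPR_IN_PROGRESS` or the barrier label, else `NONE`.
#'
#' @param calls A call tibble that passed study-level inclusion.
#' @return `calls` with added logical `recognizable` and character
#'   `recognizability_reason` columns.
#' @export
classify_recognizable <- function(calls) {
  check_columns(calls, c("cpr_in_progress", "recognizability_barrier"),
                "call table")
  reason <- dplyr::case_when(
    isTRUE_v(calls$cpr_in_progress)          ~ "CPR_IN_PROGRESS",
    calls$recognizability_barrier != "NONE"  ~ calls$recognizability_barrier,
    TRUE                                     ~ "NONE"
  )
  dplyr::mutate(calls,
    recognizable = reason == "NONE",
    recognizability_reason = reason
  )
}

#' Classify recognized calls as available for DA-CPR
#'
#' Flags each recognized, recognizable call as available for
#' dispatcher-assisted CPR. A call is unavailable iff a caller-side DA-CPR
#' barrier was recorded (cannot move the patient, refusal, hang-up, caller
#' not with patient, other). Applying this to a non-recognized call is a
#' contract violation and errors.
#'
#' @param calls A call tibble of recognized, recognizable calls.
#' @return `calls` with added logical `dacpr_available` and character
#'   `dacpr_exclusion_reason` columns.
#' @export
classify_dacpr_available <- function(calls) {
  check_columns(calls, c("recognized", "dacpr_barrier"), "call table")
  if (!all(isTRUE_v(calls$recognized))) {
    abort("classify_dacpr_available() requires recognized calls only")
  }
  dplyr::mutate(calls,
    dacpr_available = .data$dacpr_barrier == "NONE",
    dacpr_exclusion_reason = dplyr::if_else(.data$dacpr_barrier == "NONE",
                                            "NONE", .data$dacpr_barrier)
  )
}

#' Build the cohort-construction cascade report
#'
#' Composes the three classifiers into the full flowchart: input cohort,
#' study-level exclusions, recognizable OHCA, recognized OHCA, and calls
#' available for DA-CPR, with per-reason exclusion counts at every stage.
#'
#' Two recognition counts are reported because they answer different
#' questions: `n_recognized_overall` counts recognized calls in the whole
#' included cohort (the numerator of performance goal 1), while
#' `n_recognized` counts them within the recognizable stratum (the
#' numerator of goal 2 and the input to the DA-CPR availability stage).
#'
#' @param calls A validated call tibble (the full audited sample).
#' @return A `cascade_report` object; see [tidy.cascade_report()] for the
#'   tabular form and [cascade_to_json()] for serialization.
#' @examples
#' rep <- build_cascade_report(reference_cohort())
#' rep$n_dacpr_available
#' @export
build_cascade_report <- function(calls) {
  check_columns(calls, call_columns(), "call table")
  stage0 <- apply_study_exclusions(calls)
  inc <- classify_recognizable(stage0$included)
  recognizable <- dplyr::filter(inc, .data$recognizable)
  rec_counts <- count_reasons(
    inc$recognizability_reason[!inc$recognizable],
    recognizability_exclusion_reasons()
  )
  recognized <- dplyr::filter(recognizable, isTRUE_v(.data$recognized))
  av <- classify_dacpr_available(recognized)
  dacpr_counts <- count_reasons(
    av$dacpr_exclusion_reason[!av$dacpr_available],
    dacpr_exclusion_reasons()
  )
  report <- structure(list(
    n_input = nrow(calls),
    study_exclusions = stage0$counts,
    n_included = nrow(stage0$included),
    recognizability_exclusions = rec_counts,
    n_recognizable = nrow(recognizable),
    n_recognized_overall = sum(isTRUE_v(inc$recognized)),
    n_recognized = nrow(recognized),
    dacpr_exclusions = dacpr_counts,
    n_dacpr_available = sum(av$dacpr_available)
  ), class = "cascade_report")
  stopifnot(
    report$n_included == report$n_input - sum(report$study_exclusions),
    report$n_recognizable ==
      report$n_included - sum(report$recognizability_exclusions),
    report$n_dacpr_available ==
      report$n_recognized - sum(report$dacpr_exclusions)
  )
  report
}

#' @export
print.cascade_report <- function(x, ...) {
  line <- function(...) cat(sprintf(...), "\n", sep = "")
  reasons <- function(counts) {
    for (r in names(counts)) line("    - %-18s n = %d", r, counts[[r]])
  }
  line("OHCA call cohort cascade")
  line("  audited calls                 n = %d", x$n_input)
  reasons(x$study_exclusions)
  line("  included                      n = %d", x$n_included)
  reasons(x$recognizability_exclusions)
  line("  recognizable OHCA             n = %d", x$n_recognizable)
  line("  recognized (whole cohort)     n = %d", x$n_recognized_overall)
  line("  recognized (of recognizable)  n = %d", x$n_recognized)
  reasons(x$dacpr_exclusions)
  line("  available for DA-CPR          n = %d", x$n_dacpr_available)
  invisible(x)
}

#' Tidy a cascade report
#'
#' @param x A `cascade_report`.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `reason`, `n`: one row per stage
#'   count and one per exclusion reason.
#' @method tidy cascade_report
#' @export
tidy.cascade_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(stage = "input", reason = NA_character_, n = x$n_input),
    tibble::tibble(stage = "study_exclusion",
                   reason = names(x$study_exclusions),
                   n = as.integer(x$study_exclusions)),
    tibble::tibble(stage = "included", reason = NA_character_,
                   n = x$n_included),
    tibble::tibble(stage = "recognizability_exclusion",
                   reason = names(x$recognizability_exclusions),
                   n = as.integer(x$recognizability_exclusions)),
    tibble::tibble(stage = "recognizable", reason = NA_character_,
                   n = x$n_recognizable),
    tibble::tibble(stage = "recognized_overall", reason = NA_character_,
                   n = x$n_recognized_overall),
    tibble::tibble(stage = "recognized", reason = NA_character_,
                   n = x$n_recognized),
    tibble::tibble(stage = "dacpr_exclusion",
                   reason = names(x$dacpr_exclusions),
                   n = as.integer(x$dacpr_exclusions)),
    tibble::tibble(stage = "dacpr_available", reason = NA_character_,
                   n = x$n_dacpr_available)
  )
}

#' Serialize a cascade report to JSON
#'
#' @param report A `cascade_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
cascade_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "cascade_report"))
  payload <- purrr::map(unclass(report), function(x) {
    if (length(names(x)) > 0) as.list(x) else x
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
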