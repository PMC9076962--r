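# Per-call data model: one row per audited OHCA emergency call.
#
# All event times are seconds from the moment the emergency call was
# answered (the audit's time origin). Missing values are genuine NAs and are
# distinguishable from FALSE/0 for every nullable field.

#' Barrier and covariate level sets
#'
#' Canonical level sets for the enumerated columns of a call table. Unknown
#' labels are rejected on read rather than silently reclassified.
#'
#' @name call-levels
#' @keywords internal
NULL

recognizability_barrier_levels <- function() {
  c("NONE", "THIRD_PARTY", "HYSTERICAL", "HANG_UP", "LANGUAGE", "OTHER")
}

dacpr_barrier_levels <- function() {
  c("NONE", "CANNOT_MOVE", "REFUSES", "HANG_UP", "NOT_WITH_PATIENT", "OTHER")
}

location_levels <- function() c("RESIDENTIAL", "PUBLIC", "OTHER")

cause_levels <- function() {
  c("CARDIAC", "OVERDOSE", "TRAUMA", "RESPIRATORY", "ASPHYXIA",
    "SUICIDE", "SUBMERSION", "SIDS", "OTHER")
}

sex_levels <- function() c("MALE", "FEMALE")

# internal schema: column -> type descriptor
call_schema <- function() {
  list(
    call_id                    = list(type = "id"),
    t_recognition_s            = list(type = "time"),
    t_dispatch_s               = list(type = "time"),
    t_cpr_instruction_s        = list(type = "time"),
    t_first_compression_s      = list(type = "time"),
    t_first_dacpr_compression_s = list(type = "time"),
    recognized                 = list(type = "bool", required = TRUE),
    alive_during_call          = list(type = "bool", required = TRUE),
    audio_available            = list(type = "bool", required = TRUE),
    cpr_in_progress            = list(type = "bool", required = TRUE),
    recognizability_barrier    = list(type = "enum", required = TRUE,
                                      levels = recognizability_barrier_levels()),
    dacpr_barrier              = list(type = "enum", required = TRUE,
                                      levels = dacpr_barrier_levels()),
    any_compression_during_call = list(type = "bool", required = FALSE),
    dacpr_compressions_given   = list(type = "bool", required = TRUE),
    survived_30d               = list(type = "bool", required = FALSE),
    patient_age                = list(type = "age"),
    patient_sex                = list(type = "enum", required = FALSE,
                                      levels = sex_levels()),
    caller_sex                 = list(type = "enum", required = FALSE,
                                      levels = sex_levels()),
    caller_alone               = list(type = "bool", required = FALSE),
    caller_hcp                 = list(type = "bool", required = FALSE),
    caller_knows_victim        = list(type = "bool", required = FALSE),
    location                   = list(type = "enum", required = FALSE,
                                      levels = location_levels()),
    witnessed                  = list(type = "bool", required = FALSE),
    cause                      = list(type = "enum", required = FALSE,
                                      levels = cause_levels()),
    shockable_rhythm           = list(type = "bool", required = FALSE),
    aed_addressed              = list(type = "bool", required = FALSE),
    call_continued_until_ems   = list(type = "bool", required = FALSE)
  )
}

#' Column names of a call table
#'
#' The canonical column order of the per-call CSV schema.
#'
#' @return Character vector of column names.
#' @export
call_columns <- function() names(call_schema())

time_columns <- function() {
  c("t_recognition_s", "t_dispatch_s", "t_cpr_instruction_s",
    "t_first_compression_s", "t_first_dacpr_compression_s")
}

# an empty, correctly typed call table
empty_call_table <- function() {
  sch <- call_schema()
  cols <- purrr::map(sch, function(s) {
    switch(s$type,
      id   = character(),
      time = numeric(),
      age  = numeric(),
      bool = logical(),
      enum = character()
    )
  })
  tibble::as_tibble(cols)
}

# ---- parsing helpers (strings -> typed columns, with row/column errors) ----

blank_to_na <- function(x) {
  x[!is.na(x) & (x == "" | toupper(x) == "NA")] <- NA_character_
  x
}

parse_fail <- function(col, rows, why) {
  abort(sprintf(
    "column '%s': %s at row%s %s",
    col, why, if (length(rows) > 1) "s" else "",
    paste(head(rows, 5), collapse = ", ")
  ))
}

parse_time_col <- function(x, col) {
  x <- blank_to_na(x)
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(y))
  if (length(bad) > 0) parse_fail(col, bad, "not a number")
  neg <- which(!is.na(y) & (y < 0 | !is.finite(y)))
  if (length(neg) > 0) parse_fail(col, neg, "negative or non-finite time")
  y
}

parse_bool_col <- function(x, col) {
  x <- blank_to_na(x)
  key <- tolower(x)
  y <- rep(NA, length(x))
  y[key %in% c("1", "true")] <- TRUE
  y[key %in% c("0", "false")] <- FALSE
  bad <- which(!is.na(x) & is.na(y))
  if (length(bad) > 0) parse_fail(col, bad, "not a boolean (use 0/1/true/false)")
  y
}

parse_enum_col <- function(x, col, levels) {
  x <- blank_to_na(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0) {
    parse_fail(col, bad, sprintf(
      "unknown label (allowed: %s)", paste(levels, collapse = ", ")
    ))
  }
  x
}

parse_age_col <- function(x, col) {
  x <- blank_to_na(x)
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(y))
  if (length(bad) > 0) parse_fail(col, bad, "not a number")
  neg <- which(!is.na(y) & (y < 0 | !is.finite(y)))
  if (length(neg) > 0) parse_fail(col, neg, "negative or non-finite age")
  y
}

#' Read a per-call audit table
#'
#' Reads the CSV schema of audited OHCA calls into a typed tibble. Empty
#' cells and the sentinel `NA` are read as missing; booleans accept
#' `0/1/true/false` case-insensitively; unknown enumeration labels are an
#' error (audit data must not be silently reclassified); unknown columns are
#' dropped with a warning.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return A tibble with one row per call, columns as in [call_columns()].
#' @seealso [write_call_table()], [validate_calls()]
#' @export
read_call_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  sch <- call_schema()
  miss <- setdiff(names(sch), names(raw))
  if (length(miss) > 0) {
    abort(sprintf("missing required column%s: %s",
                  if (length(miss) > 1) "s" else "",
                  paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(raw), names(sch))
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown column%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste(extra, collapse = ", ")))
  }
  if (nrow(raw) == 0) return(empty_call_table())

  out <- purrr::imap(sch, function(s, col) {
    x <- raw[[col]]
    switch(s$type,
      id   = blank_to_na(x),
      time = parse_time_col(x, col),
      age  = parse_age_col(x, col),
      bool = parse_bool_col(x, col),
      enum = parse_enum_col(x, col, s$levels)
    )
  })
  calls <- tibble::as_tibble(out)
  if (anyNA(calls$call_id)) {
    parse_fail("call_id", which(is.na(calls$call_id)), "missing identifier")
  }
  dup <- calls$call_id[duplicated(calls$call_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate call_id: %s",
                  paste(unique(head(dup, 5)), collapse = ", ")))
  }
  calls
}

#' Write a per-call audit table
#'
#' Writes calls in the canonical column order; missing values become empty
#' cells, so [read_call_table()] round-trips the table exactly.
#'
#' @param calls A call tibble (see [call_columns()]).
#' @param path Output CSV path.
#' @return `calls`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  check_columns(calls, call_columns(), "call table")
  readr::write_csv(calls[call_columns()], path, na = "")
  invisible(calls)
}

#' Validate a call table against the schema invariants
#'
#' Row-wise structural validation: event times nonnegative and finite,
#' required flags present, implication constraints between recognition and
#' DA-CPR fields, unique identifiers. Violations are returned as data, one
#' row each, never raised as errors.
#'
#' Checked implications: a DA-CPR-directed compression requires a recognized
#' OHCA (`dacpr_compressions_given` implies `recognized`); a recorded time to
#' DA-CPR compression implies compressions were given; a recorded recognition
#' time implies the call was recognized.
#'
#' @param calls A call tibble.
#' @return A tibble with columns `row`, `call_id`, `field`, `rule`,
#'   `message`; zero rows when every invariant holds.
#' @export
validate_calls <- function(calls) {
  check_columns(calls, call_columns(), "call table")
  sch <- call_schema()
  v <- list()
  add <- function(rows, field, rule, msg) {
    if (length(rows) == 0) return()
    v[[length(v) + 1]] <<- tibble::tibble(
      row = as.integer(rows),
      call_id = as.character(calls$call_id[rows]),
      field = field, rule = rule, message = msg
    )
  }

  add(which(is.na(calls$call_id) | calls$call_id == ""), "call_id",
      "id_present", "call_id must be non-empty")
  add(which(duplicated(calls$call_id) & !is.na(calls$call_id)), "call_id",
      "id_unique", "duplicate call_id")

  for (col in time_columns()) {
    x <- calls[[col]]
    add(which(!is.na(x) & (x < 0 | !is.finite(x))), col,
        "time_nonnegative", "event times must be finite and >= 0")
  }
  add(which(!is.na(calls$patient_age) &
              (calls$patient_age < 0 | !is.finite(calls$patient_age))),
      "patient_age", "age_nonnegative", "age must be finite and >= 0")

  for (col in names(sch)) {
    s <- sch[[col]]
    if (isTRUE(s$required) && s$type %in% c("bool", "enum")) {
      add(which(is.na(calls[[col]])), col, "required_present",
          "required field is missing")
    }
    if (s$type == "enum") {
      x <- calls[[col]]
      add(which(!is.na(x) & !(x %in% s$levels)), col, "enum_label",
          sprintf("label not in {%s}", paste(s$levels, collapse = ", ")))
    }
  }

  add(which(isTRUE_v(calls$dacpr_compressions_given) &
              !isTRUE_v(calls$recognized)),
      "dacpr_compressions_given", "dacpr_implies_recognized",
      "DA-CPR compressions given but call not recognized")
  add(which(!is.na(calls$t_first_dacpr_compression_s) &
              !isTRUE_v(calls$dacpr_compressions_given)),
      "t_first_dacpr_compression_s", "dacpr_time_implies_given",
      "time to DA-CPR compression present but compressions not given")
  add(which(!is.na(calls$t_recognition_s) & !isTRUE_v(calls$recognized)),
      "t_recognition_s", "recognition_time_implies_recognized",
      "recognition time present but call not recognized")

  if (length(v) == 0) {
    return(tibble::tibble(row = integer(), call_id = character(),
                          field = character(), rule = character(),
                          message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(v), .data$row, .data$field)
}

# TRUE where x is TRUE, FALSE where FALSE or NA
isTRUE_v <- function(x) !is.na(x) & x
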