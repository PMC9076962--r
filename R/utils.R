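# Small shared helpers.

#' Round half away from zero
#'
#' Integer rounding in which ties at .5 move away from zero (so 19.5 -> 20,
#' -19.5 -> -20), the convention under which every printed audit percentage
#' reproduces from its numerator/denominator pair. `base::round()` rounds
#' half to even and would disagree on ties.
#'
#' @param x Numeric vector.
#' @return Numeric vector of whole numbers.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.49, -0.5))
#' @export
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# percentage of a count over a denominator, NA-safe for denominator 0
pct_of <- function(num, denom) {
  len <- max(length(num), length(denom))
  num <- rep_len(num, len)
  denom <- rep_len(denom, len)
  out <- 100 * num / denom
  out[denom == 0] <- NA_real_
  out
}

# assert a data frame has the given columns, with a caller-facing error
check_columns <- function(data, cols, what = "input") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")
    ))
  }
  invisible(data)
}
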