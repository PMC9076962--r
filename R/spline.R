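# Restricted cubic splines and the logistic model of 30-day survival
# against a call-handling delay.
#
# The basis is the truncated-power restricted cubic spline (Harrell's
# construction): piecewise cubic between the knots, constrained to be
# linear beyond the boundary knots, with continuous value, first and second
# derivatives everywhere. Nonlinear columns are normalized by the squared
# boundary-knot span so coefficients stay on comparable scales.

#' Restricted cubic spline design columns
#'
#' For knots `t_1 < ... < t_k` (k >= 3) the basis has k-1 columns: the
#' linear term x, plus for j = 1..k-2 the normalized truncated-power term
#'
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'        + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#'
#' which vanishes below the first knot and cancels to a linear function
#' above the last, so the spline has linear tails.
#'
#' @param x Numeric vector (seconds).
#' @param knots Strictly increasing numeric vector, length >= 3.
#' @return A numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns, named `x`, `x1`, `x2`, ...
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3) abort("a restricted cubic spline needs >= 3 knots")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing")
  k <- length(knots)
  norm <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  cols <- matrix(0, nrow = length(x), ncol = k - 1)
  cols[, 1] <- x
  for (j in seq_len(k - 2)) {
    cols[, j + 1] <- (
      cube(x - knots[j]) -
        cube(x - knots[k - 1]) * (knots[k] - knots[j]) /
          (knots[k] - knots[k - 1]) +
        cube(x - knots[k]) * (knots[k - 1] - knots[j]) /
          (knots[k] - knots[k - 1])
    ) / norm
  }
  colnames(cols) <- c("x", if (k > 2) paste0("x", seq_len(k - 2)))
  cols
}

# Harrell's recommended outer/inner quantile positions by knot count
rcs_knot_quantiles <- function(k) {
  switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
    abort("knot count must be between 3 and 7")
  )
}

#' Default knot placement for a restricted cubic spline
#'
#' Knots at the conventional quantile positions for k knots (k = 4 uses the
#' 0.05, 0.35, 0.65, 0.95 quantiles), computed with type-7 quantiles.
#'
#' @param x Numeric vector of observed delays; missing values are ignored.
#' @param k Number of knots (3-7); default 4.
#' @return Numeric vector of k strictly increasing knots.
#' @export
default_knots <- function(x, k = 4) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < k) {
    abort(sprintf("need at least %d distinct values to place %d knots", k, k))
  }
  knots <- unname(quantile(x, probs = rcs_knot_quantiles(k), type = 7))
  if (any(diff(knots) <= 0)) {
    abort(paste0(
      "ties in the data collapse the quantile knots; ",
      "use fewer knots or place them manually"
    ))
  }
  knots
}

#' Fit a restricted-cubic-spline logistic model of survival on delay
#'
#' Maximizes the Bernoulli log-likelihood of
#' `logit P(survived) = beta0 + basis(delay) %*% beta` by iteratively
#' reweighted least squares. Convergence is declared when the relative
#' deviance change falls below `tol` (default 1e-8); after `max_iter`
#' iterations, or under apparent complete separation (fitted log-odds
#' diverging), the result is returned flagged non-converged rather than
#' erroring.
#'
#' Records with a missing delay or outcome carry no information for this
#' curve and are dropped; the count is reported in the fit.
#'
#' @param times Numeric delays in seconds.
#' @param outcomes Logical (or 0/1) 30-day survival, same length.
#' @param knots Knot vector; default `default_knots(times, k)`.
#' @param k Knot count used when `knots` is NULL; default 4.
#' @param tol Relative deviance-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `rcs_logit`: coefficients, covariance,
#'   knots, deviance, iteration count, convergence and separation flags,
#'   and the retained data. Methods: [tidy.rcs_logit()],
#'   [glance.rcs_logit()], [predict_curve()], [autoplot.rcs_logit()].
#' @examples
#' set.seed(1)
#' t <- runif(500, 0, 400)
#' y <- runif(500) < plogis(0.5 - 0.01 * t)
#' fit <- fit_spline_logistic(t, y)
#' glance(fit)
#' @export
fit_spline_logistic <- function(times, outcomes, knots = NULL, k = 4,
                                tol = 1e-8, max_iter = 100) {
  stopifnot(length(times) == length(outcomes))
  keep <- !is.na(times) & !is.na(outcomes)
  n_dropped <- sum(!keep)
  x <- as.numeric(times[keep])
  y <- as.numeric(outcomes[keep])
  if (any(!is.finite(x))) abort("delays must be finite")
  if (!all(y %in% c(0, 1))) abort("outcomes must be logical or 0/1")
  if (sum(y) == 0) abort("no events: every retained outcome is FALSE")
  if (sum(y) == length(y)) abort("no non-events: every retained outcome is TRUE")

  if (is.null(knots)) knots <- default_knots(x, k)
  basis <- rcs_basis(x, knots)
  X <- cbind(`(Intercept)` = 1, basis)

  beta <- rep(0, ncol(X))
  dev <- Inf
  converged <- FALSE
  separation <- FALSE
  iter <- 0
  XtWX <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30) {
      separation <- TRUE
      break
    }
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta)) abort("singular spline design; reduce the knot count")
    eta <- drop(X %*% beta)
    p <- plogis(pmin(pmax(eta, -30), 30))
    dev_new <- -2 * sum(y * log(p) + (1 - y) * log1p(-p))
    if (is.finite(dev) && abs(dev - dev_new) / (abs(dev) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }

  eta <- drop(X %*% beta)
  p <- plogis(pmin(pmax(eta, -30), 30))
  w <- pmax(p * (1 - p), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))

  pbar <- mean(y)
  null_dev <- -2 * sum(y * log(pbar) + (1 - y) * log(1 - pbar))

  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    vcov = vcov,
    knots = knots,
    deviance = dev,
    null_deviance = null_dev,
    iterations = iter,
    converged = converged && !separation,
    separation = separation,
    n = length(y),
    n_events = as.integer(sum(y)),
    n_dropped = as.integer(n_dropped),
    data = tibble::tibble(time_s = x, survived = y == 1)
  ), class = "rcs_logit")
}

#' @export
print.rcs_logit <- function(x, ...) {
  cat(sprintf(
    "Restricted-cubic-spline logistic model (%d knots)\n", length(x$knots)
  ))
  cat("  knots (s):", paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat(sprintf("  n = %d (%d events, %d dropped for missingness)\n",
              x$n, x$n_events, x$n_dropped))
  cat(sprintf("  deviance %.3f after %d IRLS iterations%s\n",
              x$deviance, x$iterations,
              if (x$converged) "" else
                if (x$separation) " [SEPARATION: not converged]"
                else " [NOT converged]"))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a spline logistic fit
#'
#' @param x An `rcs_logit` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (Wald z), `p.value`.
#' @method tidy rcs_logit
#' @export
tidy.rcs_logit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' One-row model summary of a spline logistic fit
#'
#' @param x An `rcs_logit` object.
#' @param ... Unused.
#' @return A one-row tibble: deviance, null deviance, iterations,
#'   convergence and separation flags, n, events, dropped records.
#' @method glance rcs_logit
#' @export
glance.rcs_logit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance,
    null_deviance = x$null_deviance,
    df = length(x$coefficients),
    iterations = x$iterations,
    converged = x$converged,
    separation = x$separation,
    n = x$n,
    n_events = x$n_events,
    n_dropped = x$n_dropped
  )
}

#' Predicted survival-probability curve over a delay grid
#'
#' Inverse-logit of the fitted linear predictor on the grid, optionally
#' with a pointwise Wald confidence band from the coefficient covariance.
#'
#' @param model A fitted `rcs_logit`.
#' @param grid Numeric vector of delays (seconds); default 200 points over
#'   the observed delay range.
#' @param conf_level Band level; `NULL` suppresses the band. Default 0.95.
#' @return A tibble of class `survival_curve` with `time_s`, `p` and (with
#'   a band) `lower`, `upper`, all probabilities strictly inside (0, 1).
#' @export
predict_curve <- function(model, grid = NULL, conf_level = 0.95) {
  stopifnot(inherits(model, "rcs_logit"))
  if (!model$converged) {
    warn("predicting from a non-converged spline fit")
  }
  if (is.null(grid)) {
    grid <- seq(min(model$data$time_s), max(model$data$time_s),
                length.out = 200)
  }
  if (any(diff(grid) < 0)) grid <- sort(grid)
  X <- cbind(1, rcs_basis(grid, model$knots))
  eta <- drop(X %*% model$coefficients)
  out <- tibble::tibble(time_s = grid, p = plogis(eta))
  if (!is.null(conf_level)) {
    se <- sqrt(pmax(rowSums((X %*% model$vcov) * X), 0))
    zq <- qnorm(1 - (1 - conf_level) / 2)
    out$lower <- plogis(eta - zq * se)
    out$upper <- plogis(eta + zq * se)
  }
  class(out) <- c("survival_curve", class(out))
  out
}

#' Fit and predict a survival-vs-delay curve from a call table
#'
#' Convenience wrapper: extracts one delay column and the 30-day outcome,
#' fits [fit_spline_logistic()] and returns the predicted curve with the
#' model attached as attribute `model`.
#'
#' @param calls A call tibble.
#' @param time_col Delay column name (string).
#' @param k Knot count; default 4.
#' @param ... Passed to [fit_spline_logistic()].
#' @return A `survival_curve` tibble (see [predict_curve()]).
#' @export
survival_delay_curve <- function(calls, time_col, k = 4, ...) {
  check_columns(calls, c(time_col, "survived_30d"), "call table")
  fit <- fit_spline_logistic(calls[[time_col]], calls$survived_30d,
                             k = k, ...)
  curve <- predict_curve(fit)
  attr(curve, "model") <- fit
  curve
}
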