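test_that("the spline basis has the truncated-power structure and linear tails", {
  expect_error(rcs_basis(1:10, c(0, 100)), ">= 3 knots")
  expect_error(rcs_basis(1:10, c(0, 100, 100)), "strictly increasing")

  knots <- c(50, 150, 300, 450)
  below <- rcs_basis(seq(0, 49, by = 1), knots)
  expect_equal(below[, 1], seq(0, 49, by = 1))
  expect_true(all(below[, -1] == 0)) # pure linear left tail

  # hand-computed value: k = 3, knots 0/1/2, nonlinear column at the middle
  # knot is (1 - 0)^3 / (2 - 0)^2 = 0.25
  b <- rcs_basis(1, c(0, 1, 2))
  expect_equal(unname(b[1, 2]), 0.25)

  # second differences of each basis column: continuous across knots,
  # zero (linearity) beyond the boundary knots
  h <- 0.5
  grid <- seq(0, 600, by = h)
  B <- rcs_basis(grid, knots)
  for (j in seq_len(ncol(B))) {
    d2 <- diff(B[, j], differences = 2) / h^2
    expect_lt(max(abs(diff(d2))), 0.01) # no second-derivative jumps
    outside <- grid[-c(1, length(grid))] < knots[1] - h |
      grid[-c(1, length(grid))] > knots[4] + h
    expect_lt(max(abs(d2[outside])), 1e-8)
  }
})

test_that("default knots sit at the conventional quantiles", {
  expect_equal(default_knots(0:100, k = 4), c(5, 35, 65, 95))
  k3 <- default_knots(c(1, 2, 3), k = 3)
  expect_length(k3, 3)
  expect_true(all(diff(k3) > 0))
  expect_error(default_knots(rep(c(1, 2), 50), k = 4), "ties|distinct")
  expect_error(default_knots(1:100, k = 9), "between 3 and 7")
})

test_that("IRLS matches glm on the same basis and recovers a curvature-free truth", {
  set.seed(401)
  n <- 5000
  x <- runif(n, 0, 500)
  truth <- plogis(1 - 0.012 * x)
  y <- runif(n) < truth
  knots <- default_knots(x, 4)
  fit <- fit_spline_logistic(x, y, knots = knots)
  expect_true(fit$converged)

  ref <- glm(y ~ rcs_basis(x, knots), family = binomial())
  expect_equal(fit$deviance, unname(ref$deviance), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)

  # nonlinear terms within 3 SE of zero; linear part recovered
  td <- tidy(fit)
  nonlin <- td[grepl("^x[0-9]", td$term), ]
  expect_true(all(abs(nonlin$estimate) < 3 * nonlin$std.error))
  icpt <- td[td$term == "(Intercept)", ]
  expect_lt(abs(icpt$estimate - 1), 3 * icpt$std.error)
  slope <- td[td$term == "x", ]
  expect_lt(abs(slope$estimate - (-0.012)), 3 * slope$std.error)
})

test_that("tiny-sample deviance matches a brute-force likelihood maximizer", {
  set.seed(77)
  x <- c(20, 35, 60, 80, 120, 150, 200, 260, 320, 400, 450, 500)
  y <- c(1, 1, 0, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  knots <- c(50, 150, 350)
  fit <- fit_spline_logistic(x, y, knots = knots)

  X <- cbind(1, rcs_basis(x, knots))
  nll <- oracle_neg_loglik(X, y)
  opt <- optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  opt <- optim(opt$par, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$deviance, 2 * opt$value, tolerance = 1e-6)

  # local optimum: any perturbed coefficient vector has lower likelihood
  for (j in seq_along(fit$coefficients)) {
    for (eps in c(-1e-3, 1e-3)) {
      beta <- fit$coefficients
      beta[j] <- beta[j] + eps
      expect_gte(2 * nll(beta) + 1e-12, fit$deviance)
    }
  }
})

test_that("degenerate outcomes error and separation is flagged, not fatal", {
  x <- seq(10, 400, length.out = 40)
  expect_error(fit_spline_logistic(x, rep(TRUE, 40)), "non-events")
  expect_error(fit_spline_logistic(x, rep(FALSE, 40)), "no events")

  sep <- fit_spline_logistic(x, x < 100, knots = c(50, 150, 300))
  expect_false(sep$converged)
  expect_true(sep$separation)

  # missing delays are dropped with a count
  fit <- fit_spline_logistic(c(x, NA, NA), c(runif(40) < 0.5, TRUE, FALSE))
  expect_identical(fit$n_dropped, 2L)
  expect_identical(fit$n, 40L)
})

test_that("predicted curves are proper probabilities consistent with the fit", {
  set.seed(402)
  n <- 5000
  x <- runif(n, 0, 600)
  y <- runif(n) < plogis(0.5 - 0.008 * x)
  fit <- fit_spline_logistic(x, y)
  curve <- predict_curve(fit, grid = c(0, 100, 250, 400, 600))
  expect_true(all(curve$p > 0 & curve$p < 1))
  expect_true(all(curve$lower <= curve$p & curve$p <= curve$upper))

  # at a training point the curve equals the fitted probability
  eta <- drop(cbind(1, rcs_basis(250, fit$knots)) %*% fit$coefficients)
  expect_equal(curve$p[curve$time_s == 250], plogis(eta))

  # all-zero coefficients give p = 0.5 everywhere
  flat <- fit
  flat$coefficients[] <- 0
  expect_true(all(predict_curve(flat, grid = c(0, 300))$p == 0.5))

  # monotone-decreasing truth: fitted curve decreasing over the central span
  central <- seq(fit$knots[2], fit$knots[3], length.out = 50)
  pc <- predict_curve(fit, grid = central, conf_level = NULL)
  expect_true(all(diff(pc$p) < 0))

  # linear predictor is linear in x beyond the boundary knots
  right <- predict_curve(fit, grid = seq(max(x) + 50, max(x) + 250, by = 10),
                         conf_level = NULL)
  eta_tail <- qlogis(right$p)
  expect_lt(max(abs(diff(eta_tail, differences = 2))), 1e-9)
})

test_that("survival_delay_curve fits decreasing survival on synthetic cohorts", {
  cohort <- generate_cohort(6000, seed = 5)
  included <- apply_study_exclusions(cohort)$included
  curve <- survival_delay_curve(included, "t_first_compression_s")
  model <- attr(curve, "model")
  expect_true(model$converged)
  delays <- model$data$time_s
  span <- quantile(delays, c(0.25, 0.75))
  grid <- seq(span[1], span[2], length.out = 30)
  pc <- predict_curve(model, grid = grid, conf_level = NULL)
  # decreasing across the IQR: a clear net drop, no substantive local rise
  expect_lt(pc$p[30], 0.95 * pc$p[1])
  expect_true(all(diff(pc$p) < 1e-3))
})
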