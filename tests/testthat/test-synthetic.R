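test_that("the generator is seeded-deterministic and handles n = 0", {
  expect_identical(nrow(generate_cohort(0)), 0L)
  expect_identical(names(generate_cohort(0)), call_columns())

  a <- generate_cohort(300, seed = 42)
  b <- generate_cohort(300, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(300, seed = 43)
  expect_false(identical(a, c))
})

test_that("generated cohorts satisfy every schema invariant", {
  for (seed in 1:3) {
    expect_identical(nrow(validate_calls(generate_cohort(500, seed = seed))),
                     0L)
  }
})

test_that("log-normal calibration hits exact symmetric cases and plugs back", {
  z <- qnorm(0.75)
  sym <- calibrate_lognormal(100, exp(-z * 0.5) * 100, exp(z * 0.5) * 100)
  expect_equal(unname(sym), c(log(100), 0.5), tolerance = 1e-12)

  for (triple in list(c(113, 62, 204), c(88, 64, 131), c(240, 176, 332))) {
    par <- calibrate_lognormal(triple[1], triple[2], triple[3])
    expect_equal(unname(par["mu"]), log(triple[1]))
    expect_gt(par["sigma"], 0)
    # analytic quartiles of the calibrated distribution within 10%
    q <- qlnorm(c(0.25, 0.75), par["mu"], par["sigma"])
    expect_equal(q[1], triple[2], tolerance = 0.1)
    expect_equal(q[2], triple[3], tolerance = 0.1)
  }
  expect_error(calibrate_lognormal(100, 120, 200), "q1 < median")
})

test_that("the generator recovers its configured parameters at scale", {
  n <- 20000
  cohort <- generate_cohort(n, seed = 123)
  st <- stage_cohorts_for_tests(cohort)
  par <- cohort_params()

  within_3se <- function(phat, p, m) {
    se <- sqrt(p * (1 - p) / m)
    abs(phat - p) <= 3 * se
  }
  expect_true(within_3se(mean(cohort$alive_during_call),
                         par$stage$p_alive_during_call, n))
  expect_true(within_3se(1 - mean(cohort$audio_available),
                         par$stage$p_missing_audio, n))
  phat_rec <- mean(st$recognizable$recognized)
  expect_true(within_3se(phat_rec, 645 / 760, nrow(st$recognizable)))
  expect_lt(abs(100 * phat_rec - 84.9), 2) # within 2 percentage points
  expect_true(within_3se(mean(st$dacpr_available$dacpr_compressions_given),
                         343 / 560, nrow(st$dacpr_available)))

  # barrier frequencies among included calls
  inc <- apply_study_exclusions(cohort)$included
  expect_true(within_3se(mean(inc$cpr_in_progress), 97 / 936, nrow(inc)))
  expect_true(within_3se(mean(inc$recognizability_barrier == "THIRD_PARTY"),
                         23 / 936, nrow(inc)))

  # overall survival within one percentage point of the configured target
  surv <- mean(inc$survived_30d, na.rm = TRUE)
  expect_lt(abs(surv - 66 / 936), 0.01)

  # time medians within 5% of the configured targets, per stage stratum
  med <- function(x) median(x, na.rm = TRUE)
  expect_equal(med(st$recognizable$t_recognition_s), 113, tolerance = 0.05)
  expect_equal(med(cohort$t_dispatch_s), 88, tolerance = 0.05)
  given <- st$dacpr_available[st$dacpr_available$dacpr_compressions_given, ]
  expect_equal(med(given$t_cpr_instruction_s), 201, tolerance = 0.05)
  expect_equal(med(given$t_first_dacpr_compression_s), 240, tolerance = 0.05)
  comp <- st$dacpr_available[
    !is.na(st$dacpr_available$any_compression_during_call) &
      st$dacpr_available$any_compression_during_call, ]
  expect_equal(med(comp$t_first_compression_s), 214, tolerance = 0.05)

  # configured missingness reproduced (recognition time, survival)
  n_rec <- sum(st$recognizable$recognized)
  miss_rec <- sum(st$recognizable$recognized &
                    is.na(st$recognizable$t_recognition_s))
  expect_true(within_3se(miss_rec / n_rec, 117 / 645, n_rec))
  expect_true(within_3se(mean(is.na(inc$survived_30d)), 47 / 936, nrow(inc)))
})

test_that("generated survival decreases stochastically with compression delay", {
  cohort <- generate_cohort(20000, seed = 55)
  inc <- apply_study_exclusions(cohort)$included
  comp <- inc[!is.na(inc$t_first_compression_s) & !is.na(inc$survived_30d), ]
  qs <- quantile(comp$t_first_compression_s, c(0.25, 0.75))
  early <- comp$survived_30d[comp$t_first_compression_s <= qs[1]]
  late <- comp$survived_30d[comp$t_first_compression_s >= qs[2]]
  expect_gt(mean(early), mean(late))
})

test_that("event-chain ordering holds in every generated record", {
  cohort <- generate_cohort(5000, seed = 77)
  both <- !is.na(cohort$t_cpr_instruction_s) &
    !is.na(cohort$t_first_dacpr_compression_s)
  expect_true(all(cohort$t_first_dacpr_compression_s[both] >=
                    cohort$t_cpr_instruction_s[both]))
  rec_ins <- !is.na(cohort$t_recognition_s) &
    !is.na(cohort$t_cpr_instruction_s)
  expect_true(all(cohort$t_cpr_instruction_s[rec_ins] >=
                    cohort$t_recognition_s[rec_ins]))
  first_dacpr <- !is.na(cohort$t_first_compression_s) &
    !is.na(cohort$t_first_dacpr_compression_s)
  expect_true(all(cohort$t_first_compression_s[first_dacpr] <=
                    cohort$t_first_dacpr_compression_s[first_dacpr]))
})

test_that("the reference cohort is valid and reproduces the audit's marginal counts", {
  rc <- reference_cohort()
  expect_identical(nrow(rc), 1000L)
  expect_identical(nrow(validate_calls(rc)), 0L)
  inc <- apply_study_exclusions(rc)$included
  expect_identical(sum(inc$dacpr_compressions_given), 343L)
  expect_identical(sum(inc$any_compression_during_call, na.rm = TRUE),
                   504L + 97L) # available-cohort 504 plus CPR-in-progress
  expect_identical(sum(inc$survived_30d, na.rm = TRUE), 66L)
  expect_identical(sum(is.na(inc$survived_30d)), 47L)
  expect_identical(sum(inc$witnessed, na.rm = TRUE), 531L)
  expect_identical(sum(inc$location == "RESIDENTIAL", na.rm = TRUE), 677L)
  expect_identical(sum(inc$cause == "CARDIAC", na.rm = TRUE), 512L)
  expect_identical(sum(is.na(inc$cause)), 57L)
})
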