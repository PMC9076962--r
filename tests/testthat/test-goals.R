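test_that("median_iqr follows the midpoint/type-7 conventions", {
  expect_equal(median_iqr(5), tibble::tibble(median_s = 5, q1_s = 5,
                                             q3_s = 5, n = 1L))
  m <- median_iqr(c(1, 2, 3, 4))
  expect_equal(c(m$median_s, m$q1_s, m$q3_s), c(2.5, 1.75, 3.25))
  expect_error(median_iqr(numeric()), "at least one")
  expect_error(median_iqr(c(1, NA)), "finite")

  for (seed in 1:5) {
    x <- withr::with_seed(seed, rlnorm(1 + seed * 7, 5, 0.9))
    m <- median_iqr(x)
    expect_equal(m$median_s, oracle_quantile(x, 0.5))
    expect_equal(m$q1_s, oracle_quantile(x, 0.25))
    expect_equal(m$q3_s, oracle_quantile(x, 0.75))
  }
})

test_that("rounding is half away from zero and reproduces printed percentage pairs", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.4, -0.5)), c(1, 2, 2, -1))
  printed <- list(
    c(742, 936, 79), c(645, 760, 85), c(343, 560, 61), c(504, 560, 90),
    c(150, 760, 20), c(267, 760, 35), c(154, 760, 20), c(386, 760, 51),
    c(31, 560, 6), c(109, 560, 19), c(9, 560, 2), c(52, 560, 9),
    c(117, 760, 15), c(136, 560, 24), c(40, 560, 7), c(7, 560, 1),
    c(66, 936, 7), c(318, 936, 34), c(550, 936, 59), c(531, 936, 57),
    c(677, 936, 72), c(170, 936, 18), c(97, 936, 10), c(488, 936, 52)
  )
  for (p in printed) {
    expect_equal(round_half_up(100 * p[1] / p[2]), p[3],
                 label = sprintf("%d/%d", p[1], p[2]))
  }
})

test_that("proportion goals count correctly, including degenerate cohorts", {
  inc <- call_tbl(936, recognized = c(rep(TRUE, 742), rep(FALSE, 194)))
  g1 <- goal1_recognition(inc)
  expect_identical(g1$numerator, 742L)
  expect_identical(g1$pct_rounded, 79L)
  expect_true(g1$met)

  none <- goal1_recognition(call_tbl(50, recognized = FALSE))
  expect_identical(none$pct, 0)
  expect_false(none$met)

  empty <- goal2_recognizable_recognition(call_tbl(1)[0, ])
  expect_true(empty$undefined)
  expect_false(empty$met)
  expect_true(is.na(empty$pct))

  all_rec <- goal2_recognizable_recognition(call_tbl(10, recognized = TRUE))
  expect_identical(all_rec$pct, 100)
  expect_true(all_rec$met)

  g3 <- goal3_dacpr_delivery(call_tbl(560,
    recognized = TRUE,
    dacpr_compressions_given = c(rep(TRUE, 343), rep(FALSE, 217)),
    any_compression_during_call = c(rep(TRUE, 504), rep(FALSE, 56))
  ))
  expect_identical(g3$pct_rounded, c(61L, 90L))
  expect_equal(g3$met, c(FALSE, FALSE)) # companion row is descriptive

  # recount oracle on random cohorts
  for (seed in 1:4) {
    cohort <- generate_cohort(300, seed = seed)
    st <- apply_study_exclusions(cohort)$included
    expect_identical(goal1_recognition(st)$numerator,
                     as.integer(oracle_count_true(st$recognized)))
  }
})

test_that("time metrics use strict thresholds and full-cohort attainment denominators", {
  flat <- call_tbl(10, recognized = TRUE, t_recognition_s = 60)
  tm <- time_metric(flat, "t_recognition_s", c(30, 60, 90),
                    applicable = rep(TRUE, 10))
  expect_equal(tm$median_s, 60)
  expect_equal(tm$q1_s, 60)
  expect_equal(tm$q3_s, 60)
  att <- tm$attainment[[1]]
  expect_equal(att$n, c(0L, 0L, 10L)) # strict "<": exactly 60 fails <= 60

  # 10 calls, 4 with time < 60, 3 time-missing: pct denominator is all 10
  part <- call_tbl(10, recognized = TRUE,
                   t_recognition_s = c(10, 20, 30, 40, 70, 80, 90, NA, NA, NA))
  tm <- time_metric(part, "t_recognition_s", 60)
  expect_identical(tm$n_missing, 3L)
  expect_identical(tm$n_with_time, 7L)
  att <- tm$attainment[[1]]
  expect_identical(att$n, 4L)
  expect_equal(att$pct, 40)

  # attainment monotone in threshold, counts equal a loop oracle
  for (seed in 1:4) {
    cohort <- generate_cohort(400, seed = seed)
    st <- stage_cohorts_for_tests(cohort)
    tm <- goal4_times(st$recognizable)
    for (i in seq_len(nrow(tm))) {
      att <- tm$attainment[[i]]
      expect_true(all(diff(att$n) >= 0))
      col <- c(recognition = "t_recognition_s",
               dispatch = "t_dispatch_s")[[tm$variable[i]]]
      for (j in seq_len(nrow(att))) {
        expect_identical(att$n[j],
                         as.integer(oracle_count_below(
                           st$recognizable[[col]], att$threshold_s[j])))
      }
    }
  }
})

test_that("goal-4/5 metrics on the reference cohort reproduce the audit table", {
  st <- stage_cohorts_for_tests(reference_cohort())
  g4 <- goal4_times(st$recognizable)
  rec <- g4[g4$variable == "recognition", ]
  expect_identical(rec$n_missing, 117L)
  expect_identical(rec$n_with_time, 528L)
  expect_identical(rec$attainment[[1]]$n, c(150L, 267L))
  expect_identical(rec$attainment[[1]]$pct_rounded, c(20L, 35L))
  disp <- g4[g4$variable == "dispatch", ]
  expect_identical(disp$attainment[[1]]$pct_rounded, c(20L, 51L))

  g5 <- goal5_times(st$dacpr_available)
  any <- g5[g5$variable == "any_compression", ]
  expect_identical(any$n_missing, 136L)
  expect_identical(any$attainment[[1]]$n, c(31L, 109L))
  expect_identical(any$attainment[[1]]$pct_rounded, c(6L, 19L))
  dac <- g5[g5$variable == "dacpr_compression", ]
  expect_identical(dac$n_missing, 40L)
  expect_identical(dac$attainment[[1]]$n, c(9L, 52L))
  ins <- g5[g5$variable == "cpr_instruction", ]
  expect_identical(ins$n_missing, 7L)
})

test_that("percentages are permutation invariant", {
  cohort <- generate_cohort(500, seed = 9)
  perm <- withr::with_seed(1, sample.int(nrow(cohort)))
  st1 <- stage_cohorts_for_tests(cohort)
  st2 <- stage_cohorts_for_tests(cohort[perm, ])
  expect_equal(goal1_recognition(st1$included)$pct,
               goal1_recognition(st2$included)$pct)
  tm1 <- goal5_times(st1$dacpr_available)
  tm2 <- goal5_times(st2$dacpr_available)
  expect_equal(tm1$median_s, tm2$median_s)
  expect_equal(tm1$attainment, tm2$attainment)
})

test_that("median benchmarks apply the strict AHA thresholds", {
  v <- benchmark_medians(tibble::tibble(
    goal_id = c(4, 4, 5, 4),
    variable = c("recognition", "dispatch", "dacpr_compression", "boundary"),
    median_s = c(113, 87, 240, 90)
  ))
  expect_equal(v$met_high, c(FALSE, FALSE, FALSE, FALSE))
  # dispatch meets only the minimal standard; a median exactly at the
  # 90 s threshold does not meet it (strict "<")
  expect_equal(v$met_minimal, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("benchmarks can be overridden from YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "goal2:", "  target_pct: 80",
    "goal4:", "  high_perf_s: 45", "  minimal_std_s: 75"
  ), path)
  bm <- benchmarks_from_yaml(path)
  expect_equal(bm$target_pct[bm$goal_id == 2], 80)
  expect_equal(bm$high_perf_s[bm$goal_id == 4], 45)
  expect_equal(bm$target_pct[bm$goal_id == 1], 75) # untouched default

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("goal5:", "  high_perf_s: 200"), bad)
  expect_error(benchmarks_from_yaml(bad), "below")

  g2 <- benchmark_proportions(
    goal2_recognizable_recognition(call_tbl(100, recognized =
      c(rep(TRUE, 85), rep(FALSE, 15)))), bm)
  expect_true(g2$met) # 85% meets the relaxed 80% target
})
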