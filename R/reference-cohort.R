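# Deterministic 1000-call reference cohort whose categorical structure
# reproduces, exactly, the count cascade of a national dispatch audit
# (1000 audited calls; 35 alive during call + 29 missing audio -> 936
# included; barriers 97/23/10/9/4/33 -> 760 recognizable; 645 recognized of
# 760 plus the 97 CPR-in-progress calls -> 742 recognized overall; DA-CPR
# barriers 49/13/5/5/13 -> 560 available; 343 directed compressions; 504
# any compression; 66 survivors of 936 with 47 unknown). Event times are
# filled deterministically from log-normal quantiles within fixed
# threshold bins so attainment counts are exact and medians land near the
# audit's values; the times are structural scaffolding, not a statistical
# sample.

# quantile-spaced values of a log-normal within threshold bins:
# counts[i] values in [breaks[i], breaks[i+1])
bin_quantile_fill <- function(counts, breaks, triple) {
  par <- calibrate_lognormal(triple[["median"]], triple[["q1"]],
                             triple[["q3"]])
  out <- numeric(0)
  for (i in seq_along(counts)) {
    m <- counts[i]
    if (m == 0) next
    p_lo <- plnorm(breaks[i], par[["mu"]], par[["sigma"]])
    p_hi <- plnorm(breaks[i + 1], par[["mu"]], par[["sigma"]])
    p <- p_lo + (seq_len(m) - 0.5) / m * (p_hi - p_lo)
    out <- c(out, qlnorm(p, par[["mu"]], par[["sigma"]]))
  }
  out
}

# evenly spaced quantiles of the whole distribution
grid_quantile_fill <- function(m, triple) {
  par <- calibrate_lognormal(triple[["median"]], triple[["q1"]],
                             triple[["q3"]])
  qlnorm((seq_len(m) - 0.5) / m, par[["mu"]], par[["sigma"]])
}

# expand named level counts into a vector; the count named ".na" becomes
# trailing missing values
fill_levels <- function(counts, convert = identity) {
  keep <- names(counts) != ".na"
  lv <- rep(names(counts)[keep], times = counts[keep])
  n_na <- if (any(!keep)) counts[[".na"]] else 0
  c(convert(lv), rep(NA, n_na))
}

as_bool_levels <- function(x) x == "TRUE"

#' Deterministic reference audit cohort
#'
#' A fixed 1000-call cohort that reproduces a national audit's cohort
#' cascade and goal counts exactly: 936 included, 760 recognizable, 742
#' recognized overall (645 of the recognizable stratum), 560 available for
#' DA-CPR, 343 directed and 504 any compressions, threshold-attainment
#' counts (150 recognitions < 60 s, 386 dispatches < 90 s, 109 compressions
#' < 150 s, ...) and 66 survivors of 936. Useful as a pipeline fixture and
#' as the worked example for the goal metrics. Event times are filled from
#' log-normal quantiles inside fixed attainment bins: counts and rounded
#' percentages are exact, medians only approximate.
#'
#' @return A call tibble of 1000 rows, valid under [validate_calls()].
#' @examples
#' build_cascade_report(reference_cohort())
#' @export
reference_cohort <- function() {
  n <- 1000
  n_inc <- 936
  calls <- empty_call_table()[rep(1, n), ]
  calls$call_id <- sprintf("R%04d", seq_len(n))

  calls$alive_during_call <- c(rep(TRUE, 35), rep(FALSE, n - 35))
  calls$audio_available <- c(rep(TRUE, 35), rep(FALSE, 29),
                             rep(TRUE, n - 64))
  inc <- 65:1000  # the 936 included calls

  # recognizability status within the included cohort
  status <- rep("NONE", n_inc)
  status[1:97] <- "CPR_IN_PROGRESS"
  status[98:120] <- "THIRD_PARTY"
  status[121:130] <- "HYSTERICAL"
  status[131:139] <- "HANG_UP"
  status[140:143] <- "LANGUAGE"
  status[144:176] <- "OTHER"
  calls$cpr_in_progress <- FALSE
  calls$cpr_in_progress[inc] <- status == "CPR_IN_PROGRESS"
  calls$recognizability_barrier <- "NONE"
  calls$recognizability_barrier[inc] <-
    ifelse(status %in% c("CPR_IN_PROGRESS", "NONE"), "NONE", status)

  # recognized: all 97 CPR-in-progress calls plus 645 of the 760
  # recognizable (j 177..821) -> 742 overall
  recog <- rep(FALSE, n_inc)
  recog[1:97] <- TRUE
  recog[177:821] <- TRUE
  calls$recognized <- FALSE
  calls$recognized[inc] <- recog

  # DA-CPR barriers among the 645 recognized recognizable calls
  dacpr_b <- rep("NONE", n_inc)
  rr <- 177:821  # recognized recognizable, local i = 1..645
  dacpr_b[rr[1:49]] <- "CANNOT_MOVE"
  dacpr_b[rr[50:62]] <- "REFUSES"
  dacpr_b[rr[63:67]] <- "HANG_UP"
  dacpr_b[rr[68:72]] <- "NOT_WITH_PATIENT"
  dacpr_b[rr[73:85]] <- "OTHER"
  calls$dacpr_barrier <- "NONE"
  calls$dacpr_barrier[inc] <- dacpr_b

  avail <- rr[86:645]  # 560 available, local a = 1..560
  given <- rep(FALSE, n_inc)
  given[avail[1:343]] <- TRUE
  calls$dacpr_compressions_given <- FALSE
  calls$dacpr_compressions_given[inc] <- given

  anyc <- rep(FALSE, n_inc)
  anyc[avail[1:504]] <- TRUE          # 343 directed + 161 spontaneous
  anyc[1:97] <- TRUE                  # CPR already in progress
  calls$any_compression_during_call <- NA
  calls$any_compression_during_call[inc] <- anyc

  tm <- cohort_params()$time_models

  # recognition: 528 of the 645 recognized recognizable calls with time
  # (150 < 60 s, 117 in [60, 90), 261 >= 90), 117 missing; the 97
  # CPR-in-progress recognized calls get plain quantile-grid times
  t_rec <- rep(NA_real_, n_inc)
  t_rec[rr[1:528]] <- bin_quantile_fill(c(150, 117, 261), c(0, 60, 90, Inf),
                                        tm$recognition)
  t_rec[1:97] <- grid_quantile_fill(97, tm$recognition)
  calls$t_recognition_s <- NA_real_
  calls$t_recognition_s[inc] <- t_rec

  # dispatch: recognizable calls binned (154 < 60 s, 232 in [60, 90),
  # 374 >= 90); everyone else on the plain quantile grid
  t_disp <- rep(NA_real_, n_inc)
  t_disp[177:936] <- bin_quantile_fill(c(154, 232, 374), c(0, 60, 90, Inf),
                                       tm$dispatch)
  t_disp[1:176] <- grid_quantile_fill(176, tm$dispatch)
  calls$t_dispatch_s <- NA_real_
  calls$t_dispatch_s[inc] <- t_disp
  calls$t_dispatch_s[1:64] <- grid_quantile_fill(64, tm$dispatch)

  # CPR instructions: 336 of 343 directed calls with time, 7 missing
  t_ins <- rep(NA_real_, n_inc)
  t_ins[avail[1:336]] <- grid_quantile_fill(336, tm$instruction)
  calls$t_cpr_instruction_s <- NA_real_
  calls$t_cpr_instruction_s[inc] <- t_ins

  # first DA-CPR compression: 303 of 343 with time (9 < 90 s, 43 in
  # [90, 150), 251 >= 150), 40 missing
  t_dac <- rep(NA_real_, n_inc)
  t_dac[avail[1:303]] <- bin_quantile_fill(c(9, 43, 251), c(0, 90, 150, Inf),
                                           tm$dacpr_compression)
  calls$t_first_dacpr_compression_s <- NA_real_
  calls$t_first_dacpr_compression_s[inc] <- t_dac

  # first compression by anyone: 368 of the 504 compression calls with
  # time (31 < 90 s, 78 in [90, 150), 259 >= 150), 136 missing; the
  # CPR-in-progress calls get small early times
  t_any <- rep(NA_real_, n_inc)
  t_any[avail[1:368]] <- bin_quantile_fill(c(31, 78, 259), c(0, 90, 150, Inf),
                                           tm$any_compression)
  t_any[1:97] <- (seq_len(97) - 0.5) / 97 * 30
  calls$t_first_compression_s <- NA_real_
  calls$t_first_compression_s[inc] <- t_any

  # survival: 66 survivors of 936 (47 unknown), survivors placed among the
  # calls with the earliest effective delay so survival decays with delay
  delay <- ifelse(anyc & !is.na(t_any), t_any, 600 + seq_len(n_inc))
  rk <- rank(delay, ties.method = "first")
  surv <- rep(FALSE, n_inc)
  surv[rk %in% seq(1, by = 3, length.out = 66)] <- TRUE
  surv[rk >= n_inc - 46] <- NA
  calls$survived_30d <- NA
  calls$survived_30d[inc] <- surv

  # covariates at the audit's marginal counts, assigned through a fixed
  # stride permutation so they are not aligned with the cascade ordering
  perm <- order((seq_len(n_inc) * 617) %% n_inc)
  put <- function(col, values) {
    calls[[col]][inc] <<- values[perm]
  }
  calls$patient_age <- NA_real_
  put("patient_age", round(qnorm((seq_len(n_inc) - 0.5) / n_inc, 72,
                                 (81 - 61) / (2 * qnorm(0.75)))))
  put("patient_sex", fill_levels(c(FEMALE = 318, MALE = 611, .na = 7)))
  put("caller_sex", fill_levels(c(FEMALE = 550, MALE = 356, .na = 30)))
  put("caller_alone",
      fill_levels(c(`TRUE` = 348, `FALSE` = 543, .na = 45), as_bool_levels))
  put("caller_hcp",
      fill_levels(c(`TRUE` = 259, `FALSE` = 643, .na = 34), as_bool_levels))
  put("caller_knows_victim",
      fill_levels(c(`TRUE` = 780, `FALSE` = 121, .na = 35), as_bool_levels))
  put("location", fill_levels(c(RESIDENTIAL = 677, PUBLIC = 176, OTHER = 79,
                                .na = 4)))
  put("witnessed",
      fill_levels(c(`TRUE` = 531, `FALSE` = 376, .na = 29), as_bool_levels))
  put("cause", fill_levels(c(CARDIAC = 512, OVERDOSE = 21, TRAUMA = 19,
                             RESPIRATORY = 46, ASPHYXIA = 28, SUICIDE = 38,
                             SUBMERSION = 19, SIDS = 7, OTHER = 189,
                             .na = 57)))
  put("shockable_rhythm",
      fill_levels(c(`TRUE` = 170, `FALSE` = 754, .na = 12), as_bool_levels))
  put("aed_addressed",
      fill_levels(c(`TRUE` = 68, `FALSE` = 786, .na = 82), as_bool_levels))
  put("call_continued_until_ems",
      fill_levels(c(`TRUE` = 488, `FALSE` = 347, .na = 101), as_bool_levels))

  calls[call_columns()]
}
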