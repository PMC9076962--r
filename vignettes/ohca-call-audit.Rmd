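---
title: "Auditing OHCA emergency-call handling against the AHA DA-CPR goals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing OHCA emergency-call handling against the AHA DA-CPR goals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcaudit)
```

## The problem

When a bystander calls the emergency number about an out-of-hospital
cardiac arrest (OHCA), the dispatcher's handling of the call is itself a
clinical intervention: recognizing the arrest, dispatching an ambulance,
and talking the caller through chest compressions (dispatcher-assisted
CPR, DA-CPR) all happen minutes before any professional reaches the
patient, and each minute of delay costs survival. The American Heart
Association (AHA) states five performance goals for this work:

1. proportion of all OHCA calls recognized by the dispatcher — goal 75%;
2. proportion recognized among *recognizable* calls (excluding calls a
   dispatcher could not plausibly identify: CPR already in progress,
   third-party callers, hysterical callers, hang-ups, language barriers,
   other barriers) — goal 95%;
3. proportion of recognized OHCA receiving DA-CPR — goal 75%;
4. median time from call answer to recognition and to EMS dispatch —
   under 60 s for a high-performance system, under 90 s as the minimal
   acceptable standard;
5. median time from call answer to the first DA-CPR-directed chest
   compression — under 90 s (high performance) or 150 s (minimal).

`ohcaudit` implements a complete, tested audit pipeline for these goals on
a per-call table (one row per emergency call, event times in seconds from
call answer), together with a counterfactual *additional survivors*
estimator and smooth survival-versus-delay curves. Because registry and
voice-log data of this kind cannot be shared, the package also ships a
seeded synthetic cohort generator with the statistical structure of a
national audit sample, so every stage of the pipeline is testable and
demonstrable without any data access.

## The exclusion cascade

The audit cohort is built in three stages, each with per-reason exclusion
accounting. Study-level exclusions remove calls where the patient was
alive during the call, then calls with no voice log. The AHA
recognizability filter removes barrier calls (CPR in progress is checked
before the recorded barrier, so each call counts exactly once). The DA-CPR
availability filter removes recognized calls with a caller-side barrier
(caller cannot move the patient, refuses, hangs up, is not with the
patient, other). Conservation holds at every stage by construction:
included plus excluded-by-reason equals the stage input, which the test
suite verifies on arbitrary generated cohorts.

```{r cascade}
calls <- reference_cohort()
build_cascade_report(calls)
```

Two recognition counts coexist deliberately. The whole-cohort count (742
above) is goal 1's numerator; the within-recognizable count (645) is goal
2's numerator and feeds the availability stage. Audit tables sometimes
print one under a heading suggesting the other, so the report labels both
explicitly.

The `reference_cohort()` used above is a deterministic 1000-call fixture
whose categorical structure (stage counts, barrier counts, compression
and survival counts, threshold-attainment counts) is internally
consistent and fixed; its event times are filled from log-normal
quantiles inside the attainment bins, so counts and rounded percentages
are exact while medians are only approximate. It is scaffolding for
demonstrations and end-to-end tests, not a statistical sample.

## Goal metrics and conventions

```{r goals}
report <- run_audit(calls)
glance(report)
```

Several small conventions matter because printed audit tables depend on
them; each is surfaced rather than buried:

* **Quartiles** are type 7 (linear interpolation of order statistics),
  the most common convention and R's default; the midpoint convention is
  used for the median of an even count. No published audit states its
  quartile rule, and medians from unavailable raw data cannot be
  recomputed anyway, so the choice is about internal consistency.
* **Threshold attainment** uses strict `<` (the AHA wording is "< 60 s"),
  and its percentage denominator is the *full stage cohort including
  calls with missing times* — that is how audit tables report it (e.g.
  150 recognitions under 60 s among 760 recognizable calls is printed as
  20% even though 117 of the 760 have no recognition time). Counts of
  missing times are always reported alongside.
* **Missing times for the median** are excluded: a recognition time
  exists only for recognized calls, so the median is over calls with the
  event observed, with the missing count reported.
* **Rounding** of reported percentages is half away from zero to whole
  percent, which reproduces every printed numerator/denominator pair in
  the audit tables this package mirrors; raw percentages are retained in
  every result object.
* **Benchmark verdicts** for the time goals are strict: a median of
  exactly 90 s does not meet a "< 90 s" standard.

```{r verdicts}
report$verdicts
```

## The additional-survivors estimator

For a delay target (say, recognition under 60 s), the cohort splits into a
target-meeting stratum (time observed and strictly below the threshold)
and a target-missing stratum (everything else — a call with no observed
event cannot have met the target). The estimator is

\[
\text{raw} = (p_{\text{met}} - p_{\text{not met}}) \times n_{\text{not met}},
\]

the expected number of extra 30-day survivors if every target-missing
patient had instead experienced the target-meeting stratum's survival
rate. Survival proportions are computed over calls with a known 30-day
outcome; \(n_{\text{not met}}\) counts the whole target-missing stratum
including unknown outcomes, because the multiplier counts patients. The
headline integer is the *floor* of the raw value, not its rounding — the
convention under which all published worked examples of this estimator
reproduce exactly (one of them prints a product of 10.59 as 10 lives). A
negative raw estimate is reported as zero additional lives with a flag,
since "additional lives" is non-negative by construction.

```{r lives}
run_lives_saved(rates = lives_saved_input(
  p_met = c(0.1052, 0.08556, 0.20),
  p_not_met = c(0.07056, 0.07142, 0.0615),
  n_not_met = c(727, 749, 530)
))
```

The explicit-rates mode exists because published stratum rates are
printed even where raw data are not shared; cohort mode
(`run_lives_saved(calls)`) computes the same table from a call table, and
the test suite verifies that the two routes agree with an independent
two-pass recount. `extrapolate_national()` scales an estimate to a
national annual case load; it is reported unrounded and labelled an
approximation — published national figures of this kind are ambiguous
about their own scaling convention, so the package takes no position and
sets no target on them. The estimator itself is deliberately crude: it
adjusts for nothing (initial rhythm, age, witnessed status), carries no
confidence interval, and should be read as a planning-scale figure, not a
causal effect.

## Survival probability as a function of delay

The probability of 30-day survival against a delay variable is modelled
by logistic regression on a restricted cubic spline (RCS) basis of the
delay: piecewise cubic between knots, constrained to be linear beyond the
boundary knots, with continuous value, first and second derivatives.
The basis is Harrell's truncated-power construction with nonlinear terms
normalized by the squared boundary-knot span; the fitter is iteratively
reweighted least squares on the Bernoulli log-likelihood, converging on a
relative deviance change below 1e-8 (100-iteration cap; apparent complete
separation — fitted log-odds diverging — returns a flagged non-converged
result rather than an error).

Defaults, chosen where no published convention exists: **4 knots** at the
conventional quantile positions (0.05, 0.35, 0.65, 0.95), configurable
from 3 to 7 — four knots is the standard compromise between flexibility
and stability for cohorts in the hundreds-to-thousands range. Calls with
a missing delay or outcome carry no information about the curve and are
dropped with a reported count. Confidence bands are pointwise Wald bands
from the coefficient covariance; they are optional and make no
simultaneous-coverage claim.

```{r spline, fig.width = 6, fig.height = 4}
cohort <- generate_cohort(6000, seed = 5)
included <- apply_study_exclusions(cohort)$included
curve <- survival_delay_curve(included, "t_first_compression_s")
glance(attr(curve, "model"))
autoplot(curve)
```

The test suite pins this module down from several directions: the fitted
deviance matches `stats::glm` on the identical basis and a brute-force
Nelder–Mead/BFGS maximization of the same likelihood (to 1e-6) on small
data; on curvature-free simulated truth the nonlinear coefficients are
statistically zero; second differences of the basis vanish beyond the
boundary knots (linear tails) and show no second-derivative jumps at the
knots.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` samples, in generative order: study-exclusion flags;
a recognizability status (categorical over CPR-in-progress, the five
barrier classes, and none, at the audit's frequencies); recognition
(probability 645/760 for recognizable calls); DA-CPR barriers and
delivery; event times; survival; covariates; and missingness masks, all
at rates matching a 1000-call audit's published tables. Design choices a
user should know:

* **Event times are log-normal**, matched by quartiles to published
  median [IQR] triples (`calibrate_lognormal()`): positive support and
  right skew match the strong median-much-below-q3 asymmetry of dispatch
  audit times. Only median and quartiles are published, so only those are
  matched.
* **The event chain shares one latent severity quantile per call**
  (comonotone coupling of recognition, instruction and compression
  times). Coupling preserves each marginal exactly while keeping the
  chain ordered; the rare tail crossings that remain (the spreads differ
  across variables) are clamped to the preceding event plus one second,
  touching only the far upper tail. The alternative — resampling the
  later event until it follows the earlier one — would have inflated the
  later event's marginal median far outside the generator's own recovery
  tolerances, because the published medians of consecutive events are
  close relative to their spreads. The cost is perfect rank correlation
  between event times within a call, which is stronger than reality.
* **Recognition outside the recognizable stratum**: whole-cohort and
  within-recognizable recognition counts imply that the barrier calls
  recognized anyway are, numerically, exactly the CPR-in-progress calls —
  which makes clinical sense (ongoing compressions make the arrest
  obvious). The generator therefore recognizes CPR-in-progress calls with
  probability 1 and other barrier calls with probability 0.
* **Survival is a single-covariate logistic** in time to first
  compression (slope −0.004 per second, roughly a one-third drop in odds
  per 100 s), with calls that never receive compressions assigned a fixed
  late effective delay of 600 s; the intercept is root-found at
  generation time so the included cohort's overall 30-day survival hits
  the 7.05% target. Published audits of this kind fit no richer survival
  model, so neither does the generator.
* **Covariates are independent marginals** (Table-1-style frequencies);
  joint structure (witnessed × location, age × rhythm) is deliberately
  not emulated.

Consequently, passing tests demonstrate that the *pipeline* is correct —
counts, conservation, stratified rates, spline optimum, parameter
recovery — not that real dispatch data look like the generator. Effects
that live in the joint structure of real registries (confounding of delay
with witnessed status or rhythm, informative missingness, inter-centre
heterogeneity) are outside what this synthetic cohort can exhibit.

The generator's recovery properties are tested at a cohort size of
20 000: every configured proportion within three binomial standard
errors, every time median within 5% in its stage stratum, overall
survival within one percentage point. Property tests over random cohorts
use sizes of 300–1500; the spline demonstrations use 5000–6000. These
sizes keep the whole suite fast while leaving Monte-Carlo noise well
inside the asserted tolerances.

## Numerical and degenerate-input choices

* Percentages with a zero denominator are `NA` and flagged `undefined`,
  never `NaN`; an empty cohort is an explicit error in `run_audit()`.
* A stratum with no known survival outcomes is an error naming the
  stratum (the estimator cannot be formed), not a silent `NaN`.
* IRLS weights are floored at 1e-10; fitted log-odds are clamped at ±30
  for deviance evaluation, and exceeding that range triggers the
  separation flag.
* Knot placement errors out when quantile ties collapse knots, advising
  fewer knots, rather than silently de-duplicating.
* Unknown enumeration labels on CSV read are an error: audit data must
  not be silently reclassified into `OTHER`.
* `read_call_table()`/`write_call_table()` round-trip bit-exactly, with
  missing values as empty cells (`NA` accepted on read).

## Known limitations

The estimator is unadjusted and interval-free by design; the spline
curves describe association, not cause — both inherit every confounder
the audit design leaves uncontrolled. The reference cohort's medians are
approximate by construction (its attainment counts are exact, and the two
constraints cannot both hold in a 1000-call deterministic table). The
generator's comonotone event chain overstates within-call correlation,
and registry-level exclusions upstream of an audit sample (cases not yet
available, EMS-witnessed arrests, other dispatch organizations) are out
of scope: they happen before any call table this package sees.
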