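---
title: "Calibrating an automated bone age predictor to a local population"
author: "boneagecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an automated bone age predictor to a local population}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bone age (BA) — skeletal maturity read from the ossification of the hand
and wrist, expressed in months — is assessed manually with the
Greulich–Pyle atlas or automatically by deep-learning predictors. Because
maturation timing differs between populations, an automated predictor
trained on one population can systematically over- or under-estimate BA
in another. `boneagecal` implements the statistical machinery for
validating such a predictor against a local multi-rater reference and,
when a systematic miscalibration is found, removing it with a
sex-specific linear map — without touching the predictor itself.

The pipeline has five stages, each exposed as ordinary R functions and as
subcommands of the `boneage-calib` script:

1. **Consensus reference** (`consensus_pipeline()`). The per-image mean of
   the k rater estimates is the *initial, uncorrected consensus*. Images
   with a missing assessment, or with any single rating deviating
   strictly more than 30 months from that mean, are excluded. For each
   rater j the signed mean difference against the initial mean
   (`smd_bias_j`) and the mean absolute difference of the bias-corrected
   rater (`mad_j`) are computed in a single pass, and the reference is
   the performance-weighted average
   `consensus_i = sum_j w_j (r_ij - smd_bias_j)` with
   `w_j = (1/mad_j) / sum_l (1/mad_l)`.
2. **Stratified partition** (`stratified_split()`). Images of children
   with a known genetic disorder always go to the test set; the rest are
   split per (24-month age bin x sex) stratum with largest-remainder
   rounding so the global train fraction (default 1/3) is met exactly.
3. **Calibration** (`fit_calibration()`). Ordinary least squares of the
   consensus on the raw prediction, separately per sex:
   `BA_cal = slope_sex * BA_raw + intercept_sex`, with t-based 95%
   coefficient intervals. The regression direction is dictated by the
   calibration equation; consensus is the response.
4. **Agreement evaluation** (`agreement_report()`): MAD, RMSE with a
   chi-squared CI, signed mean difference (SMD) with a t CI, 1-year
   accuracy, ICC(2,k), Bland–Altman limits of agreement, and a
   Lilliefors normality check of the signed residuals.
5. **Stability** (`bootstrap_repartition()`): 1000 fresh stratified
   partitions, refitting the calibration each time, summarized as
   percentile intervals of the parameters and test metrics and as
   per-sex correction-curve bands, against which the primary
   calibration is checked (`correction_within_band()`).

## Statistical conventions

* **Units.** Every age and bone age is a real number of months;
  chronological age is restricted to [0, 216] months (0–18 years) unless
  explicitly relaxed.
* **RMSE interval.** `(sqrt(n RMSE^2 / chisq(0.975, n)), sqrt(n RMSE^2 /
  chisq(0.025, n)))` with the chi-squared quantiles at **n** degrees of
  freedom (not n − 1). With n = 260 this reconstructs the intervals the
  downstream validation literature reports for RMSEs of 8.76 and 7.37
  months to the printed precision, which fixes the df convention.
* **SMD interval.** `mean(d) ± t(0.975, n-1) * sd(d)/sqrt(n)`, sample SD
  with the n − 1 denominator throughout the package.
* **1-year accuracy.** The 12-month boundary counts as accurate
  (|error| ≤ 12); the boundary convention is otherwise arbitrary and is
  configurable via `threshold`.
* **ICC(2,k).** McGraw & Wong's two-way random-effects, absolute
  agreement, average-measures coefficient, computed from the ANOVA mean
  squares, with the Satterthwaite F-based interval (average-measure
  bounds via the Spearman–Brown step-up). Whether the rating matrix is
  the (reference, predictor) pair or the predictor against the full
  rater panel is genuinely ambiguous in this design; both modes are
  implemented (`icc_mode = "pair"` / `"panel"`) and every report records
  which one was used.
* **Normality.** The KS test with parameters estimated from the sample
  is the Lilliefors test, and the Lilliefors null distribution
  (`nortest::lillie.test`) is used; a naive KS test against
  `pnorm(mean(x), sd(x))` would be badly miscalibrated at these sample
  sizes.
* **Quantiles.** All percentile intervals use R's default
  linear-interpolation quantile (type 7); the bootstrap summary records
  this so order-statistic comparisons are exact.

## What the bias correction does — and does not — absorb

A subtle property of the Halabi-style consensus is worth stating
precisely, because it is easy to over-claim. Adding a constant c to one
rater's ratings moves the initial all-rater mean by c/k, so the final
consensus shifts **uniformly by exactly c/k** — it is *not* invariant.
What the bias correction does absorb, exactly, is everything else: the
per-rater MADs and the 1/MAD weights are untouched, and the shift does
not depend on the offending rater's weight (without bias correction the
weighted average would shift by `w_j * c`). The test suite asserts this
absorption law at 1e-9.

## The synthetic cohort generator

No public cohort with per-rater ratings exists for this design, so the
package ships a generator (`generate_cohort()`) whose defaults
(`default_gbad_like_config()`) emulate the study conditions the package
is built for:

* 381 images, female fraction 184/381, disorder rate 19/381;
* chronological age uniform on [12, 216] months (the real cohort's age
  histogram is not published; uniform keeps every stratification bin
  occupied, which the split logic needs), true BA = CA + N(0, 12²);
* a 7-rater panel with fixed additive biases
  (−3.07, −0.8, −0.2, 0.3, 0.9, 1.32, 1.55) months — spanning the
  reported bias range and summing to zero so the consensus is centred on
  the true BA — and noise SDs (7, 8, 8.5, 9, 9.5, 10.5, 12) months,
  chosen to reproduce an inter-rater MAD near 8 months and a 1/MAD
  weight spread near [0.11, 0.17];
* an AI whose raw output is the *forward* linear distortion
  `ai_raw = a_sex * BA_true + c_sex + N(0, 5.5²)`, with (a, c) set to the
  inverse of the published calibration fits (female a = 1/1.032,
  c = 6.532/1.032; male a = 1/1.040, c = 9.860/1.040), so the correct
  recalibration parameters are analytically known and the uncalibrated
  predictor overestimates the consensus by about +2.8 (female) and +5.1
  (male) months in expectation;
* simulated bone ages floored at 0 months; all draws from one seeded
  generator, so a config reproduces its cohort bit for bit.

**What it does not emulate:** the generator is Gaussian and
homoscedastic per rater (an age-proportional noise mode exists but is
off by default), ratings are continuous rather than atlas-stage
discrete, and there are no gross outliers. Real residual distributions
are heavier-tailed, so a passing test suite shows the *machinery* is
correct under the assumed noise model — it does not certify performance
numbers on real radiographs. One visible consequence: simulated 1-year
accuracies run a few points higher than the published ones at matched
RMSE.

## Parameter recovery and the attenuation limit

Because the distortion is modeled forward, OLS calibration has a known,
quantifiable bias: regressing the reference on a *noisy* predictor
estimates the best linear predictor, whose slope is
`(1/a) * (1 - sigma^2 / (a^2 Var(BA_true) + sigma^2))`. With AI noise
SD 4 and ages uniform on [12, 216], that attenuation is about 0.5% of
the slope (≈ 0.005) with a matching intercept offset (≈ +0.6 months).
This is a property of the estimand, not an implementation defect: on
noise-free data the fit is exact to machine precision, and recovery of
(1/a, −c/a) holds comfortably on the scale of the replicate spread
(±0.03 on the slope at n = 400). At Monte-Carlo precision over hundreds
of replicates, however, the attenuation is resolvable, and nominal-level
CI coverage of the *unattenuated* inverse parameters is structurally
below 95%. The same applies to the real study's fitted parameters: they
estimate the population's best linear correction, which is exactly what
one wants to apply, but they should not be read as the inverse of a
physical distortion to four digits.

Similarly, the bootstrap correction-curve band is a pointwise 95%
percentile corridor; since the primary partition is exchangeable with
the re-partitions, the chance that its whole correction line stays
inside the corridor at every grid point for both sexes is necessarily
below 95% (measured around 70–85% per run on synthetic cohorts). The
band check therefore reports per-sex pointwise coverage alongside the
all-points pass flag rather than treating a graze of the band edge as a
failure of the method.

## Numerical and design choices

* Exclusion threshold comparison is strict (`> 30` months); ratings at
  exactly 30 months deviation are retained.
* A rater in perfect agreement with the initial mean (MAD 0) would get
  infinite weight; the MAD is floored (default 1e-6 months) with a
  warning.
* The consensus is single-pass, anchored on the initial uncorrected mean
  (both the bias and the MAD); an iterate-to-convergence mode
  (`iterate = TRUE`) re-anchors on the weighted consensus but is off by
  default, matching the two-step description of the reference procedure.
* Calibrated outputs are not clamped to [0, 216]; negative outputs only
  trigger a warning, since clamping would distort SMD analyses near the
  range edges.
* Stratification uses 24-month age bins by default — fine enough to
  balance the age distribution, coarse enough to keep all strata
  occupied at n ≈ 381. Whether the primary split uses exactly 1/3 or a
  121/362-style fraction is configurable (`train_fraction`).
* Replicate seeds are a counter-keyed affine function of the master seed
  (`derive_seed()`), so any single replicate can be reproduced in
  isolation and replicate order is irrelevant.
* Correction curves are evaluated on a 12-month grid over [12, 216] —
  the generator's age support; extrapolating the band to raw BA 0 would
  compare intercepts far outside the data.
* Bootstrap replicates that fail (singular fit in a sex stratum) are
  recorded; more than 1% failures aborts with a diagnostic.

## Problem sizes in the test suite

The suite exercises the pipeline at the study's own scale where that is
what is being claimed — 381-image cohorts, 7 raters, 1000-replicate
bootstraps, 200-replicate parameter-recovery sweeps — and at small
hand-checkable sizes (3×3 rating tables, 5×3 ICC matrices) where the
point is exact agreement with independent oracles: a spreadsheet-style
consensus computation, `anova()`-based ICC mean squares, sort-based
order statistics for the percentile intervals, and from-scratch
recomputation of every leave-one-rater-out consensus.

## Known limitations

* Plain OLS; no errors-in-variables (Deming) or robust alternative — by
  design, since the procedure being implemented is simple linear
  recalibration.
* Continuous ratings only; ordinal atlas stages are out of scope.
* The generator's noise model is Gaussian; heavy-tailed rater error and
  pathology-driven outliers are not simulated.
* Laterality (left vs right hand) is not part of the data model.
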