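---
title: "Methods: imminent-decline thresholds, the synthetic cohort, and power mapping"
author: "fdgdecline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imminent-decline thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The outcome throughout is the annualized percent change in FDG-PET SUVR,

$$\Delta = \frac{\mathrm{SUVR}_{fu} - \mathrm{SUVR}_{bl}}{\mathrm{SUVR}_{bl}}
  \cdot \frac{100}{\Delta t},$$

with $\Delta t$ in years. The follow-up interval is stored in months
(cohorts report follow-up that way) and converted to years inside
`annualized_change()`; all downstream calibration constants
($\Delta\mu$, $\sigma$) are in percent per year. Annualizing — rather than
using the raw 2-year change — makes subjects with 18- and 30-month
follow-ups comparable; with the ~24-month intervals the two conventions
differ only by a factor of about two and share the same thresholds.

**Supra-threshold curves.** For a biomarker $B$ (amyloid-PET SUVR or CSF
p-tau) and each candidate threshold $t$ among the sorted observed values,
the response is the mean change among subjects with $B \ge t$
(`build_threshold_curve()`). This supra-threshold (tail-mean) reading is
the construction consistent with building biomarker-positive groups at
progressively higher cutoffs; candidates whose tail holds fewer than
`min_tail = 5` subjects are dropped because a tail mean over a handful of
subjects is dominated by noise.

**Sigmoid and threshold.** The dose–response family is the four-parameter
logistic

$$Y = a + \frac{b}{1 + e^{-(x - c)/d}},$$

with $a$ the low-$x$ asymptote, $b$ the (signed) total change, $c$ the
inflection and $d > 0$ the steepness. The biomarker threshold for imminent
decline is the $x$-location of the inflection, i.e. the fitted $c$ — the
point where the curvature changes sign. A straight line is fitted to the
same curve and the two models are compared by the small-sample Akaike
criterion; the "probability of correctness" of the preferred model is its
two-model Akaike weight $1/(1 + e^{-\Delta/2})$, $\Delta$ being the
absolute AICc difference, so the two model probabilities sum to one.

**Threshold grid.** Every subject's observed biomarker value is a candidate
threshold on its axis, so $n$ subjects yield $n^2$ cells (14,400 at
$n = 120$) — the only construction that reproduces that printed count. Per
cell the group holds the subjects with *both* biomarkers at or above the
pair; the cell reports the group size, its mean averaged-cluster change
(missing below `min_cell = 3`, not zero), a two-sided one-sample t-test
against zero, and a four-way category: both candidates at or below the
standard cutoffs, exactly one above, both above with at least one below the
proposed pair, or both at/above the proposed pair (the `>=` convention for
the proposed boundary).

**Power formula.** Per arm,

$$n = \left\lceil \frac{(\partial + \delta)^2 \; 2\sigma^2}
  {(\Delta\mu \, \beta)^2} \right\rceil,$$

with $\partial = 0.842$, $\delta = 1.96$, $\beta = 0.25$ by default. The
printed coefficients are used verbatim instead of re-derived normal
quantiles (0.8416…, 1.9600) so the worked arithmetic reproduces exactly;
$\Delta\mu$ enters as a magnitude, and the result is rounded up to a whole
subject with a floor of one. Voxel-wise, the same formula is evaluated at
every voxel whose decline survives a Benjamini–Hochberg mask; "FDR at
$P < 0.001$" is implemented as BH-adjusted $p < 0.001$ (under adjusted-$p$
semantics the two readings of that phrase coincide). Group contrasts of
decline use ANCOVA adjusted for age, sex, education and APOE-ε4 (education
can be dropped by passing a different covariate set), with the Bonferroni
family declared explicitly as ROIs × pairwise contrasts; chi-squared tests
are computed without continuity correction, as appropriate for
multi-category tables.

## The synthetic cohort generator

Real source data for this design are access-controlled, so the generator
(`generate_cohort()`) emulates the published cohort structure and is itself
first-class, tested code:

* **Strata.** Five truncated-normal strata matching the published group
  moments and counts: 24 biomarker-negative, 63 at-risk, 16 preclinical
  below and 17 above the proposed thresholds. The at-risk split (3 with
  only amyloid abnormal, 60 with only p-tau abnormal) is not reported
  anywhere; it is chosen so that exactly 36/120 = 30% of subjects exceed
  SUVR 1.15, matching the reported amyloid-positivity rate. The published
  at-risk SUVR dispersion is printed as "1.12 (1)"; an SD of 1 SUVR is
  physically impossible and is read as 0.1.
* **Margins.** Sampling is rejection-based inside bounds kept 0.005 SUVR /
  0.5 pg/ml away from every classification threshold, so classification
  recovers the generating stratum for 100% of subjects at any seed, and the
  strict-`>` boundary convention is immaterial on synthetic data.
* **Decline model.** Expected change in ROI $r$ is
  $\bar Q_r = \mathrm{drift} - M_r \, L\!\big(\tfrac{B_A - c_A}{d_A}\big)
  L\!\big(\tfrac{B_T - c_T}{d_T}\big)$ with $L$ the standard logistic,
  $c_A = 1.228$ SUVR, $d_A = 0.02$, $c_T = 45$ pg/ml, $d_T = 3$, drift
  $-0.1$ %/yr, and per-ROI maxima $M_r$ of 3.4 (mediobasal temporal), 3.0
  (orbitofrontal), 2.8 (anterior and posterior cingulate), 2.5 (lateral
  temporal) and 0 (precuneus, occipital — the control regions). Decline is
  injected multiplicatively on the baseline SUVR so the annualized
  statistic recovers $\bar Q_r + \varepsilon$, $\varepsilon \sim
  N(0, \sigma_Q)$, $\sigma_Q = 2$ %/yr, by construction.
* **Ancillaries.** Follow-up $\sim N(24, 1)$ months truncated to
  [18, 30]; demographics from the published per-group moments (they feed
  only the ANCOVA covariates, never the decline model); CSF Aβ is a noisy
  decreasing linear transform of SUVR whose noise SD (25 pg/ml) is
  calibrated to a rank correlation of about −0.65 at large $n$ — the
  printed magnitude 0.68 is treated as calibration only, and the sign is
  taken negative on biological grounds since it is not printed.

What the generator does **not** emulate: scanner physics, smoothing,
registration error, partial-volume effects, reference-region construction,
assay chemistry, or any cognition/diagnosis trajectory. Passing tests
therefore demonstrate the correctness of the statistical machinery on data
satisfying the model's assumptions, not robustness to the preprocessing
artefacts of real PET data.

## Numerical choices

* **Sigmoid fitting** uses multi-start Levenberg–Marquardt (raw
  `minpack.lm::nls.lm` with a positivity box on $d$). Starts: $a$ at both
  response extremes, $b$ the response range signed by the data trend, $c$
  at the 25/50/75% x-quantiles, $d$ at x-range/30, /10 and the full range,
  plus one start *linearized from the OLS fit* (large $d$, slope-matched
  $b$), which guarantees the sigmoid never ends worse than the straight
  line — an invariant the test suite asserts. Best RSS wins. Optional
  per-point weights (e.g. tail counts) are accepted; the default is
  unweighted, matching the curve definition.
* **CI for $c$** is asymptotic, from the Jacobian-based covariance at the
  solution with a $t$ critical value on $n - 4$ degrees of freedom; on
  zero-residual data it collapses to width zero. (The source analysis does
  not state its CI method; a subject-level bootstrap would be the natural
  alternative and can be layered on by resampling cohorts.)
* **AICc** uses $k$ = fitted parameters + 1 (variance), i.e. $k = 5$ for
  the sigmoid and $k = 3$ for the line, matching the convention of common
  curve-fitting software; plain AIC is available via `small_sample =
  FALSE`. A perfect fit maps to AICc $-\infty$ and is handled throughout.
* **Degenerate inputs.** Constant responses are rejected as non-identified;
  fewer than 6 curve points are rejected; if every start fails the fit
  object carries `converged = FALSE` rather than raising. Grid cells with
  zero within-group variance get a missing p-value; background voxels are
  missing, never zero.
* **Problem sizes.** The shipped tests run the full pipeline at the
  study's natural size (120 subjects, 50 replicate seeds), voxel analyses
  at a 32³ grid, and the trial simulation at 10,000 replicates.

## Known limitations

* **The supra-threshold inflection is composition-driven.** Below the
  proposed cutoffs the tail mean is a dilution curve: the decliner subgroup
  contributes a fixed mass $K$, so $Y(t) \approx \mathrm{drift} - \bar M
  K/n(t)$, shaped by the biomarker's empirical distribution rather than by
  the generative steepness. Its rise is asymmetric and begins as soon as
  biomarker-negative subjects start leaving the tail, which biases the
  fitted inflection of a *symmetric* sigmoid below the generative amyloid
  value, and the estimator inherits the sampling noise of small tails
  (at $\sigma_Q = 2$ %/yr the per-replicate scatter is several times the
  width of the published confidence intervals). The acceptance suite
  documents this honestly: noiseless curves refit their inflections to
  machine precision, while the replicate-containment check against the
  published CIs fails at the generator's stated noise level — a property of
  the supra-threshold construction itself, not of the optimizer.
* **Grid monotonicity is approximate.** With a finite logistic steepness,
  subjects just above the amyloid inflection carry roughly half the decline
  loading, so dropping them when a threshold rises can *lower* the group
  mean; exact cell-wise monotonicity beyond the inflections holds only in
  the step-function limit $d \to 0$. The acceptance suite asserts the exact
  property and records its violation; the qualitative trend (deeper decline
  at jointly higher thresholds) is what the grid shows.
* **Power is two-sample-normal.** The formula assumes equal variances and
  a pure mean-shift drug effect; no longitudinal mixed-effects power model,
  cluster-extent inference or random-field correction is attempted.
* **No CSF-Aβ classifier.** Classification uses PET amyloid plus CSF
  p-tau; CSF Aβ is generated only as a correlated ancillary because Aβ
  thresholds did not usefully model decline in the source analysis.
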