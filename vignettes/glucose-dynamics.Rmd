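---
title: "Three components of glucose dynamics: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three components of glucose dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotriad)
```

## The scientific problem

Continuous glucose monitoring (CGM) samples interstitial glucose every 5
or 15 minutes over several days. Dozens of summary indices of such traces
are in clinical use — mean level, variability measures (Std, MAGE, CONGA,
MODD, LI, MAG), risk-transform indices (HBGI, GRADE, ADRR, M-value,
J-index) — and most of them are strongly intercorrelated. This package
implements an analysis built on the observation that the information in
these indices organizes into three latent components of glucose dynamics:

* **mean** — the overall glucose level;
* **variance** — the spread of excursions;
* **autocorrelation** — the persistence of the trace, summarized by the
  mean (AC_Mean) and variance (AC_Var) of the autocorrelation function
  over a fixed 150-minute lag window.

Each component carries independent information about a continuous
vascular outcome (the necrotic-core percentage of coronary plaque, %NC,
measured by intravascular ultrasound), whereas conventional diagnostics
(fasting glucose, HbA1c, 2-h OGTT glucose) track the mean component
only.

## The CGM index panel

`index_panel()` computes 15 values per trace. All formulas operate on a
uniformly resampled trace (see below). Conventions that matter:

* **Units.** Internal canonical unit is mg/dL; the conversion factor is
  fixed at 18.016 mg/dL per mmol/L. CONGA, MODD, MAGE, LI and MAG are
  reported in mmol/L terms; HBGI and M-value operate on mg/dL; GRADE and
  the J-index convert to mmol/L internally, matching the usual
  formulations.
* **AC lag window.** 30 lags at 5-min sampling, 10 lags at 15-min
  sampling — both span 150 minutes, so the two sampling rates measure
  the same physiology. AC_Var uses the unbiased sample variance of
  r_1..r_K. The ACF is computed on the full contiguous resampled series
  (not per-day) with the standard biased-denominator estimator.
* **CONGA** uses a 1-hour lag; **LI** is evaluated on a 60-minute
  resampled grid — both are the common defaults of the established
  glycemic-variability software.
* **GRADE** caps per-reading scores at 50 and reports the mean (the
  original publication summarized by the median; the mean is the
  convention of the widely used implementation this panel follows).
* **M-value** uses the ideal glucose 120 mg/dL and adds the range
  correction W/20.
* **MAGE** finds alternating local extrema by three-point comparison
  with plateau merging (series endpoints are not turning points),
  iteratively deletes adjacent extremum pairs with amplitude below one
  trace Std, and averages the remaining amplitudes regardless of
  direction. The direction-agnostic mean keeps the statistic
  deterministic and symmetric; implementations that count only upswings
  differ by a roughly constant factor on typical traces.
* **ADRR** requires at least 20 hours of readings for a day to count,
  and `index_panel()` reports it only for traces covering at least two
  days (a one-day "average daily risk range" is not an average over
  days). Days are calendar days when the trace carries a timestamp,
  otherwise consecutive 1440-minute blocks.
* **TIR** counts readings in [70, 180] mg/dL with both bounds included.

### Missing data

The resampler (`resample_uniform()`) interpolates linearly across gaps
up to `max_gap` (default 30 min — roughly the span over which linear
interpolation of interstitial glucose is defensible) and splits the
trace at longer gaps, analyzing the longest covered block. Whether the
original clinical analyses interpolated across CGM gaps is not
documented; this policy is a declared default of this package, applied
uniformly.

## OGTT indices

From 0/30/60/90/120-min glucose and insulin samples:
insulinogenic index (I.I.) = ΔIRI/ΔPG over 0–30 min; composite
insulin-sensitivity index = 10000/√(FPG·FIRI·meanG·meanI) with plain
means over the five samples (the standard convention; a time-weighted
mean is a defensible alternative the package does not use); oral
disposition index = composite × AUC_ins/AUC_glu over the nodes
0/30/60/120 (the 90-min sample is excluded by definition).

The three-point OGTT curve characterization interpolates 0/30/120-min
glucose linearly on a 1-minute grid (the grid step is not prescribed by
the source analysis; 1 min makes lags 1–20 span 20 minutes), and
reports the curve's time-average (trapezoid, hence grid-invariant), the
sample Std of the grid values, and AC_Var at lags 1–20.

## The delay-integral glucose–insulin model

```
dG/dt = −k_glu·G − k_sen·I·G + k_pro + f(t)
dI/dt = (k_sec/k_tim) ∫_{t−k_tim}^{t} G ds − k_cle·I
```

G is glucose (mg/dL); I is insulin in arbitrary units (only the
products k_sen·I and k_sec·G are physically constrained, so the insulin
scale is a free normalization). Insulin secretion responds to average
glucose over the trailing `k_tim` minutes — a distributed delay — and
insulin accelerates glucose disposal. The default stimulus is a square
bolus of 5 mg/dL/min on [30, 40) min of a 240-min horizon.

Numerical scheme: classical fixed-step RK4. The delay integral is
carried as an extra cumulative-integral state Z(t) = ∫₀ᵗ G ds; the
trailing-window integral is Z(t) − Z(t − k_tim) with lagged Z read from
the stored grid by linear interpolation, and the pre-history
G(s ≤ 0) = G(0) contributing in closed form. A fixed step keeps the
delay quadrature deterministic; the solver refuses steps above k_tim/4.
At the default step (0.1 min) halving the step moves the trace summary
statistics by well under 0.1%; the square bolus limits pointwise
convergence to about 10⁻³ relative near the input discontinuities,
which is far below any tolerance used in the analysis.

Initial conditions default to the basal steady state, which is known in
closed form: I* = (k_sec/k_cle)·G* and G* solves
k_sen(k_sec/k_cle)G² + k_glu·G − k_pro = 0.

### The component sweep

`component_sweep()` demonstrates that mean, Std and AC_Var of the
simulated trace are independently adjustable: it simulates a grid over
the rate constants and returns, per component, a pair of parameter sets
in which that component differs by ≥20% while the other two agree
within 5%. The default grid spans half-to-four-fold around the base
values of k_glu, k_pro, k_sen, k_sec and half-to-two-fold of k_tim and
k_cle — generous but physiologic spans for non-diabetic regulation (the
underlying mechanistic model's published parameter ranges live in its
original source and are not restated here, so these spans are this
package's own choice). Simulations whose mean leaves [50, 300] mg/dL
are discarded as unphysiological before pairing. Sweep simulations use
a 0.5-min step: the grid is 2304 points and the pairing tolerances
(5%/20%) are three orders of magnitude above the step-size error.

## The synthetic cohort

No clinical dataset is distributed with the analysis, so
`generate_cohort()` builds one with the same statistical skeleton:

* 8 NGT, 16 IGT and 29 T2DM subjects (the study composition), three
  consecutive days of 5-min CGM each;
* traces are AR(1)-plus-meals: level μ, innovation scale σ and AR
  coefficient φ drawn per class (level, variability and meal size rise
  from NGT to T2DM; φ spans 0.80–0.97 in every class, mirroring the
  observed low multicollinearity of the autocorrelation component with
  the others), three gamma-shaped meal bumps per day near 08:00, 13:00
  and 19:00 with 30-min timing jitter, floored at 40 mg/dL;
* conventional markers (FBG, HbA1c, PG120) are generated from the
  subject's level parameter only — by construction they carry no
  variance or autocorrelation information — and are rejection-sampled
  into the diagnostic windows of the subject's class (T2DM: HbA1c ≥
  6.5%, FPG ≥ 126 mg/dL or PG120 ≥ 200 mg/dL; IGT: 6.0–6.4%, 110–125,
  140–199; NGT below all prediabetes thresholds);
* the outcome is %NC = b₀ + b_mean·z(mean) + b_var·z(Std) +
  b_ac·z(AC_Var) + ε with defaults b = (18, 4, 3, 3), ε ~ N(0, 4),
  truncated to [0, 100] — the minimal generative structure that makes
  the regression, selection and factor analyses testable as recovery
  problems with known truth.

An alternative trace generator drives the mechanistic simulator instead
of the AR(1) process; the AR(1) form is the default for recovery tests
because its autocorrelation is known analytically and it is orders of
magnitude faster.

What the generator deliberately does not emulate: sensor noise spectra
and dropout, inter-day habit structure, medication effects, and any
real covariance between %NC and lipids or blood pressure. Passing
recovery tests on this cohort shows the pipeline is correct and
calibrated, not that real %NC is predictable to the same degree.

`generate_index_table()` is the matching fixture for the factor stage:
variables = ΛF + unique noise with block loadings (default three blocks
of four variables, loading 0.85), so retention criteria, rotation and
congruence have a known truth.

## Statistical pipeline choices

* **AIC** is Gaussian maximum-likelihood with constants,
  parameters = coefficients + intercept (σ uncounted). Printed AICs are
  only comparable within a fixed convention; this one is fixed for
  internal comparisons.
* **LASSO** uses the (1/2n)·RSS + λ‖β‖₁ objective (glmnet's gaussian
  scaling) with an unpenalized intercept and a 200-point log-spaced λ
  grid on [10⁻³, 10²]; λ is chosen by exact leave-one-out CV (n refits
  of the full path), and ties go to the larger λ.
* **PLS** is univariate-response NIPALS with components chosen by
  leave-one-out CV in 1..min(5, p, n−1);
  VIP_j = √(p·Σ_a SS_a w_ja² / Σ_a SS_a) with unit-norm weight vectors,
  so Σ VIP² = p.
* **Spearman network**: average ranks for ties; percentile bootstrap
  CIs over subjects (default 10000 resamples); Benjamini–Hochberg
  correction applied jointly across all pairs; constant columns skip
  their pairs with a recorded reason.
* **Factor analysis**: maximum-likelihood extraction (required for a
  likelihood-based BIC), Kaiser-normalized varimax, regression
  (Thurstone) scores. BIC = −2·logLik + params·ln n with
  params = p(k+1) − k(k−1)/2 up to the Ledermann bound (capped at 8).
  MAP is Velicer's original squared-partial-correlation form. Heywood
  cases are flagged, not fatal. The extraction method and score
  estimator of the source analysis are unreported; these are this
  package's choices.
* **Reliability**: raw-score Cronbach α with Feldt F-based CI;
  item–total correlations are corrected (item excluded from the total),
  the reading consistent with a two-item factor reporting a single
  value; negative-loading items are sign-flipped first.
* **Clustering**: variables as points in z-scored subject space,
  Euclidean/Ward (ward.D2), k chosen in 2..6 by mean silhouette; the
  insulin-sensitivity/secretion indices and AC_Mean are negated first
  so every variable increases with abnormality.
* **Power**: n = ⌈((z_{1−α/2} + z_power)/atanh r)²⌉ + 3 (Fisher z).

## Degenerate inputs and tie-breaks

Constant traces make the ACF undefined (error), MAGE 0 with a flag, and
CONGA/LI/Std 0. VIF pruning breaks ties toward the first variable in
input order; exactly collinear predictors get infinite VIF and are
removed one per iteration. Flat three-point OGTT curves report Std 0
and missing AC metrics. LASSO at λ ≥ max|X'(y−ȳ)|/n returns the
all-zero coefficient vector exactly.

## Problem sizes in the shipped analyses

The bundled analysis scripts and acceptance checks run at the scales
the recovery properties were designed for: cohorts of 53 (study
composition) or 200 subjects (30/60/110 across classes), 100 generator
seeds for the regression and selection rates, 50 seeds for
factor-score sign recovery, n = 300 index tables for retention, and a
2304-point simulator grid for the component sweep. These sizes were
chosen so every stochastic rate estimate has a standard error well
below the margin it is compared against.

## Known limitations

* The clinical values reported with the original analysis (R², AIC, λ,
  KMO, α, variance shares) depend on an undeposited dataset; nothing
  here reproduces them, and the synthetic analogues are calibrated
  recovery problems, not re-estimates.
* EasyGV-compatible formula variants differ across versions for
  M-value, GRADE and LI; the conventions above are fixed and documented
  rather than configurable.
* The AR(1)-plus-meals generator has a single autocorrelation timescale
  per subject; real CGM traces mix meal, circadian and sensor dynamics.
* The simulator's parameter ranges are plausibility spans, not fitted
  population ranges; `component_sweep` statements are existence claims
  over that grid.
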