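# glucotriad

Glucose dynamics measured by continuous glucose monitoring (CGM) carry
more information than the average glycemia that conventional diabetes
diagnostics (fasting glucose, HbA1c, 2-h OGTT glucose) summarize. This
package implements a three-component view of glucose dynamics — **mean**,
**variance** and **autocorrelation** — and the full analysis built on it:

* the 14 CGM-derived indices (CGM_Mean, CGM_Std, CONGA, LI, J-index,
  HBGI, GRADE, MODD, MAGE, ADRR, M-value, MAG, and the autocorrelation
  metrics **AC_Mean**/**AC_Var**) plus time in range, with the lag
  convention tied to the sampling rate (lags 1–30 at 5-min sampling,
  1–10 at 15-min — both a 150-min window);
* OGTT-derived indices (insulinogenic index, Matsuda composite index,
  oral disposition index) and a three-point OGTT curve characterization
  (mean / Std / AC_Var of the interpolated curve, lags 1–20);
* a deterministic delay-integral glucose–insulin simulator

  ```
  dG/dt = −k_glu·G − k_sen·I·G + k_pro + f(t)
  dI/dt = (k_sec/k_tim) ∫_{t−k_tim}^t G ds − k_cle·I
  ```

  used to show the three components are independently adjustable;
* the statistical pipeline linking the components to a continuous
  plaque-vulnerability outcome (%NC): z-scoring, OLS with AIC/VIF,
  iterative VIF pruning, bootstrap Spearman networks with
  Benjamini–Hochberg correction, LASSO with leave-one-out CV, PLS with
  VIP scores, exploratory factor analysis (BIC/MAP retention, varimax,
  KMO/Bartlett, Cronbach α), and Ward/silhouette variable clustering;
* a synthetic-cohort generator (8 NGT / 16 IGT / 29 T2DM by default,
  three days of 5-min CGM each) whose %NC outcome is driven by the three
  trace components with known coefficients, so every downstream stage is
  testable as a recovery problem.

It is targeted at researchers working with CGM/OGTT panels who need
reproducible index computation and a tested reference implementation of
the component analysis; no clinical data ships with it.

## Worked example

```r
library(glucotriad)

# a synthetic subject: AR(1)-plus-meals trace, 3 days at 5-min sampling
tr <- generate_trace("S001", mu = 130, sigma = 8, phi = 0.9,
                     meal_amp = 50, days = 3, seed = 11)
round(index_panel(tr), 3)
#> CGM_Mean  CGM_Std    CONGA       LI   JINDEX     HBGI    GRADE     MODD
#>  131.522   21.644    1.460    1.989   23.418    1.550    4.162    1.086
#>     MAGE     ADRR   MVALUE      MAG  AC_Mean   AC_Var      TIR
#>    2.460   13.109    6.583    4.694    0.163    0.141   97.801

# basal steady state of the glucose-insulin model
steady_state(sim_params(k_glu = 0.01, k_sen = 1e-4, k_pro = 1.0,
                        k_sec = 0.02, k_cle = 0.1))
#>        G        I
#> 85.41020 17.08204
```

CGM_Mean and CGM_Std are in mg/dL; CONGA, MODD, MAGE and MAG are in
mmol/L terms; AC_Mean/AC_Var are unitless summaries of the
autocorrelation function at lags 1–30; TIR is the percentage of readings
in [70, 180] mg/dL. The steady state is the closed-form root of the
basal balance and is also where simulations start.

The full analysis is a numbered workflow under `analysis/` (each script
prints what it found and writes tables under `results/`):

```sh
Rscript analysis/01_build_cohort.R          # synthetic cohort + index panel
Rscript analysis/02_component_regression.R  # %NC ~ components vs markers, VIF, network
Rscript analysis/03_feature_selection.R     # LASSO + PLS-VIP
Rscript analysis/04_factor_structure.R      # EFA, reliability, clustering
Rscript analysis/05_simulated_dynamics.R    # component sweep, OGTT shapes
```

On the default cohort the component regression prints

```
Three-component model:  R2 = 0.68, AIC = 319, VIFs: 1.8/1.9/1.0
Conventional markers:   R2 = 0.54, AIC = 338
```

— the three-component model out-predicts the markers because the
generated %NC depends on variance and autocorrelation that FBG, HbA1c
and PG120 cannot see, and the low VIFs show the three components carry
nearly independent information. The factor stage isolates AC_Mean and
AC_Var into their own factor, the synthetic analogue of the
autocorrelation component.

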