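#!/usr/bin/env Rscript
# Which variables carry the %NC signal: LASSO with leave-one-out CV and
# PLS regression with VIP scores over the full index panel.
# Requires results/cohort.csv. Outputs: results/selection.json

library(glucotriad)
cohort <- read.csv("results/cohort.csv")
y <- cohort$NC
feats <- c("BMI", "FBG", "HbA1c", "PG120", "II", "Composite", "OralDI",
           "CGM_Mean", "CGM_Std", "CONGA", "LI", "JINDEX", "HBGI", "GRADE",
           "MODD", "MAGE", "ADRR", "MVALUE", "MAG", "AC_Mean", "AC_Var")
X <- as.matrix(zscore(cohort[, feats]))

lr <- lasso_loocv(X, y)
cat(sprintf("LASSO optimal lambda (LOO-CV): %.3f\n", lr$lambda_opt))
cat("Non-zero coefficients at the optimum:\n")
nz <- sort(lr$coefficients[lr$coefficients != 0], decreasing = TRUE)
for (nm in names(nz)) cat(sprintf("  %-10s %+0.3f\n", nm, nz[[nm]]))

pr <- pls_vip(X, y)
cat(sprintf("PLS: %d components by LOO-CV; variables with VIP >= 1:\n",
            pr$n_components))
vip1 <- sort(pr$vip[pr$vip >= 1], decreasing = TRUE)
for (nm in names(vip1)) cat(sprintf("  %-10s %.2f\n", nm, vip1[[nm]]))

jsonlite::write_json(list(
  lambda_opt = lr$lambda_opt,
  lasso_nonzero = as.list(nz),
  pls_components = pr$n_components,
  vip = as.list(round(pr$vip, 4))),
  "results/selection.json", auto_unbox = TRUE, digits = NA)
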