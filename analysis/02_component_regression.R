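#!/usr/bin/env Rscript
# Regression of %NC on the three glucose-dynamics components versus the
# conventional markers; VIF pruning of the full panel; Spearman network.
# Requires results/cohort.csv from 01_build_cohort.R.
# Outputs: results/regression.json, results/network_edges.csv,
#          results/vif_pruning.csv

library(glucotriad)
cohort <- read.csv("results/cohort.csv")
y <- cohort$NC

three <- fit_ols(zscore(cohort[, c("CGM_Mean", "CGM_Std", "AC_Var")]), y)
markers <- fit_ols(zscore(cohort[, c("FBG", "HbA1c", "PG120")]), y)
cat(sprintf("Three-component model:  R2 = %.2f, AIC = %.0f, VIFs: %s\n",
            three$r_squared, three$aic,
            paste(sprintf("%.1f", three$vif), collapse = "/")))
cat(sprintf("Conventional markers:   R2 = %.2f, AIC = %.0f\n",
            markers$r_squared, markers$aic))

panel_vars <- c("BMI", "SBP", "DBP", "TG", "LDLC", "HDLC", "FBG", "HbA1c",
                "PG120", "II", "Composite", "OralDI", "CGM_Mean", "CGM_Std",
                "CONGA", "LI", "JINDEX", "HBGI", "GRADE", "MODD", "MAGE",
                "ADRR", "MVALUE", "MAG", "AC_Mean", "AC_Var")
pruned <- vif_prune(zscore(cohort[, panel_vars]))
cat(sprintf("VIF pruning retained %d of %d variables; AC_Var retained: %s\n",
            length(pruned$retained), length(panel_vars),
            "AC_Var" %in% pruned$retained))
write.csv(pruned$trail, "results/vif_pruning.csv", row.names = FALSE)

net <- spearman_network(cbind(cohort[panel_vars], NC = y),
                        n_boot = 2000, seed = 1)
edges_nc <- subset(net$edges, (var1 == "NC" | var2 == "NC") & significant)
cat(sprintf("Network: %d significant edges (Q < 0.05), %d involve %%NC\n",
            sum(net$edges$significant), nrow(edges_nc)))
write.csv(net$edges, "results/network_edges.csv", row.names = FALSE)

jsonlite::write_json(list(
  three_component = list(r2 = three$r_squared, adj_r2 = three$adj_r_squared,
                         aic = three$aic, vif = as.list(three$vif)),
  conventional = list(r2 = markers$r_squared, aic = markers$aic),
  power_n_r0.4 = power_sample_size(0.4, 0.05, 0.8),
  vif_retained = pruned$retained),
  "results/regression.json", auto_unbox = TRUE, digits = NA)
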