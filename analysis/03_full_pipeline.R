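#!/usr/bin/env Rscript
## Full nine-patient synthetic pipeline at the study conditions: calibrated
## hemodynamics, forward-penalty stress, registration-based growth maps,
## 9 x 38 region table, and the mixed-effects analyses for stress, WSS,
## pressure and thrombus predictors. Writes results/pipeline/.

suppressMessages(library(aortagrowth))

cfg <- pipeline_config(seed = 2026, out_dir = "results/pipeline",
                       solid_circ = 32L, solid_axial = 44L,
                       reg_args = list(layer_step = 8L, node_step = 2L,
                                       max_iter = 80L))
run <- suppressWarnings(run_pipeline(cfg, verbose = TRUE))
print(run)

cat("\nPer-patient Pearson correlations (stress vs growth):\n")
print(run$pearson, row.names = FALSE)
cat("\nMixed-effects fits:\n")
for (nm in names(run$fits)) { cat("--", nm, "--\n"); print(run$fits[[nm]]) }
cat(sprintf("\nTL vs FL pressure paired t-test: t = %.3f, p = %.4f\n",
            run$pressure_summary$t_test$statistic,
            run$pressure_summary$t_test$p.value))
write.csv(run$pearson, "results/pipeline/pearson.csv", row.names = FALSE)
write.csv(run$pressure_summary$table, "results/pipeline/lumen_pressures.csv",
          row.names = FALSE)

cat("\nNote on reading the stress fit: with random-slope SD 0.13 around a\n",
    "fixed slope of 0.095, a single 9-patient cohort's fixed-slope\n",
    "estimate tracks 0.095 + mean of the drawn patient slopes, so any one\n",
    "seed can land far from 0.095 (and per-patient correlations can have\n",
    "either sign). The unbiasedness/coverage properties of the estimator\n",
    "are established over 200 replicates in\n",
    "analysis/04_monte_carlo_statistics.R.\n", sep = "")
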