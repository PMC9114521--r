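#!/usr/bin/env Rscript
# Strain and Young's modulus analysis of the simulated campaign, plus the
# worked reference examples: stress calibrated from the normal population's
# (modulus, strain) pair, applied to the treated population.

suppressPackageStartupMessages(library(depmech))
dir.create("results", showWarnings = FALSE)

if (!file.exists("results/traces.csv")) {
  stop("run analysis/04_simulate_campaign.R first (results/traces.csv missing)")
}
traces <- read_traces("results/traces.csv")

stress <- calibrate_stress(203.7, 0.0864)
cat(sprintf("calibrated stress: %.5f Pa (from E = 203.7 Pa at strain 0.0864)\n",
            stress))

res <- analyze_traces(traces, stress, estimator = "model")
write_results("results/cell_results.csv", res)
cat(sprintf("analyzed %d cells: %s\n", nrow(res),
            paste(sprintf("%s=%d", names(table(res$qc_flag)),
                          table(res$qc_flag)), collapse = ", ")))

rep <- compare_groups(res[res$group == "normal", ],
                      res[res$group == "treated", ])
print(rep)
props <- do.call(rbind, lapply(rep$groups, function(g) {
  p <- g$proportions
  p$group <- g$label
  p
}))
write_results("results/strain_interval_proportions.csv", props)

# worked reference examples (population means, calibration mode)
cat("\nreference worked examples:\n")
cat(sprintf("  HUVEC:   stress from (203.7 Pa, 0.0864) -> E(0.1013) = %.1f Pa\n",
            youngs_modulus(stress, 0.1013)))
cat(sprintf("  MCF-10A: stress from (257.3 Pa, 0.0684) -> E(0.0901) = %.1f Pa\n",
            youngs_modulus(calibrate_stress(257.3, 0.0684), 0.0901)))
cat("per-cell results in results/cell_results.csv; interval proportions in\n")
cat("results/strain_interval_proportions.csv\n")
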