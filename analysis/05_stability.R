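#!/usr/bin/env Rscript
# Stage 5: bootstrap accuracy and stability of the baseline network.
#
# Case-dropping bootstrap over a grid of drop proportions gives the
# CS-coefficient (largest droppable fraction keeping >= 0.7 correlation
# with the full-sample network in >= 95% of replicates; >= 0.25 is the
# conventional minimum for interpretability, >= 0.5 preferred).
# Nonparametric resampling with replacement gives 95% edge-weight CIs and
# pairwise bootstrapped difference tests (uncorrected, by design).
# B = 250 replicates per analysis here; the conventional full setting is
# B = 1000 (a config key), which simply takes four times as long.

suppressPackageStartupMessages(library(qolnet))

cohort <- read_cohort_csv("results/cohort_imputed.csv")
nodes <- readLines("results/selected_nodes.txt")
cfg <- pipeline_config(bootstrap_B = 250)

stab <- case_drop_bootstrap(cohort, cfg, timepoint = "M0", nodes = nodes,
                            seed = 201)
cat("Case-dropping stability (M0):\n")
print(stab)
curve <- aggregate(correlation ~ proportion + statistic,
                   data = stab$correlations, FUN = mean)
write.csv(curve, "results/stability_curves_M0.csv", row.names = FALSE)
write.csv(stab$cs, "results/cs_coefficients_M0.csv", row.names = FALSE)

boot <- edge_ci_bootstrap(cohort, cfg, timepoint = "M0", nodes = nodes,
                          seed = 202)
ci <- boot$ci
cat(sprintf("\nEdge CIs: %d/%d exclude zero; widest interval %.3f\n",
            sum(ci$lower > 0 | ci$upper < 0), nrow(ci),
            max(ci$upper - ci$lower)))
write.csv(ci, "results/edge_ci_M0.csv", row.names = FALSE)

dt <- difference_tests(boot)
cat(sprintf("Significant pairwise differences: %d edge pairs, %d strength pairs\n",
            sum(dt$edges[upper.tri(dt$edges)]),
            sum(dt$strength[upper.tri(dt$strength)])))
write.csv(dt$edges, "results/edge_difference_tests_M0.csv")
write.csv(dt$strength, "results/strength_difference_tests_M0.csv")
cat("Wrote stability and bootstrap tables under results/\n")
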