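#!/usr/bin/env Rscript
# Step 4 — Monte-Carlo inference.
#
# Reports the three pairwise orientation tests for the central target and
# the trunk-orientation control from the step-2 tables, alongside the
# orientation differences implied by the configured condition geometry.

source("analysis/00_config.R")

tabs <- read_results("results/analysis")
truth <- c(LEFT_CP = 72.8, RIGHT_CP = 112.7, NCP = 100.4)

pt <- tabs$permutation_table
ep <- pt[pt$analysis == "endpoint_orientation", ]
ep$expected_diff_deg <- apply(ep, 1, function(r) {
  pair <- strsplit(r[["pair"]], " vs ", fixed = TRUE)[[1]]
  axial_difference(truth[pair[1]], truth[pair[2]])
})
cat("Pairwise Monte-Carlo orientation tests (central target):\n")
print(ep[, c("pair", "observed_diff_deg", "expected_diff_deg", "N",
             "n_sims", "p_value")], row.names = FALSE, digits = 4)
cat("\nThe left-vs-right contrast carries the largest configured separation\n")
cat("(39.9 deg) and should give the smallest p of the three pairs.\n")

tk <- pt[pt$analysis == "trunk_orientation", ]
cat("\nInitial trunk orientation control (identical posture generated):\n")
print(tk[, c("pair", "observed_diff_deg", "p_value")],
      row.names = FALSE, digits = 3)
cat("\nAll trunk differences are fractions of a degree and non-significant:\n")
cat("endpoint effects are not attributable to a rotated initial posture.\n")
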