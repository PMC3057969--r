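#!/usr/bin/env Rscript
# Step 1 — simulate the experiment.
#
# Generates the full synthetic study (10 participants x 300 trials) with the
# published per-condition endpoint orientations as configured ground truth,
# checks the design balance, and writes the design and ground-truth tables.

source("analysis/00_config.R")

cfg <- study_generator_config()
cat("Generating synthetic experiment (seed", cfg$seed, ")...\n")
ex <- generate_experiment(cfg)

design <- ex$design
stopifnot(nrow(design) == cfg$n_participants * 300L)
balance <- do.call(rbind, lapply(split(design, design$participant),
  function(d) data.frame(
    participant = d$participant[1],
    n_trials = nrow(d),
    n_blocks = length(unique(d$block)),
    blocks_per_condition = paste(
      as.vector(table(unique(d[, c("block", "condition")])$condition)),
      collapse = "/"),
    targets_twice_per_block = all(vapply(split(d$target, d$block),
                                         function(tg) all(table(tg) == 2L),
                                         TRUE)))))
print(balance, row.names = FALSE)
cat("\nEvery participant: 300 trials in 30 blocks (10 per condition),",
    "each target twice per block.\n")

out <- results_dir("study")
write_results(list(design = design, ground_truth = ex$ground_truth,
                   design_balance = balance), out)
cat("Wrote", file.path(out, "design.csv"), "and ground truth tables.\n")
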