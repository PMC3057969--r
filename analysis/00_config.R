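# Shared study configuration for the analysis scripts.
#
# The simulated experiment mirrors the study protocol: 10 participants,
# 3 conditions (left-addressee CP, right-addressee CP, NCP), 5 targets in a
# cross arrangement, 20 repetitions per target and condition grouped into 30
# blocks of 10 trials, marker streams at 400 Hz. The per-condition endpoint
# orientations are set to the published values (72.8 / 112.7 / 100.4 degrees)
# so downstream scripts can compare their estimates against known truth.

library(pointkin)

STUDY_SEED <- 20260929L

study_generator_config <- function() {
  generator_config(seed = STUDY_SEED)
}

study_run_config <- function() {
  run_config(rng_seed = STUDY_SEED)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
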