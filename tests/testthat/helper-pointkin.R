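# Shared fixtures and independent brute-force oracles.

# A small synthetic experiment for pipeline-level tests.
small_config <- function(seed = 42, n_participants = 4L, reps = 10L,
                         blocks = 2L, ...) {
  generator_config(n_participants = n_participants,
                   reps_per_target_per_condition = reps,
                   blocks_per_condition = blocks, seed = seed, ...)
}

# A handcrafted trial: rest at `start`, constant-velocity straight segment,
# rest at the end. Exact and fully predictable (no noise).
make_straight_trial <- function(move_mm = c(0, -300, 0), move_samples = 240L,
                                pre_samples = 40L, post_samples = 40L,
                                release_at = pre_samples, rt_raw_ms = 500,
                                fs = 400) {
  n <- pre_samples + move_samples + post_samples + 1L
  s <- c(rep(0, pre_samples), seq(0, 1, length.out = move_samples + 1L),
         rep(1, post_samples))
  pos <- outer(s, move_mm)
  trial_recording(
    participant = "P01", condition = "NCP", target = "glass", block = 1L,
    rt_raw_ms = rt_raw_ms,
    t = (seq_len(n) - 1L) / fs,
    led1 = pos,
    led2_on = seq_len(n) <= release_at,
    led3 = matrix(c(180, 120, 450), n, 3, byrow = TRUE),
    led4 = matrix(c(-180, 120, 450), n, 3, byrow = TRUE),
    sampling_rate_hz = fs)
}

# Explicit-summation unbiased covariance of a 2-column point set.
cov_brute <- function(p) {
  n <- nrow(p)
  mx <- sum(p[, 1]) / n
  my <- sum(p[, 2]) / n
  sxx <- sum((p[, 1] - mx)^2) / (n - 1)
  syy <- sum((p[, 2] - my)^2) / (n - 1)
  sxy <- sum((p[, 1] - mx) * (p[, 2] - my)) / (n - 1)
  matrix(c(sxx, sxy, sxy, syy), 2, 2)
}

# Closed-form eigenvalues of a symmetric 2x2 matrix (quadratic formula).
eig_brute <- function(m) {
  tr <- m[1, 1] + m[2, 2]
  det <- m[1, 1] * m[2, 2] - m[1, 2]^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  c(tr / 2 + disc, tr / 2 - disc)
}

# Classical Cook's distance for an intercept-only fit, evaluated from the
# textbook formula D_i = (e_i^2 / (p s^2)) * h / (1-h)^2 with h = 1/n, p = 1.
cooks_brute <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s2 <- sum(e^2) / (n - 1)
  h <- 1 / n
  (e^2 / s2) * h / (1 - h)^2
}
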