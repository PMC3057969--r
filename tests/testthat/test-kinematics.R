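test_that("exponential filter fixed points and closed-form step response", {
  expect_equal(exponential_filter(c(5, 5, 5), 0.1), c(5, 5, 5))
  x <- rnorm(50)
  expect_equal(exponential_filter(x, 1), x)
  # unit step through the recursive form: k-th post-step value = 1 - 0.9^k
  step <- c(0, rep(1, 30))
  got <- exponential_filter(step, 0.1)
  expect_equal(got[-1], 1 - 0.9^(1:30), tolerance = 1e-12)
  # literal two-tap form blends with the raw previous sample
  expect_equal(exponential_filter(c(0, 1, 1, 1), 0.1, form = "two_tap"),
               c(0, 0.1, 1, 1))
  expect_error(exponential_filter(numeric(0), 0.1), "empty")
  expect_error(exponential_filter(1:5, 0), "0, 1")
})

test_that("filtering acts per axis and never increases total variation", {
  set.seed(5)
  M <- cbind(cumsum(rnorm(100)), cumsum(rnorm(100)), cumsum(rnorm(100)))
  FM <- exponential_filter(M, 0.3)
  expect_equal(FM[, 2], exponential_filter(M[, 2], 0.3))
  tv <- function(x) sum(abs(diff(x)))
  for (coef in c(0.05, 0.1, 0.5, 0.9)) {
    for (j in 1:3) {
      expect_lte(tv(exponential_filter(M[, j], coef)), tv(M[, j]) + 1e-12)
    }
  }
})

test_that("tangential velocity matches analytic speeds", {
  still <- matrix(1:3, 50, 3, byrow = TRUE)
  expect_equal(tangential_velocity(still, 400), rep(0, 50))
  # uniform straight-line motion, 100 mm per sample at 400 Hz
  line <- outer(0:20, c(100, 0, 0))
  v <- tangential_velocity(line, 400)
  expect_equal(v, rep(40000, 21))
  # circular motion: speed = r * omega
  r <- 50; omega <- 2 * pi  # one revolution per second
  tt <- seq(0, 1, by = 1 / 400)
  circ <- cbind(r * cos(omega * tt), r * sin(omega * tt), 0)
  v <- tangential_velocity(circ, 400)
  expect_equal(v[2:(length(v) - 1)], rep(r * omega, length(v) - 2),
               tolerance = 1e-3)
  expect_error(tangential_velocity(line[1, , drop = FALSE], 400),
               "at least 2")
})

test_that("threshold segmentation on an enumerated triangular profile", {
  v <- c(seq(0, 100, by = 5), seq(95, 0, by = -5))  # 41 samples, peak at 21
  seg <- segment_movement(v, threshold_frac = 0.05)
  expect_identical(seg$onset, 2L)       # first v >= 5
  expect_identical(seg$peak_index, 21L)
  expect_identical(seg$offset, 41L)     # first v < 5 after the peak
  expect_identical(seg$peak_count, 1L)
  expect_true(seg$valid)
  expect_false(seg$offset_clipped)
})

test_that("multi-peak profiles are invalid, single bells are not", {
  tt <- seq(0, 1, length.out = 101)
  bell <- sin(pi * tt)^2 * 100
  seg <- segment_movement(bell, 0.05)
  expect_true(seg$valid)
  # symmetric bell: time to peak is half the duration (within one sample)
  expect_lte(abs((seg$peak_index - seg$onset) -
                   (seg$offset - seg$onset) / 2), 1)
  two <- c(bell, rep(20, 10), bell)  # equal maxima, valley below half-max
  seg2 <- segment_movement(two, 0.05, peak_multiplicity_frac = 0.5)
  expect_identical(seg2$peak_count, 2L)
  expect_false(seg2$valid)
  # a noisy flat top is still a single peak
  set.seed(2)
  noisy <- pmax(bell + rnorm(101, 0, 0.5), 0)
  expect_identical(segment_movement(noisy, 0.05)$peak_count, 1L)
})

test_that("segmentation is invariant to uniform velocity rescaling", {
  set.seed(7)
  for (i in 1:20) {
    v <- abs(stats::filter(rexp(200), rep(1, 7), sides = 2))
    v[is.na(v)] <- 0
    s1 <- segment_movement(v, 0.05)
    s2 <- segment_movement(v * runif(1, 0.01, 100), 0.05)
    expect_identical(s1[c("onset", "offset", "peak_count")],
                     s2[c("onset", "offset", "peak_count")])
  }
  expect_error(segment_movement(rep(0, 10)), "no movement")
})

test_that("offset falls back to the final sample when velocity stays high", {
  v <- c(seq(0, 100, by = 10), rep(95, 10))
  expect_warning(seg <- segment_movement(v, 0.05), "final sample")
  expect_identical(seg$offset, length(v))
  expect_true(seg$offset_clipped)
})

test_that("temporal parameters of an exact constant-velocity movement", {
  # 300 mm in 600 ms: meanvel must be 500 mm/s; release at onset => cRT = RT
  tr <- make_straight_trial(move_mm = c(0, -300, 0), move_samples = 240L,
                            release_at = 38L, rt_raw_ms = 500)
  cfg <- run_config(filter_coefficient = 1)  # no smoothing: exact profile
  pp <- temporal_parameters(tr, cfg)
  expect_true(pp$valid)
  expect_equal(pp$distance_mm, 300, tolerance = 1e-6)
  expect_equal(pp$meanvel_mm_s, pp$distance_mm / (pp$dur_ms / 1000))
  expect_equal(pp$meanvel_mm_s, 500, tolerance = 0.02)
  expect_equal(pp$dur_ms, 600, tolerance = 600 * 0.02)
  # onset within a few samples of the release sample => cRT close to raw RT
  expect_lte(abs(pp$cRT_ms - 500), 3 * 2.5)
  expect_lte(pp$meanvel_mm_s, pp$maxvel_mm_s)
  expect_gt(pp$ttp_ms, 0)
  expect_lte(pp$ttp_ms, pp$dur_ms)
})

test_that("trials whose onset precedes button release are flagged", {
  tr <- make_straight_trial(release_at = 100L)  # release mid-movement
  pp <- temporal_parameters(tr, run_config(filter_coefficient = 1))
  expect_false(pp$valid)
  expect_match(pp$invalid_reason, "precedes")
})

test_that("resampling yields collinear equally spaced points ending at offset", {
  tr <- make_straight_trial()
  pos <- tr$led1
  # pure constant-velocity span: 240 sample steps from sample 41 to 281
  rs <- resample_trajectory(pos, tr$t, 41L, 281L, 20L)
  expect_identical(dim(rs), c(20L, 3L))
  steps <- diff(rs[, 2])
  expect_equal(steps, rep(steps[1], 19), tolerance = 1e-9)
  expect_equal(rs[, 1], rep(0, 20))  # collinear: x stays 0
  expect_equal(rs[20, ], pos[281L, ], tolerance = 1e-9)
  # segmentation-based span: final point within one raw step of the offset
  v <- tangential_velocity(pos, tr$sampling_rate_hz)
  seg <- segment_movement(v, 0.05)
  rs2 <- resample_trajectory(pos, tr$t, seg$onset, seg$offset, 20L)
  raw_step <- max(sqrt(rowSums(diff(pos)^2)))
  expect_lte(sqrt(sum((rs2[20, ] - pos[seg$offset, ])^2)), raw_step + 1e-9)
  expect_error(resample_trajectory(pos, tr$t, seg$onset, seg$offset, 1L),
               "at least 2")
})

test_that("straight-line distance never exceeds resampled path length", {
  set.seed(31)
  cfg <- small_config(seed = 31, n_participants = 1L, reps = 2L, blocks = 1L)
  ex <- generate_experiment(cfg)
  for (tr in ex$trials[1:6]) {
    pos <- exponential_filter(tr$led1, 0.1)
    v <- tangential_velocity(pos, tr$sampling_rate_hz)
    seg <- segment_movement(v, 0.05)
    rs <- resample_trajectory(pos, tr$t, seg$onset, seg$offset, 20L)
    chord <- sqrt(sum((pos[seg$offset, ] - pos[seg$onset, ])^2))
    path_len <- sum(sqrt(rowSums(diff(rbind(pos[seg$onset, ], rs))^2)))
    raw_len <- sum(sqrt(rowSums(
      diff(pos[seg$onset:seg$offset, , drop = FALSE])^2)))
    expect_lte(chord, path_len + 1e-9)
    expect_lte(path_len, raw_len + 1e-9)
  }
})

test_that("segmentation recovers generator ground truth within two samples", {
  # random bell-profile trials; reference = measurement model applied to the
  # noiseless trajectory (stochastic marker noise makes threshold crossings
  # jitter by ~1 sample, so accuracy is asserted as coverage, not worst case)
  set.seed(99)
  cfg <- generator_config(seed = 99)
  n_trials <- 200L
  err <- numeric(n_trials)
  rc <- run_config()
  for (i in seq_len(n_trials)) {
    tg <- sample(cfg$targets$target, 1)
    cond <- sample(cfg$conditions, 1)
    tr <- generate_trial("P01", cond, tg, 1L, cfg)
    gt <- attr(tr, "ground_truth")
    pos <- exponential_filter(tr$led1, rc$filter_coefficient)
    v <- tangential_velocity(pos, tr$sampling_rate_hz)
    seg <- segment_movement(v, rc$velocity_threshold_frac)
    err[i] <- (seg$offset - seg$onset) - (gt$ref_offset - gt$ref_onset)
  }
  expect_gte(mean(abs(err) <= 2), 0.95)
  expect_lte(stats::median(abs(err)), 1)
})
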