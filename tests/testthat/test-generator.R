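test_that("default design matches the experimental protocol", {
  d <- generate_design(generator_config(seed = 1))
  per <- split(d, d$participant)
  expect_length(per, 10L)
  for (dp in per) {
    expect_identical(nrow(dp), 300L)
    expect_identical(length(unique(dp$block)), 30L)
    expect_equal(as.vector(table(dp$condition)), rep(100L, 3),
                 ignore_attr = TRUE)
    cond_by_block <- table(unique(dp[, c("block", "condition")])$condition)
    expect_equal(as.vector(cond_by_block), rep(10L, 3), ignore_attr = TRUE)
    for (b in split(dp, dp$block)) {
      expect_identical(length(unique(b$condition)), 1L)
      expect_equal(as.vector(table(b$target)), rep(2L, 5),
                   ignore_attr = TRUE)
    }
  }
  # condition order of blocks is counterbalanced across participants
  first_conditions <- vapply(per, function(dp)
    dp$condition[dp$block == 1][1], "")
  expect_length(unique(first_conditions), 3L)
})

test_that("design balance holds for every seed", {
  for (seed in 1:50) {
    cfg <- generator_config(n_participants = 1L, seed = seed)
    d <- generate_design(cfg)
    expect_identical(nrow(d), 300L)
    blocks <- split(d$target, d$block)
    expect_length(blocks, 30L)
    expect_true(all(vapply(blocks, function(tg)
      all(table(tg) == 2L), TRUE)))
  }
})

test_that("zero-noise trials land exactly on the target", {
  cfg <- generator_config(
    marker_jitter_sd_mm = 0, endpoint_z_sd_mm = 0, trunk_jitter_sd_deg = 0,
    endpoint_model = list(
      LEFT_CP = list(orientation_deg = 72.8, axis_ratio = 0.25,
                     scale_mm = 0),
      RIGHT_CP = list(orientation_deg = 112.7, axis_ratio = 0.25,
                      scale_mm = 0),
      NCP = list(orientation_deg = 100.4, axis_ratio = 0.25,
                 scale_mm = 0)))
  set.seed(5)
  tr <- generate_trial("P01", "NCP", "glass", 1L, cfg)
  gt <- attr(tr, "ground_truth")
  target <- cfg$targets[cfg$targets$target == "glass", ]
  expect_equal(c(gt$endpoint_x, gt$endpoint_y), c(target$x, target$y))
  expect_equal(tr$led1[nrow(tr$led1), ], c(target$x, target$y, target$z),
               tolerance = 1e-9)
})

test_that("generated trials are valid single-peaked movements", {
  set.seed(6)
  cfg <- generator_config()
  rc <- run_config()
  for (i in 1:40) {
    tr <- generate_trial("P01", sample(cfg$conditions, 1),
                         sample(cfg$targets$target, 1), 1L, cfg)
    pos <- exponential_filter(tr$led1, rc$filter_coefficient)
    seg <- segment_movement(tangential_velocity(pos, tr$sampling_rate_hz),
                            rc$velocity_threshold_frac,
                            rc$peak_multiplicity_frac)
    expect_true(seg$valid)
    expect_gte(seg$onset, button_release_index(tr))
  }
})

test_that("endpoint sampler reproduces a configured orientation closely", {
  set.seed(7)
  pts <- generate_endpoints(10000, 112.7, axis_ratio = 0.25)
  expect_lte(axial_difference(covariance_ellipse(pts)$orientation_deg,
                              112.7), 1)
  # configured covariance is reproduced, not just the angle
  th <- 112.7 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expected <- R %*% diag(c(64, 16)) %*% t(R)
  expect_equal(stats::cov(pts), expected, tolerance = 0.05 * 64)
})

test_that("experiments are reproducible and carry ground truth", {
  cfg <- small_config(seed = 77, n_participants = 1L, reps = 2L, blocks = 1L)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$design, e2$design)
  expect_identical(lapply(e1$trials, `[[`, "led1"),
                   lapply(e2$trials, `[[`, "led1"))
  expect_identical(e1$ground_truth, e2$ground_truth)
  expect_identical(nrow(e1$ground_truth), length(e1$trials))
  expect_true(all(c("endpoint_x", "nominal_dur_ms", "ref_dur_ms",
                    "trunk_angle_deg", "outlier") %in%
                    names(e1$ground_truth)))
  # written datasets are byte-identical across runs with one seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_experiment(cfg, path = d1)
  generate_experiment(cfg, path = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_true(file.exists(file.path(d1, "ground_truth.csv")))
  expect_true(file.exists(file.path(d1, "generator_config.txt")))
})

test_that("outlier contamination produces far-field endpoints", {
  cfg <- generator_config(outlier_rate = 1, outlier_range_mm = c(50, 60))
  set.seed(8)
  tr <- generate_trial("P01", "NCP", "glass", 1L, cfg)
  gt <- attr(tr, "ground_truth")
  expect_true(gt$outlier)
  target <- cfg$targets[cfg$targets$target == "glass", ]
  offset <- sqrt((gt$endpoint_x - target$x)^2 + (gt$endpoint_y - target$y)^2)
  expect_gt(offset, 25)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(reps_per_target_per_condition = 15L,
                                blocks_per_condition = 10L), "multiple")
  expect_error(generator_config(conditions = c("A", "B", "C")),
               "three pointing conditions")
  em <- default_endpoint_model()
  names(em)[1] <- "OTHER"
  expect_error(generator_config(endpoint_model = em), "per condition")
})
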