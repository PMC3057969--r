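test_that("covariance, eigenstructure and Cook's distance match brute force", {
  set.seed(4)
  for (n in 4:6) {
    for (rep in 1:20) {
      p <- matrix(rnorm(2 * n, sd = runif(1, 0.5, 20)), n, 2)
      ell <- covariance_ellipse(p)
      expect_equal(ell$cov, cov_brute(p), tolerance = 1e-12)
      expect_equal(ell$eigenvalues, eig_brute(ell$cov), tolerance = 1e-12)
      flt <- cooks_outlier_filter(p, cutoff = Inf)
      expect_equal(flt$cooks_d,
                   pmax(cooks_brute(p[, 1]), cooks_brute(p[, 2])),
                   tolerance = 1e-12)
      # fast closed-form 2x2 path used inside the Monte-Carlo engine
      expect_equal(
        pointkin:::eig2_orientation_deg(ell$cov[1, 1], ell$cov[2, 2],
                                        ell$cov[1, 2]),
        ell$orientation_deg, tolerance = 1e-9)
      ev <- pointkin:::eig2_values(ell$cov[1, 1], ell$cov[2, 2],
                                   ell$cov[1, 2])
      expect_equal(c(ev$l1, ev$l2), ell$eigenvalues, tolerance = 1e-12)
    }
  }
})

test_that("degenerate and collinear clouds are handled", {
  line <- cbind(1:10, 1:10)
  ell <- covariance_ellipse(line)
  expect_equal(ell$orientation_deg, 45)
  expect_equal(ell$eigenvalues[2], 0, tolerance = 1e-12)
  grid <- as.matrix(expand.grid(x = -2:2, y = -2:2))
  iso <- covariance_ellipse(grid)
  expect_true(iso$degenerate)
  expect_error(covariance_ellipse(line[1:2, ]), "at least 3")
})

test_that("orientation is equivariant to rotation, invariant to the rest", {
  set.seed(8)
  pts <- generate_endpoints(200, orientation_deg = 30, axis_ratio = 0.2)
  base <- covariance_ellipse(pts)$orientation_deg
  for (theta in c(10, 45, 90, 137.5)) {
    th <- theta * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ctr <- colMeans(pts)
    rot <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr, `+`)
    expect_equal(covariance_ellipse(rot)$orientation_deg,
                 (base + theta) %% 180, tolerance = 1e-9)
  }
  shifted <- sweep(pts * 3.7, 2, c(120, -45), `+`)
  expect_equal(covariance_ellipse(shifted)$orientation_deg, base,
               tolerance = 1e-9)
  # reflection through the cloud mean leaves the axial orientation unchanged
  refl <- sweep(-sweep(pts, 2, colMeans(pts)), 2, colMeans(pts), `+`)
  expect_equal(covariance_ellipse(refl)$orientation_deg, base,
               tolerance = 1e-9)
})

test_that("orientation estimate is consistent as n grows", {
  set.seed(13)
  med_err <- vapply(c(20, 200, 2000), function(n) {
    errs <- replicate(200, {
      pts <- generate_endpoints(n, 100.4, axis_ratio = 0.25)
      axial_difference(covariance_ellipse(pts)$orientation_deg, 100.4)
    })
    stats::median(errs)
  }, 1)
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 1)
})

test_that("normalization fixes the first eigenvalue and keeps orientation", {
  ell <- pointkin:::ellipse_from_cov(diag(c(4, 1)))
  nrm <- normalize_matrix(ell)
  expect_equal(nrm$cov, diag(c(1, 0.25)))
  expect_equal(nrm$eigenvalues[1], 1)
  expect_true(nrm$normalized)
  set.seed(9)
  pts <- generate_endpoints(50, 72.8, 0.25, scale_mm = 11)
  e <- covariance_ellipse(pts)
  expect_equal(normalize_matrix(e)$orientation_deg, e$orientation_deg)
  degenerate_pt <- pointkin:::ellipse_from_cov(matrix(0, 2, 2))
  expect_error(normalize_matrix(degenerate_pt), "zero")
})

test_that("averaging normalized ellipses behaves like an axial mean", {
  e1 <- normalize_matrix(pointkin:::ellipse_from_cov(diag(c(4, 1))))
  expect_equal(average_ellipse(list(e1, e1))$cov, e1$cov)
  mk <- function(theta, ratio = 0.25) {
    th <- theta * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    normalize_matrix(pointkin:::ellipse_from_cov(
      R %*% diag(c(1, ratio)) %*% t(R)))
  }
  # symmetric pair about 90 degrees with equal anisotropy averages to 90
  expect_equal(average_ellipse(list(mk(80), mk(100)))$orientation_deg, 90,
               tolerance = 1e-9)
  # per-participant matrices scattered around a common axis recover it
  set.seed(22)
  members <- lapply(1:10, function(i)
    normalize_matrix(covariance_ellipse(
      generate_endpoints(60, 72.8 + rnorm(1, 0, 2), 0.25))))
  avg <- average_ellipse(members)
  expect_lte(axial_difference(avg$orientation_deg, 72.8), 2)
  expect_error(average_ellipse(list(mk(80),
                                    pointkin:::ellipse_from_cov(diag(2)))),
               "normalized")
})

test_that("axial differences wrap correctly", {
  expect_equal(axial_difference(72.8, 112.7), 39.9, tolerance = 1e-9)
  expect_equal(axial_difference(10, 170), 20)
  for (theta in c(0, 17.3, 90, 179.9)) {
    expect_equal(axial_difference(theta, theta), 0)
  }
  set.seed(6)
  a <- runif(50, 0, 360); b <- runif(50, -180, 180)
  expect_equal(axial_difference(a, b), axial_difference(b, a))
  expect_true(all(axial_difference(a, b) >= 0 & axial_difference(a, b) <= 90))
})

test_that("Cook's filter excludes exactly the influential points", {
  pts <- matrix(5, 6, 2)
  flt <- cooks_outlier_filter(pts, 0.25)
  expect_equal(flt$cooks_d, rep(0, 6))
  expect_identical(nrow(flt$kept), 6L)
  set.seed(14)
  cloud <- matrix(rnorm(38), 19, 2)
  far <- rbind(cloud, c(20, 20))
  expect_identical(cooks_outlier_filter(far, 0.25)$excluded_idx, 20L)
  # hand evaluation of the intercept-only formula for the far point
  D20 <- max(cooks_brute(far[, 1])[20], cooks_brute(far[, 2])[20])
  expect_gt(D20, 0.25)
  expect_identical(cooks_outlier_filter(far, Inf)$excluded_idx, integer(0))
  expect_error(cooks_outlier_filter(far[1:3, ], 0.25), "at least 4")
  # joint bivariate variant also catches the far point
  expect_true(20L %in%
                cooks_outlier_filter(far, 0.25,
                                     method = "mahalanobis")$excluded_idx)
})

test_that("trunk orientation is the axial shoulder-line angle", {
  expect_equal(trunk_orientation(c(-200, 0, 400), c(200, 0, 400)), 0)
  th <- 10 * pi / 180
  l3 <- c(200 * cos(th), 200 * sin(th), 400)
  expect_equal(trunk_orientation(l3, -l3 + c(0, 0, 800)), 10,
               tolerance = 1e-9)
  expect_error(trunk_orientation(c(0, 0, 400), c(0, 0, 300)), "coincide")
  # axial mean wraps across 0/180
  expect_equal(pointkin:::axial_mean_deg(c(1, 179)), 0, tolerance = 1e-9)
})
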