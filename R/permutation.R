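# Fast closed-form eigen/orientation math for 2x2 covariance matrices,
# vectorized across simulations. Verified against eigen() in the test suite.

# Covariance entries of row-wise resampled point sets, vectorized over
# simulations. `pool` is a centered k x 2 matrix; returns n_iter draws of
# size nd with replacement as covariance entry vectors.
sim_cov_entries <- function(pool, nd, n_iter) {
  k <- nrow(pool)
  idx <- sample.int(k, n_iter * nd, replace = TRUE)
  X <- matrix(pool[idx, 1], n_iter, nd)
  Y <- matrix(pool[idx, 2], n_iter, nd)
  mx <- rowMeans(X); my <- rowMeans(Y)
  list(sxx = (rowSums(X * X) - nd * mx^2) / (nd - 1),
       syy = (rowSums(Y * Y) - nd * my^2) / (nd - 1),
       sxy = (rowSums(X * Y) - nd * mx * my) / (nd - 1))
}

# Largest/smallest eigenvalues of symmetric 2x2 matrices, vectorized.
eig2_values <- function(sxx, syy, sxy) {
  tr2 <- (sxx + syy) / 2
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  list(l1 = tr2 + disc, l2 = tr2 - disc)
}

# Axial orientation (deg in [0, 180)) of the dominant eigenvector of
# symmetric 2x2 matrices, vectorized.
eig2_orientation_deg <- function(sxx, syy, sxy) {
  (0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi) %% 180
}

DEGENERATE_RATIO <- 0.999

#' Monte-Carlo test for a difference in average-ellipse orientation
#'
#' Tests whether the axial orientations of the across-subject average
#' tolerance ellipses of two conditions differ more than expected by chance.
#' The observed statistic is the axial difference between the two average
#' ellipses, each built by averaging the per-subject size-normalized endpoint
#' covariance matrices. Under the null hypothesis that each subject's two
#' endpoint samples come from one common distribution, simulated sample pairs
#' are drawn per subject, with replacement, from the union of that subject's
#' two samples (preserving the original per-condition sample sizes), the two
#' average ellipses are rebuilt, and the simulated orientation difference is
#' recorded. The p-value is N / n_sims where N counts simulations with a
#' difference at least as large as observed (ties count).
#'
#' Iterations that produce a degenerate (near-isotropic) or rank-zero ellipse,
#' whose orientation is undefined, are redrawn (up to \code{max_retries}
#' passes) and counted in the result.
#'
#' @param samples_a,samples_b Named lists (same subject names) of numeric
#'   endpoint matrices (>= 3 rows, 2 columns) for the two conditions.
#' @param n_sims Number of Monte-Carlo simulations.
#' @param seed Integer seed; identical seed and inputs give bit-identical
#'   results.
#' @param condition_pair Optional label, e.g. \code{"LEFT_CP vs RIGHT_CP"}.
#' @param max_retries Maximum redraw passes for degenerate iterations.
#' @return An object of class \code{"permutation_result"}: a list with
#'   \code{condition_pair}, \code{observed_diff_deg}, \code{orientation_a},
#'   \code{orientation_b}, \code{n_sims}, \code{exceed_count},
#'   \code{p_value}, \code{seed}, \code{degenerate_redraws}.
#' @export
permutation_orientation_test <- function(samples_a, samples_b,
                                         n_sims = 10000L, seed = NULL,
                                         condition_pair = NULL,
                                         max_retries = 100L) {
  subjects <- align_subjects(samples_a, samples_b)
  samples_a <- lapply(samples_a[subjects], as.matrix)
  samples_b <- lapply(samples_b[subjects], as.matrix)
  for (s in subjects) {
    if (nrow(samples_a[[s]]) < 3L || nrow(samples_b[[s]]) < 3L)
      stop("subject '", s, "' has fewer than 3 endpoints in a condition")
  }
  # observed statistic through the public ellipse path
  avg_a <- average_ellipse(lapply(samples_a, function(p)
    normalize_matrix(covariance_ellipse(p))))
  avg_b <- average_ellipse(lapply(samples_b, function(p)
    normalize_matrix(covariance_ellipse(p))))
  if (avg_a$degenerate || avg_b$degenerate)
    stop("average ellipse is degenerate (near-isotropic); ",
         "orientation difference is undefined for these data")
  observed <- axial_difference(avg_a$orientation_deg, avg_b$orientation_deg)

  pools <- lapply(subjects, function(s) {
    p <- rbind(samples_a[[s]], samples_b[[s]])
    sweep(p, 2, colMeans(p))  # centering stabilizes the moment sums
  })
  n_a <- vapply(samples_a, nrow, 1L)
  n_b <- vapply(samples_b, nrow, 1L)
  ns <- length(subjects)

  run_sims <- function(n_iter) {
    acc <- list(a = list(sxx = 0, syy = 0, sxy = 0),
                b = list(sxx = 0, syy = 0, sxy = 0))
    bad <- logical(n_iter)
    for (j in seq_len(ns)) {
      for (side in c("a", "b")) {
        nd <- if (side == "a") n_a[j] else n_b[j]
        cv <- sim_cov_entries(pools[[j]], nd, n_iter)
        ev <- eig2_values(cv$sxx, cv$syy, cv$sxy)
        bad <- bad | ev$l1 <= 0 | (ev$l2 / ev$l1) > DEGENERATE_RATIO
        l1 <- ifelse(ev$l1 > 0, ev$l1, 1)
        acc[[side]]$sxx <- acc[[side]]$sxx + cv$sxx / l1
        acc[[side]]$syy <- acc[[side]]$syy + cv$syy / l1
        acc[[side]]$sxy <- acc[[side]]$sxy + cv$sxy / l1
      }
    }
    th <- diffs <- NULL
    for (side in c("a", "b")) {
      a <- acc[[side]]
      ev <- eig2_values(a$sxx / ns, a$syy / ns, a$sxy / ns)
      bad <- bad | (ev$l2 / ev$l1) > DEGENERATE_RATIO
      th[[side]] <- eig2_orientation_deg(a$sxx, a$syy, a$sxy)
    }
    list(diff = axial_difference(th[["a"]], th[["b"]]), bad = bad)
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- run_sims(n_sims)
  redraws <- 0L
  tries <- 0L
  while (any(res$bad) && tries < max_retries) {
    tries <- tries + 1L
    ii <- which(res$bad)
    redraws <- redraws + length(ii)
    patch <- run_sims(length(ii))
    res$diff[ii] <- patch$diff
    res$bad[ii] <- patch$bad
  }
  if (any(res$bad))
    stop("degenerate simulated ellipses persisted after ", max_retries,
         " redraw passes; data are too close to isotropic")
  N <- sum(res$diff >= observed)
  structure(
    list(condition_pair = condition_pair %||% "a vs b",
         observed_diff_deg = observed,
         orientation_a = avg_a$orientation_deg,
         orientation_b = avg_b$orientation_deg,
         n_sims = as.integer(n_sims),
         exceed_count = as.integer(N),
         p_value = N / n_sims,
         seed = seed,
         degenerate_redraws = redraws),
    class = "permutation_result")
}

#' Monte-Carlo test for a difference in mean axial angle
#'
#' Same within-subject union-resampling scheme as
#' \code{\link{permutation_orientation_test}}, applied to scalar axial angles
#' (such as per-trial trunk orientations): the statistic is the axial
#' difference between the across-subject means of per-subject axial mean
#' angles in the two conditions.
#'
#' @param angles_a,angles_b Named lists (same subject names) of numeric
#'   vectors of angles in degrees.
#' @inheritParams permutation_orientation_test
#' @return A \code{"permutation_result"} object.
#' @export
permutation_angle_test <- function(angles_a, angles_b, n_sims = 10000L,
                                   seed = NULL, condition_pair = NULL) {
  subjects <- align_subjects(angles_a, angles_b)
  angles_a <- angles_a[subjects]
  angles_b <- angles_b[subjects]
  ns <- length(subjects)
  subj_axial <- function(x) axial_mean_deg(x)
  obs_a <- axial_mean_deg(vapply(angles_a, subj_axial, 1))
  obs_b <- axial_mean_deg(vapply(angles_b, subj_axial, 1))
  observed <- axial_difference(obs_a, obs_b)

  pools2 <- lapply(subjects, function(s)
    c(angles_a[[s]], angles_b[[s]]) * pi / 90)  # doubled angles, radians
  n_a <- vapply(angles_a, length, 1L)
  n_b <- vapply(angles_b, length, 1L)

  if (!is.null(seed)) set.seed(as.integer(seed))
  accs <- list(a = list(C = 0, S = 0), b = list(C = 0, S = 0))
  for (j in seq_len(ns)) {
    pool <- pools2[[j]]
    k <- length(pool)
    for (side in c("a", "b")) {
      nd <- if (side == "a") n_a[j] else n_b[j]
      idx <- sample.int(k, n_sims * nd, replace = TRUE)
      A <- matrix(pool[idx], n_sims, nd)
      # per-subject axial mean direction, unit weight per subject
      ang <- atan2(rowMeans(sin(A)), rowMeans(cos(A)))
      accs[[side]]$C <- accs[[side]]$C + cos(ang)
      accs[[side]]$S <- accs[[side]]$S + sin(ang)
    }
  }
  th_a <- (atan2(accs$a$S, accs$a$C) * 90 / pi) %% 180
  th_b <- (atan2(accs$b$S, accs$b$C) * 90 / pi) %% 180
  N <- sum(axial_difference(th_a, th_b) >= observed)
  structure(
    list(condition_pair = condition_pair %||% "a vs b",
         observed_diff_deg = observed,
         orientation_a = obs_a,
         orientation_b = obs_b,
         n_sims = as.integer(n_sims),
         exceed_count = as.integer(N),
         p_value = N / n_sims,
         seed = seed,
         degenerate_redraws = 0L),
    class = "permutation_result")
}

align_subjects <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("samples must be named lists keyed by subject")
  only <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
  if (length(only) > 0)
    stop("subject(s) present in only one condition: ",
         paste(sort(unique(only)), collapse = ", "))
  sort(names(a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo orientation test (%s):\n  observed difference %.1f deg (%.1f vs %.1f), N = %d / %d, p = %.4g\n",
    x$condition_pair, x$observed_diff_deg, x$orientation_a, x$orientation_b,
    x$exceed_count, x$n_sims, x$p_value))
  if (x$degenerate_redraws > 0)
    cat(sprintf("  (%d degenerate iterations redrawn)\n",
                x$degenerate_redraws))
  invisible(x)
}
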