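# Internal: axial angle (degrees in [0, 180)) of a 2-vector vs the x-axis.
axial_angle_deg <- function(v) {
  (atan2(v[2], v[1]) * 180 / pi) %% 180
}

# Internal: build a tolerance_ellipse from a 2x2 covariance matrix.
# Eigenvalues are sorted decreasingly; the orientation is the axial angle of
# the dominant eigenvector. Near-isotropic matrices (lambda2/lambda1 beyond
# `degenerate_ratio`) are flagged: their orientation is numerically defined
# but statistically meaningless.
ellipse_from_cov <- function(cov, n = NA_integer_, normalized = FALSE,
                             excluded_count = 0L, degenerate_ratio = 0.999) {
  cov <- (cov + t(cov)) / 2
  e <- eigen(cov, symmetric = TRUE)
  if (e$values[1] < 0 && e$values[1] > -1e-12) e$values[] <- pmax(e$values, 0)
  structure(
    list(cov = cov,
         eigenvalues = e$values,
         eigenvectors = e$vectors,
         orientation_deg = axial_angle_deg(e$vectors[, 1]),
         degenerate = e$values[1] > 0 &&
           e$values[2] / e$values[1] > degenerate_ratio,
         normalized = normalized,
         n = as.integer(n),
         excluded_count = as.integer(excluded_count)),
    class = "tolerance_ellipse")
}

#' Tolerance ellipse of a 2D endpoint cloud
#'
#' Summarises the trial-to-trial scatter of fingertip endpoints as the
#' unbiased sample covariance of their (x, y) coordinates. The ellipse axes
#' are the eigenvectors of that 2x2 matrix, scaled by its eigenvalues; the
#' orientation is the axial angle (modulo 180 degrees) between the dominant
#' eigenvector and the frontal plane's horizontal trace (the x-axis).
#' Near-isotropic clouds, whose orientation is unstable, carry a
#' \code{degenerate} flag.
#'
#' @param points Numeric matrix or data frame with >= 3 rows and 2 columns
#'   (x, y in mm).
#' @return An object of class \code{"tolerance_ellipse"} with components
#'   \code{cov}, \code{eigenvalues} (decreasing), \code{eigenvectors},
#'   \code{orientation_deg} in [0, 180), \code{degenerate},
#'   \code{normalized}, \code{n}.
#' @examples
#' pts <- cbind(1:10, (1:10) + rnorm(10, 0, 1e-3))
#' covariance_ellipse(pts)$orientation_deg  # ~45
#' @export
covariance_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 endpoints")
  if (ncol(points) != 2L) stop("endpoints must have 2 columns (x, y)")
  if (any(!is.finite(points))) stop("endpoints must be finite")
  ellipse_from_cov(stats::cov(points), n = nrow(points))
}

#' Normalize a tolerance ellipse for size
#'
#' Divides the covariance matrix by its first (largest) eigenvalue so that
#' ellipses of different overall sizes become comparable in shape and
#' orientation. Orientation is unchanged.
#'
#' @param ellipse A \code{\link{covariance_ellipse}} result.
#' @return A \code{tolerance_ellipse} with largest eigenvalue 1 and
#'   \code{normalized = TRUE}.
#' @export
normalize_matrix <- function(ellipse) {
  stopifnot(inherits(ellipse, "tolerance_ellipse"))
  l1 <- ellipse$eigenvalues[1]
  if (l1 <= 0) stop("cannot normalize: largest eigenvalue is zero")
  ellipse_from_cov(ellipse$cov / l1, n = ellipse$n, normalized = TRUE,
                   excluded_count = ellipse$excluded_count)
}

#' Average of normalized tolerance ellipses
#'
#' Element-wise mean of the (size-normalized) covariance matrices, followed
#' by a fresh eigen-decomposition. Mixing normalized and unnormalized
#' matrices is an error. Degenerate members are dropped with a warning
#' (their orientation carries no information).
#'
#' @param ellipses List of normalized \code{tolerance_ellipse} objects.
#' @return A \code{tolerance_ellipse} for the average matrix.
#' @export
average_ellipse <- function(ellipses) {
  stopifnot(is.list(ellipses), length(ellipses) >= 1L,
            all(vapply(ellipses, inherits, TRUE, "tolerance_ellipse")))
  norm <- vapply(ellipses, `[[`, TRUE, "normalized")
  if (!all(norm))
    stop("all ellipses must be normalized before averaging ",
         "(see normalize_matrix)")
  degen <- vapply(ellipses, `[[`, TRUE, "degenerate")
  if (any(degen)) {
    warning(sum(degen), " degenerate (near-isotropic) ellipse(s) ",
            "dropped from the average")
    ellipses <- ellipses[!degen]
    if (length(ellipses) == 0L)
      stop("all ellipses are degenerate; average orientation undefined")
  }
  mats <- lapply(ellipses, `[[`, "cov")
  avg <- Reduce(`+`, mats) / length(mats)
  ellipse_from_cov(avg, n = length(mats))
}

#' Axial difference between two orientations
#'
#' Difference between two undirected line orientations (defined modulo 180
#' degrees), as for ellipse major axes: the result lies in [0, 90] and is
#' symmetric in its arguments.
#'
#' @param a_deg,b_deg Orientations in degrees (wrapped into [0, 180)).
#' @return Difference in degrees, in [0, 90].
#' @examples
#' axial_difference(72.8, 112.7)  # 39.9
#' axial_difference(10, 170)      # 20, wrapping across 180
#' @export
axial_difference <- function(a_deg, b_deg) {
  d <- abs((a_deg %% 180) - (b_deg %% 180))
  pmin(d, 180 - d)
}

#' Cook's-distance outlier filter for 2D endpoints
#'
#' Flags endpoints with excessive influence on the overall distribution.
#' With the default \code{"per_axis"} method each coordinate is fit with an
#' intercept-only model and the classical Cook's distance
#' \eqn{D_i = (e_i^2 / (p s^2)) h / (1-h)^2} (leverage \eqn{h = 1/n}) is
#' computed per axis; a point is excluded when the larger of its two
#' distances exceeds the cutoff. The \code{"mahalanobis"} method uses the
#' joint bivariate analogue with the squared Mahalanobis distance in place of
#' the squared standardized residual. Exclusion is a single pass: distances
#' are not recomputed after removal.
#'
#' @param points Numeric matrix or data frame, >= 4 rows, 2 columns.
#' @param cutoff Exclusion threshold (default 0.25).
#' @param method \code{"per_axis"} or \code{"mahalanobis"}.
#' @return A list with \code{kept} and \code{excluded} point matrices,
#'   \code{cooks_d} (the per-point criterion value) and \code{excluded_idx}.
#' @export
cooks_outlier_filter <- function(points, cutoff = 0.25,
                                 method = c("per_axis", "mahalanobis")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4L) stop("need at least 4 endpoints for influence analysis")
  if (ncol(points) != 2L) stop("endpoints must have 2 columns (x, y)")
  if (any(!is.finite(points))) stop("endpoints must be finite")
  if (method == "per_axis") {
    d <- apply(points, 2, function(x) {
      if (stats::var(x) == 0) rep(0, n)
      else stats::cooks.distance(stats::lm(x ~ 1))
    })
    D <- pmax(d[, 1], d[, 2])
  } else {
    S <- stats::cov(points)
    h <- 1 / n
    d2 <- stats::mahalanobis(points, colMeans(points), S)
    D <- (d2 / 2) * h / (1 - h)^2
  }
  excl <- as.integer(which(unname(D) > cutoff))
  list(kept = points[setdiff(seq_len(n), excl), , drop = FALSE],
       excluded = points[excl, , drop = FALSE],
       cooks_d = as.numeric(D),
       excluded_idx = excl)
}

#' Trunk orientation from the shoulder markers
#'
#' Axial angle in [0, 180) between the horizontal projection of the
#' shoulder-to-shoulder vector (left minus right shoulder marker) and the
#' x-axis. Used to check that endpoint-variability differences between
#' conditions are not driven by a rotated initial posture.
#'
#' @param led3,led4 3-vectors (mm): left and right shoulder marker positions.
#' @return Angle in degrees, in [0, 180).
#' @export
trunk_orientation <- function(led3, led4) {
  v <- (led3 - led4)[1:2]
  if (sqrt(sum(v^2)) < .Machine$double.eps^0.5)
    stop("shoulder markers coincide in the horizontal plane")
  axial_angle_deg(v)
}

# Axial mean of angles in degrees: directions are doubled, averaged as unit
# vectors, and halved back, so 1 and 179 average to 0, not 90.
axial_mean_deg <- function(a_deg) {
  two <- a_deg * pi / 90
  (atan2(mean(sin(two)), mean(cos(two))) * 90 / pi) %% 180
}

#' @export
print.tolerance_ellipse <- function(x, ...) {
  cat(sprintf(
    "Tolerance ellipse (n = %s%s): orientation %.1f deg, axes %.3g / %.3g%s%s\n",
    ifelse(is.na(x$n), "?", x$n),
    if (x$excluded_count > 0) sprintf(", %d excluded", x$excluded_count) else "",
    x$orientation_deg, x$eigenvalues[1], x$eigenvalues[2],
    if (x$normalized) ", normalized" else "",
    if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' 95% tolerance-region ellipse outline (for plotting)
#'
#' Points on the boundary of the 95% tolerance region implied by a covariance
#' matrix: axes are the eigenvectors scaled by
#' \eqn{\sqrt{\lambda \chi^2_{2,0.95}}}. Reporting only; no statistic in the
#' package depends on this scaling.
#'
#' @param ellipse A \code{tolerance_ellipse}.
#' @param center Ellipse center (length-2, default origin).
#' @param n_points Number of boundary points.
#' @return An n x 2 matrix of boundary coordinates.
#' @export
ellipse_outline <- function(ellipse, center = c(0, 0), n_points = 180L) {
  stopifnot(inherits(ellipse, "tolerance_ellipse"))
  r <- sqrt(stats::qchisq(0.95, df = 2) * pmax(ellipse$eigenvalues, 0))
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(r[1] * cos(th), r[2] * sin(th))
  t(ellipse$eigenvectors %*% circ + center)
}
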