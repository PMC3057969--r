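#' Exponential smoothing filter
#'
#' Smooths a coordinate series with the blend
#' \eqn{xx_i = xx_{i-1} + (x_i - xx_{i-1}) c}, initialized at the first
#' sample, applied independently per coordinate axis. With coefficient 1 the
#' series is returned unchanged. The \code{"two_tap"} form blends with the raw
#' (not the filtered) previous sample, \eqn{xx_i = x_{i-1} + (x_i - x_{i-1}) c},
#' which delays by roughly one sample but barely smooths; the recursive
#' exponential form is the default.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param coefficient Blend fraction in (0, 1].
#' @param form \code{"recursive"} (exponential) or \code{"two_tap"} (literal
#'   previous-raw-sample blend).
#' @return Filtered series, same shape as \code{x}; the first element equals
#'   the first input.
#' @examples
#' exponential_filter(c(0, 1, 1, 1), 0.1)  # approaches 1 geometrically
#' @export
exponential_filter <- function(x, coefficient = 0.1,
                               form = c("recursive", "two_tap")) {
  form <- match.arg(form)
  if (length(x) == 0) stop("empty series")
  if (!is.finite(coefficient) || coefficient <= 0 || coefficient > 1)
    stop("'coefficient' must lie in (0, 1]")
  if (is.matrix(x)) {
    out <- apply(x, 2, exponential_filter, coefficient = coefficient,
                 form = form)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n == 1L || coefficient == 1) return(x)
  if (form == "recursive") {
    y <- stats::filter(coefficient * x, 1 - coefficient,
                       method = "recursive", init = x[1])
    as.numeric(y)
  } else {
    c(x[1], x[-n] + coefficient * diff(x))
  }
}

#' Tangential velocity of a 3D trajectory
#'
#' Euclidean norm of the time derivative of the (filtered) marker position:
#' central differences on interior samples, one-sided differences at the two
#' boundaries, scaled by the sampling rate.
#'
#' @param trajectory Numeric matrix, one row per sample, columns = coordinates.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Nonnegative numeric vector, one speed (mm/s for mm input) per sample.
#' @export
tangential_velocity <- function(trajectory, sampling_rate_hz) {
  trajectory <- as.matrix(trajectory)
  n <- nrow(trajectory)
  if (n < 2L) stop("need at least 2 samples")
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling rate must be positive")
  d <- matrix(0, n, ncol(trajectory))
  d[1, ] <- (trajectory[2, ] - trajectory[1, ]) * sampling_rate_hz
  d[n, ] <- (trajectory[n, ] - trajectory[n - 1, ]) * sampling_rate_hz
  if (n > 2L)
    d[2:(n - 1), ] <- (trajectory[3:n, , drop = FALSE] -
                         trajectory[1:(n - 2), , drop = FALSE]) *
      (sampling_rate_hz / 2)
  sqrt(rowSums(d^2))
}

#' Segment a movement by a relative velocity threshold
#'
#' Movement onset is the first sample at which tangential velocity reaches
#' the given fraction of its maximum; offset is the first sample after the
#' global maximum at which it drops below that fraction again (the final
#' sample, with a warning, if it never does). Trials whose velocity profile
#' has more than one distinct peak above \code{peak_multiplicity_frac} of
#' the global maximum are flagged invalid (target-selection errors produce
#' multi-peaked profiles). Peaks are counted as the number of separate
#' excursions of the velocity above that fraction, so local maxima are only
#' distinct when the velocity dips below the multiplicity threshold between
#' them; counting raw local maxima would flag every flat noisy peak.
#'
#' @param velocity Nonnegative numeric vector of tangential speeds.
#' @param threshold_frac Onset/offset threshold as a fraction of peak speed.
#' @param peak_multiplicity_frac Fraction of peak speed above which local
#'   maxima are counted toward the multi-peak invalidity rule.
#' @return A list with components \code{onset}, \code{offset},
#'   \code{peak_index}, \code{maxvel}, \code{peak_count}, \code{valid},
#'   \code{offset_clipped}.
#' @export
segment_movement <- function(velocity, threshold_frac = 0.05,
                             peak_multiplicity_frac = 0.5) {
  v <- as.numeric(velocity)
  if (length(v) < 2L) stop("need at least 2 velocity samples")
  if (any(!is.finite(v)) || any(v < 0))
    stop("velocity must be finite and nonnegative")
  maxvel <- max(v)
  if (maxvel <= 0) stop("no movement: velocity is identically zero")
  thr <- threshold_frac * maxvel
  peak_index <- which.max(v)
  onset <- which(v >= thr)[1]
  after <- which(v[peak_index:length(v)] < thr)
  offset_clipped <- length(after) == 0L
  if (offset_clipped) {
    warning("velocity never fell below threshold after the peak; ",
            "using the final sample as offset")
    offset <- length(v)
  } else {
    offset <- peak_index + after[1] - 1L
  }
  high <- v >= peak_multiplicity_frac * maxvel
  runs <- rle(high)
  peak_count <- sum(runs$values)
  list(onset = onset, offset = offset, peak_index = peak_index,
       maxvel = maxvel, peak_count = peak_count,
       valid = peak_count == 1L, offset_clipped = offset_clipped)
}

#' Temporal movement parameters of one trial
#'
#' Filters the fingertip trajectory, computes tangential velocity, segments
#' the movement, and derives the temporal parameters: corrected reaction time
#' (raw RT plus the gap between button release and movement onset), movement
#' duration between the threshold crossings, time to peak velocity, peak
#' velocity, straight-line start-to-end distance, and mean velocity
#' (distance/duration). A trial is flagged invalid when its velocity profile
#' is multi-peaked or its detected onset precedes the button release.
#'
#' @param trial A \code{\link{trial_recording}}.
#' @param config A \code{\link{run_config}}.
#' @return A one-row data frame of class \code{"segmented_movement"} with
#'   columns participant, condition, target, block, valid, invalid_reason,
#'   onset_index, offset_index, peak_count, cRT_ms, dur_ms, ttp_ms,
#'   maxvel_mm_s, meanvel_mm_s, distance_mm.
#' @export
temporal_parameters <- function(trial, config = run_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  pos <- exponential_filter(trial$led1, config$filter_coefficient,
                            config$filter_form)
  v <- tangential_velocity(pos, trial$sampling_rate_hz)
  seg <- segment_movement(v, config$velocity_threshold_frac,
                          config$peak_multiplicity_frac)
  release <- button_release_index(trial)
  onset_after_release <- seg$onset >= release
  valid <- seg$valid && onset_after_release
  reason <- if (valid) ""
            else if (!seg$valid) "multiple velocity peaks"
            else "onset precedes button release"
  gap_ms <- (trial$t[seg$onset] - trial$t[release]) * 1000
  dur_ms <- (trial$t[seg$offset] - trial$t[seg$onset]) * 1000
  ttp_ms <- (trial$t[seg$peak_index] - trial$t[seg$onset]) * 1000
  distance_mm <- sqrt(sum((pos[seg$offset, ] - pos[seg$onset, ])^2))
  out <- data.frame(
    participant = trial$participant,
    condition = trial$condition,
    target = trial$target,
    block = trial$block,
    valid = valid,
    invalid_reason = reason,
    onset_index = seg$onset,
    offset_index = seg$offset,
    peak_count = seg$peak_count,
    cRT_ms = trial$rt_raw_ms + gap_ms,
    dur_ms = dur_ms,
    ttp_ms = ttp_ms,
    maxvel_mm_s = seg$maxvel,
    meanvel_mm_s = distance_mm / (dur_ms / 1000),
    distance_mm = distance_mm,
    stringsAsFactors = FALSE)
  class(out) <- c("segmented_movement", class(out))
  out
}

#' Resample a movement to equal time intervals
#'
#' Isolates \code{n_points} positions along the segmented movement at times
#' onset + k * duration / n_points, k = 1..n_points, linearly interpolating
#' between raw samples. The last point coincides with the offset sample.
#'
#' @param trajectory Numeric matrix of positions (one row per sample).
#' @param t Sample times (seconds), same length as rows of \code{trajectory}.
#' @param onset,offset Sample indices delimiting the movement.
#' @param n_points Number of resampled points (default 20).
#' @return An \code{n_points} x ncol matrix of interpolated positions.
#' @export
resample_trajectory <- function(trajectory, t, onset, offset, n_points = 20L) {
  trajectory <- as.matrix(trajectory)
  if (n_points < 2L) stop("'n_points' must be at least 2")
  if (offset - onset < 1L) stop("segmented span must cover at least 2 samples")
  dur <- t[offset] - t[onset]
  times <- t[onset] + seq_len(n_points) * dur / n_points
  out <- vapply(seq_len(ncol(trajectory)), function(j) {
    stats::approx(t, trajectory[, j], xout = times, rule = 2)$y
  }, numeric(n_points))
  matrix(out, nrow = n_points)
}

#' @export
print.segmented_movement <- function(x, ...) {
  print.data.frame(x, ...)
  invisible(x)
}
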