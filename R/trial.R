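#' Experimental conditions
#'
#' The three pointing conditions: communicative pointing addressed to the
#' left or right addressee, and non-communicative pointing.
#' @export
POINTING_CONDITIONS <- c("LEFT_CP", "RIGHT_CP", "NCP")

#' A single recorded pointing trial
#'
#' Bundles the multi-marker 3D time series of one trial with its metadata.
#' Marker 1 is the fingertip LED, marker 2 the button-state LED (on while the
#' answer button is held down), markers 3 and 4 the left and right shoulder
#' LEDs. Coordinates are in millimetres in the participant-centred frame:
#' origin at the fingertip on the depressed button, x from the participant's
#' right to left (parallel to the shoulder line), y from front to back,
#' z from bottom to top. Time is in seconds.
#'
#' @param participant Participant identifier (character scalar).
#' @param condition One of \code{\link{POINTING_CONDITIONS}}.
#' @param target Target object label.
#' @param block Block index (1-based integer).
#' @param rt_raw_ms Raw reaction time in milliseconds (stimulus onset to
#'   button release, as measured by the stimulus software).
#' @param t Sample times in seconds, strictly increasing and uniform.
#' @param led1,led3,led4 Numeric matrices with one row per sample and columns
#'   x, y, z (mm).
#' @param led2_on Logical vector: TRUE while the answer button is held down.
#'   Must switch from TRUE to FALSE exactly once (the button release).
#' @param sampling_rate_hz Sampling rate in Hz (default 400).
#'
#' @return An object of class \code{"trial_recording"}.
#' @export
trial_recording <- function(participant, condition, target, block, rt_raw_ms,
                            t, led1, led2_on, led3, led4,
                            sampling_rate_hz = 400) {
  tr <- structure(
    list(participant = as.character(participant),
         condition = as.character(condition),
         target = as.character(target),
         block = as.integer(block),
         rt_raw_ms = as.numeric(rt_raw_ms),
         t = as.numeric(t),
         led1 = as.matrix(led1),
         led2_on = as.logical(led2_on),
         led3 = as.matrix(led3),
         led4 = as.matrix(led4),
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "trial_recording")
  validate_trial(tr)
  tr
}

# Validates trial invariants; `where` prefixes error messages with file
# provenance when called from the reader. Returns the trial invisibly.
validate_trial <- function(tr, where = NULL) {
  loc <- function(line = NULL) {
    if (is.null(where)) ""
    else if (is.null(line)) paste0(" [", where, "]")
    else paste0(" [", where, ", line ", line, "]")
  }
  n <- length(tr$t)
  if (n < 2L) stop("trial has fewer than 2 samples", loc())
  if (!(tr$condition %in% POINTING_CONDITIONS))
    stop("unknown condition '", tr$condition, "'", loc())
  if (!is.finite(tr$sampling_rate_hz) || tr$sampling_rate_hz <= 0)
    stop("sampling rate must be positive", loc())
  dt <- diff(tr$t)
  step <- 1 / tr$sampling_rate_hz
  bad <- which(dt <= 0)
  if (length(bad) > 0)
    stop("timestamps not strictly increasing", loc(bad[1] + 2L))
  bad <- which(abs(dt - step) > 1e-9)
  if (length(bad) > 0)
    stop("timestamps not uniform at ", format(tr$sampling_rate_hz),
         " Hz", loc(bad[1] + 2L))
  for (m in c("led1", "led3", "led4")) {
    M <- tr[[m]]
    if (!is.numeric(M) || nrow(M) != n || ncol(M) != 3L)
      stop(m, " must be an n x 3 numeric matrix", loc())
    bad <- which(!is.finite(M))
    if (length(bad) > 0)
      stop("non-finite coordinate in ", m, loc(((bad[1] - 1L) %% n) + 2L))
  }
  if (length(tr$led2_on) != n || anyNA(tr$led2_on))
    stop("led2_on must be a logical vector matching the samples", loc())
  trans <- diff(tr$led2_on)
  if (sum(trans == -1) != 1L || any(trans == 1))
    stop("led2_on must switch from on to off exactly once", loc())
  invisible(tr)
}

#' Index of the button-release sample
#'
#' First sample at which the button-state LED is off, i.e. the sample after
#' the single on-to-off transition.
#' @param trial A \code{\link{trial_recording}}.
#' @return Integer sample index.
#' @export
button_release_index <- function(trial) {
  which(!trial$led2_on)[1]
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "Pointing trial: participant %s, %s, target '%s', block %d\n",
    x$participant, x$condition, x$target, x$block))
  cat(sprintf("  %d samples at %g Hz (%.3f s), raw RT %.0f ms\n",
              length(x$t), x$sampling_rate_hz, diff(range(x$t)), x$rt_raw_ms))
  invisible(x)
}
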