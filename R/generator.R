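#' Configuration of the synthetic pointing experiment
#'
#' Describes a complete simulated experiment with known ground truth: a
#' balanced block design (10 participants, 3 conditions, 5 targets in a cross
#' arrangement, 20 repetitions per target and condition grouped into 30
#' blocks), minimum-jerk reaches sampled at 400 Hz with marker jitter, and
#' condition-dependent anisotropic 2D endpoint scatter around the target.
#'
#' The default per-condition endpoint orientations (72.8, 112.7 and 100.4
#' degrees for left-addressee, right-addressee and non-communicative pointing)
#' are the configured ground truth used by the package's recovery studies.
#' The nominal movement duration of a trial is defined as the time between
#' the 5%-of-peak velocity crossings of the ideal continuous speed profile;
#' the generator additionally records reference onset/offset samples obtained
#' by applying the measurement model (exponential filter, tangential
#' velocity, relative threshold) to the noiseless trajectory.
#'
#' @param n_participants Number of simulated participants.
#' @param conditions Condition labels (fixed to the three pointing
#'   conditions).
#' @param reps_per_target_per_condition Repetitions of each target in each
#'   condition (must be a multiple of \code{blocks_per_condition}).
#' @param blocks_per_condition Blocks per condition.
#' @param targets Data frame with columns target, x, y, z (mm) and
#'   \code{central}; the default places the round glass at the array center
#'   and four items 100 mm away along the array axes.
#' @param endpoint_model Named list (one entry per condition) of lists with
#'   \code{orientation_deg} (major-axis axial angle vs the x-axis),
#'   \code{axis_ratio} (minor/major eigenvalue ratio) and \code{scale_mm}
#'   (major-axis standard deviation).
#' @param start Fingertip start position (the button), mm.
#' @param duration_mean_ms,duration_sd_ms Nominal movement duration
#'   distribution (truncated below at 300 ms).
#' @param rt_mean_ms,rt_sd_ms Raw reaction-time distribution (truncated below
#'   at 200 ms).
#' @param gap_range_ms Uniform range of the button-release-to-onset gap.
#' @param lift_mm Peak height of the vertical arc of the reach.
#' @param marker_jitter_sd_mm Isotropic per-sample marker noise SD.
#' @param endpoint_z_sd_mm SD of the vertical endpoint scatter at contact.
#' @param pre_ms,post_ms Stationary recording padding before release and
#'   after movement end.
#' @param sampling_rate_hz Sampling rate (400 Hz).
#' @param shoulder_left,shoulder_right Shoulder marker positions, mm.
#' @param trunk_jitter_sd_deg Per-trial SD of trunk rotation about vertical.
#' @param trunk_offset_deg Named per-condition systematic trunk rotation
#'   (default zero: identical posture across conditions).
#' @param bias_ramp Optional named per-condition list with \code{x_end_mm}
#'   (lateral deviation growing toward movement end) and \code{z_start_mm}
#'   (vertical deviation peaking early); \code{NULL} disables it. Off by
#'   default; used as a positive control for the pointwise trajectory ANOVA.
#' @param outlier_rate Probability that a trial's endpoint is displaced by a
#'   uniform far-field offset (models occasional aiming errors; 0 disables).
#' @param outlier_range_mm Magnitude range of outlier displacements.
#' @param ground_truth_filter_coefficient,ground_truth_threshold_frac
#'   Measurement model used for the recorded reference onset/offset.
#' @param seed Integer seed for \code{\link{generate_experiment}} and
#'   \code{\link{generate_design}}.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_participants = 10L,
                             conditions = POINTING_CONDITIONS,
                             reps_per_target_per_condition = 20L,
                             blocks_per_condition = 10L,
                             targets = default_targets(),
                             endpoint_model = default_endpoint_model(),
                             start = c(0, 0, 0),
                             duration_mean_ms = 600,
                             duration_sd_ms = 50,
                             rt_mean_ms = 700,
                             rt_sd_ms = 100,
                             gap_range_ms = c(20, 60),
                             lift_mm = 40,
                             marker_jitter_sd_mm = 0.05,
                             endpoint_z_sd_mm = 0.5,
                             pre_ms = 150,
                             post_ms = 150,
                             sampling_rate_hz = 400,
                             shoulder_left = c(180, 120, 450),
                             shoulder_right = c(-180, 120, 450),
                             trunk_jitter_sd_deg = 1,
                             trunk_offset_deg = NULL,
                             bias_ramp = NULL,
                             outlier_rate = 0,
                             outlier_range_mm = c(30, 60),
                             ground_truth_filter_coefficient = 0.1,
                             ground_truth_threshold_frac = 0.05,
                             seed = NULL) {
  stopifnot(is.data.frame(targets),
            all(c("target", "x", "y", "z", "central") %in% names(targets)),
            sum(targets$central) == 1L)
  conditions <- as.character(conditions)
  if (!setequal(conditions, POINTING_CONDITIONS))
    stop("conditions must be the three pointing conditions")
  if (is.null(trunk_offset_deg))
    trunk_offset_deg <- stats::setNames(rep(0, length(conditions)), conditions)
  if (!setequal(names(endpoint_model), conditions))
    stop("endpoint_model must have one entry per condition")
  reps <- as.integer(reps_per_target_per_condition)
  bpc <- as.integer(blocks_per_condition)
  if (reps %% bpc != 0L)
    stop("reps_per_target_per_condition must be a multiple of ",
         "blocks_per_condition")
  cfg <- list(
    n_participants = as.integer(n_participants),
    conditions = conditions,
    reps_per_target_per_condition = reps,
    blocks_per_condition = bpc,
    targets = targets,
    endpoint_model = endpoint_model,
    start = as.numeric(start),
    duration_mean_ms = duration_mean_ms, duration_sd_ms = duration_sd_ms,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    gap_range_ms = as.numeric(gap_range_ms),
    lift_mm = lift_mm,
    marker_jitter_sd_mm = marker_jitter_sd_mm,
    endpoint_z_sd_mm = endpoint_z_sd_mm,
    pre_ms = pre_ms, post_ms = post_ms,
    sampling_rate_hz = sampling_rate_hz,
    shoulder_left = as.numeric(shoulder_left),
    shoulder_right = as.numeric(shoulder_right),
    trunk_jitter_sd_deg = trunk_jitter_sd_deg,
    trunk_offset_deg = trunk_offset_deg,
    bias_ramp = bias_ramp,
    outlier_rate = outlier_rate,
    outlier_range_mm = as.numeric(outlier_range_mm),
    ground_truth_filter_coefficient = ground_truth_filter_coefficient,
    ground_truth_threshold_frac = ground_truth_threshold_frac,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' @rdname generator_config
#' @export
default_targets <- function() {
  data.frame(
    target = c("glass", "battery", "saltcellar", "lighter", "eraser"),
    x = c(0, 0, 0, 100, -100),
    y = c(-300, -400, -200, -300, -300),
    z = c(-150, -150, -150, -150, -150),
    central = c(TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' @rdname generator_config
#' @export
default_endpoint_model <- function() {
  list(
    LEFT_CP = list(orientation_deg = 72.8, axis_ratio = 0.25, scale_mm = 8),
    RIGHT_CP = list(orientation_deg = 112.7, axis_ratio = 0.25, scale_mm = 8),
    NCP = list(orientation_deg = 100.4, axis_ratio = 0.25, scale_mm = 8))
}

#' Draw anisotropic 2D endpoints
#'
#' Samples endpoints from a bivariate Gaussian whose principal axis has the
#' given axial orientation, whose eigenvalue ratio (minor/major) is
#' \code{axis_ratio}, and whose major-axis standard deviation is
#' \code{scale_mm}.
#'
#' @param n Number of points.
#' @param orientation_deg Major-axis axial angle vs the x-axis, degrees.
#' @param axis_ratio Minor/major eigenvalue ratio in (0, 1].
#' @param scale_mm Major-axis standard deviation (mm).
#' @param center Cloud center (length-2).
#' @return An n x 2 matrix.
#' @export
generate_endpoints <- function(n, orientation_deg, axis_ratio = 0.25,
                               scale_mm = 8, center = c(0, 0)) {
  stopifnot(n >= 1, axis_ratio > 0, axis_ratio <= 1, scale_mm >= 0)
  th <- orientation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  z <- cbind(stats::rnorm(n, 0, scale_mm),
             stats::rnorm(n, 0, scale_mm * sqrt(axis_ratio)))
  sweep(z %*% t(R), 2, center, `+`)
}

#' Generate the balanced trial design
#'
#' Builds each participant's ordered trial list: blocks of one condition each
#' (condition order counterbalanced across participants by cyclic rotation),
#' each block presenting every target \code{reps / blocks_per_condition}
#' times in an order randomized by the seed.
#'
#' @param config A \code{\link{generator_config}}.
#' @param .seed Set the configured seed before drawing block orders
#'   (disable when called from \code{\link{generate_experiment}}, which
#'   seeds once for the whole dataset).
#' @return Data frame with columns participant, block, condition,
#'   trial_in_block, target, trial_index.
#' @export
generate_design <- function(config = generator_config(), .seed = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (.seed && !is.null(config$seed)) set.seed(config$seed)
  nc <- length(config$conditions)
  n_blocks <- config$blocks_per_condition * nc
  per_block <- config$reps_per_target_per_condition /
    config$blocks_per_condition
  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    cond_seq <- config$conditions[((seq_len(n_blocks) - 1L + (p - 1L)) %% nc) + 1L]
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      targs <- sample(rep(config$targets$target, per_block))
      rows[[b]] <- data.frame(
        participant = sprintf("P%02d", p),
        block = b,
        condition = cond_seq[b],
        trial_in_block = seq_along(targs),
        target = targs,
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    d$trial_index <- seq_len(nrow(d))
    out[[p]] <- d
  }
  do.call(rbind, out)
}

# Minimum-jerk position fraction and the fraction of the full profile lying
# between the two `frac`-of-peak speed crossings (closed form).
minjerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
minjerk_threshold_span <- function(frac) sqrt(1 - sqrt(frac))

#' Generate one synthetic pointing trial
#'
#' Simulates the marker streams of a single trial: the fingertip follows a
#' minimum-jerk reach (single-peaked bell speed profile) from the start
#' position to an endpoint drawn from the condition's anisotropic 2D
#' Gaussian around the target, with a vertical arc, stationary padding
#' before button release and after movement end, isotropic marker jitter,
#' and shoulder markers at the (per-trial jittered) trunk pose. Uses the
#' current RNG state; seed the caller for reproducibility.
#'
#' @param participant,condition,target,block Trial metadata; \code{target}
#'   must name a row of \code{config$targets}.
#' @param config A \code{\link{generator_config}}.
#' @return A \code{\link{trial_recording}} whose \code{"ground_truth"}
#'   attribute records the true endpoint, nominal duration (5%-crossing span
#'   of the ideal profile), measurement-model reference onset/offset/dur,
#'   release-to-onset gap, trunk angle and outlier status.
#' @export
generate_trial <- function(participant, condition, target, block,
                           config = generator_config()) {
  stopifnot(inherits(config, "generator_config"),
            condition %in% config$conditions)
  trow <- config$targets[config$targets$target == target, ]
  if (nrow(trow) != 1L) stop("unknown target '", target, "'")
  fs <- config$sampling_rate_hz
  rt_raw <- max(200, stats::rnorm(1, config$rt_mean_ms, config$rt_sd_ms))
  gap_s <- stats::runif(1, config$gap_range_ms[1], config$gap_range_ms[2]) / 1000
  T_nom <- max(300, stats::rnorm(1, config$duration_mean_ms,
                                 config$duration_sd_ms)) / 1000
  if (T_nom <= 0) stop("non-positive movement duration")
  span <- minjerk_threshold_span(config$ground_truth_threshold_frac)
  T_full <- T_nom / span

  em <- config$endpoint_model[[condition]]
  ep_xy <- generate_endpoints(1, em$orientation_deg, em$axis_ratio,
                              em$scale_mm, center = c(trow$x, trow$y))
  is_outlier <- stats::runif(1) < config$outlier_rate
  if (is_outlier) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, config$outlier_range_mm[1],
                        config$outlier_range_mm[2])
    ep_xy <- ep_xy + rad * c(cos(ang), sin(ang))
  }
  endpoint <- c(ep_xy[1], ep_xy[2],
                trow$z + stats::rnorm(1, 0, config$endpoint_z_sd_mm))

  pre <- config$pre_ms / 1000
  post <- config$post_ms / 1000
  t <- seq(0, pre + gap_s + T_full + post, by = 1 / fs)
  tau <- pmin(pmax((t - pre - gap_s) / T_full, 0), 1)
  s <- minjerk_s(tau)
  path <- outer(s, endpoint - config$start) +
    matrix(config$start, length(t), 3, byrow = TRUE)
  path[, 3] <- path[, 3] + config$lift_mm * sin(pi * s)
  if (!is.null(config$bias_ramp)) {
    br <- config$bias_ramp[[condition]]
    if (!is.null(br)) {
      path[, 1] <- path[, 1] + (br$x_end_mm %||% 0) * s^2
      path[, 3] <- path[, 3] + (br$z_start_mm %||% 0) * 6.75 * s * (1 - s)^2
    }
  }

  # measurement-model reference on the noiseless trajectory
  ref <- segment_movement(
    tangential_velocity(
      exponential_filter(path, config$ground_truth_filter_coefficient), fs),
    config$ground_truth_threshold_frac)

  jitter <- function(M) M + matrix(
    stats::rnorm(length(M), 0, config$marker_jitter_sd_mm), nrow(M))
  led1 <- jitter(path)

  delta <- stats::rnorm(1, 0, config$trunk_jitter_sd_deg) +
    config$trunk_offset_deg[[condition]]
  mid <- (config$shoulder_left + config$shoulder_right) / 2
  half <- (config$shoulder_left - config$shoulder_right) / 2
  dr <- delta * pi / 180
  half_rot <- c(half[1] * cos(dr) - half[2] * sin(dr),
                half[1] * sin(dr) + half[2] * cos(dr), half[3])
  led3 <- jitter(matrix(mid + half_rot, length(t), 3, byrow = TRUE))
  led4 <- jitter(matrix(mid - half_rot, length(t), 3, byrow = TRUE))

  tr <- trial_recording(
    participant = participant, condition = condition, target = target,
    block = block, rt_raw_ms = rt_raw,
    t = t, led1 = led1, led2_on = t < pre, led3 = led3, led4 = led4,
    sampling_rate_hz = fs)
  attr(tr, "ground_truth") <- list(
    endpoint_x = endpoint[1], endpoint_y = endpoint[2],
    nominal_dur_ms = T_nom * 1000,
    ref_onset = ref$onset, ref_offset = ref$offset,
    ref_dur_ms = (ref$offset - ref$onset) / fs * 1000,
    gap_ms = gap_s * 1000,
    trunk_angle_deg = delta %% 180,
    orientation_deg = em$orientation_deg,
    axis_ratio = em$axis_ratio, scale_mm = em$scale_mm,
    outlier = is_outlier)
  tr
}

#' Generate a full synthetic experiment
#'
#' Draws the balanced design and every trial of every participant, seeded by
#' \code{config$seed}. With \code{path} set, writes the dataset in the
#' package's on-disk format (one trial file per trial plus manifest) together
#' with a \code{ground_truth.csv} sidecar recording the configured and drawn
#' per-trial truths, and a \code{generator_config.txt} snapshot of the scalar
#' configuration. Two runs with the same seed produce identical datasets.
#'
#' @param config A \code{\link{generator_config}}.
#' @param path Optional output directory.
#' @return Invisibly, a list with \code{trials} (list of
#'   \code{trial_recording}), \code{design}, \code{ground_truth} (data
#'   frame), and \code{path}.
#' @export
generate_experiment <- function(config = generator_config(), path = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  design <- generate_design(config, .seed = FALSE)
  trials <- vector("list", nrow(design))
  gt <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- generate_trial(design$participant[i], design$condition[i],
                         design$target[i], design$block[i], config)
    trials[[i]] <- tr
    gt[[i]] <- data.frame(
      participant = design$participant[i],
      condition = design$condition[i],
      target = design$target[i],
      block = design$block[i],
      trial_index = design$trial_index[i],
      as.data.frame(attr(tr, "ground_truth")),
      stringsAsFactors = FALSE)
  }
  ground_truth <- do.call(rbind, gt)
  if (!is.null(path)) {
    write_trials(trials, path)
    ground_truth$trial_file <- sprintf("trial_%05d.csv", seq_along(trials))
    write_table_precise(ground_truth, file.path(path, "ground_truth.csv"))
    scalars <- config[vapply(config, function(v)
      is.atomic(v) && length(v) <= 3 && !is.null(v), TRUE)]
    writeLines(
      vapply(names(scalars), function(nm) sprintf(
        "%s = %s", nm, paste(format(scalars[[nm]], digits = 17),
                             collapse = ", ")), ""),
      file.path(path, "generator_config.txt"))
  }
  invisible(list(trials = trials, design = design,
                 ground_truth = ground_truth, path = path))
}
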