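#' Run the full pointing analysis
#'
#' Orchestrates the end-to-end analysis of a set of trials: trajectory
#' filtering, velocity-threshold segmentation, temporal parameters and their
#' condition ANOVAs (within-participant and within-item), time-normalized
#' trajectory resampling with pointwise condition ANOVAs, endpoint extraction
#' with Cook's-distance outlier exclusion, per-participant normalized
#' tolerance ellipses and per-condition averages, pairwise Monte-Carlo
#' orientation tests, and the initial-trunk-orientation control analysis.
#'
#' The main endpoint analysis uses the central (isotropically placed) target
#' only; peripheral-target ellipses are always tabulated, and with
#' \code{include_peripheral = TRUE} their pairwise orientation tests are run
#' as a secondary report.
#'
#' @param trials List of \code{\link{trial_recording}} objects, or a dataset
#'   directory path (passed to \code{\link{read_trials}}).
#' @param config A \code{\link{run_config}}; \code{config$rng_seed} drives
#'   the Monte-Carlo tests.
#' @param central_target Label of the central target; defaults to the most
#'   frequent target flagged central by the generator layout
#'   (\code{"glass"}).
#' @param include_peripheral Also run orientation tests per peripheral
#'   target.
#' @return An object of class \code{"pointing_analysis"}: a named list of
#'   tables (\code{temporal_parameters}, \code{temporal_summary},
#'   \code{temporal_anova}, \code{pointwise_anova_x/y/z},
#'   \code{ellipse_table}, \code{condition_summary},
#'   \code{permutation_table}, \code{trunk_table}, \code{counts}) plus
#'   \code{endpoint_sets} (per participant x condition kept endpoints) and
#'   the \code{config} snapshot. Write it with \code{\link{write_results}}
#'   via \code{\link{results_bundle}}.
#' @export
analyze_experiment <- function(trials, config = run_config(),
                               central_target = "glass",
                               include_peripheral = FALSE) {
  if (is.character(trials)) trials <- read_trials(trials)
  stopifnot(length(trials) > 0,
            all(vapply(trials, inherits, TRUE, "trial_recording")))

  # --- kinematics: segmentation, temporal parameters, endpoints, trunk ----
  rows <- vector("list", length(trials))
  resampled <- vector("list", length(trials))
  endpoints <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    pos <- exponential_filter(tr$led1, config$filter_coefficient,
                              config$filter_form)
    v <- tangential_velocity(pos, tr$sampling_rate_hz)
    seg <- segment_movement(v, config$velocity_threshold_frac,
                            config$peak_multiplicity_frac)
    pp <- temporal_parameters(tr, config)
    pp$trunk_deg <- trunk_orientation(tr$led3[seg$onset, ],
                                      tr$led4[seg$onset, ])
    rows[[i]] <- pp
    if (pp$valid) {
      rs <- resample_trajectory(pos, tr$t, seg$onset, seg$offset,
                                config$resample_points)
      resampled[[i]] <- data.frame(
        participant = tr$participant, condition = tr$condition,
        target = tr$target, trial = i,
        point = seq_len(config$resample_points),
        x = rs[, 1], y = rs[, 2], z = rs[, 3], stringsAsFactors = FALSE)
      endpoints[[i]] <- data.frame(
        participant = tr$participant, condition = tr$condition,
        target = tr$target, trial = i,
        x = pos[seg$offset, 1], y = pos[seg$offset, 2],
        stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, rows)
  resampled <- do.call(rbind, resampled)
  endpoints <- do.call(rbind, endpoints)

  # --- temporal parameter summary and ANOVAs ------------------------------
  value_cols <- c("cRT_ms", "dur_ms", "ttp_ms", "maxvel_mm_s",
                  "meanvel_mm_s", "distance_mm")
  vp <- params[params$valid, ]
  temporal_summary <- do.call(rbind, lapply(split(vp, vp$condition),
    function(d) do.call(rbind, lapply(value_cols, function(cc) data.frame(
      condition = d$condition[1], parameter = cc, n_trials = nrow(d),
      mean = mean(d[[cc]]), sd = stats::sd(d[[cc]]),
      stringsAsFactors = FALSE)))))
  rownames(temporal_summary) <- NULL

  temporal_tests <- cbind(
    analysis = "within_participant",
    temporal_anova(params, unit = "participant", alpha = config$alpha))
  if (length(unique(vp$target)) >= 2L) {
    temporal_tests <- rbind(
      temporal_tests,
      cbind(analysis = "within_item",
            temporal_anova(params, unit = "target", alpha = config$alpha)))
  }

  pw <- lapply(c(x = "x", y = "y", z = "z"), function(ax)
    pointwise_condition_anova(resampled, axis = ax, unit = "participant",
                              alpha = config$alpha))

  # --- endpoint ellipses --------------------------------------------------
  ellipse_rows <- list()
  endpoint_sets <- list()
  for (tg in unique(endpoints$target)) {
    etg <- endpoints[endpoints$target == tg, ]
    for (pc in split(etg, list(etg$participant, etg$condition), drop = TRUE)) {
      pts <- as.matrix(pc[, c("x", "y")])
      cell <- sprintf("participant %s, %s, target '%s'",
                      pc$participant[1], pc$condition[1], tg)
      flt <- tryCatch(
        cooks_outlier_filter(pts, config$cooks_cutoff, config$cooks_method),
        error = function(e) stop("endpoint filtering failed for ", cell,
                                 ": ", conditionMessage(e)))
      if (nrow(flt$kept) < 3L)
        stop("fewer than 3 endpoints left after outlier exclusion for ",
             cell)
      ell <- normalize_matrix(covariance_ellipse(flt$kept))
      key <- paste(tg, pc$condition[1], sep = ".")
      endpoint_sets[[key]][[pc$participant[1]]] <- flt$kept
      ellipse_rows[[length(ellipse_rows) + 1L]] <- data.frame(
        target = tg, participant = pc$participant[1],
        condition = pc$condition[1],
        n_points = nrow(flt$kept), n_excluded = length(flt$excluded_idx),
        cov_xx = ell$cov[1, 1], cov_xy = ell$cov[1, 2],
        cov_yy = ell$cov[2, 2],
        lambda1 = ell$eigenvalues[1], lambda2 = ell$eigenvalues[2],
        orientation_deg = ell$orientation_deg,
        degenerate = ell$degenerate, stringsAsFactors = FALSE)
    }
  }
  ellipse_table <- do.call(rbind, ellipse_rows)
  rownames(ellipse_table) <- NULL

  condition_summary <- do.call(rbind, lapply(
    split(ellipse_table, list(ellipse_table$target,
                              ellipse_table$condition), drop = TRUE),
    function(d) {
      avg <- average_ellipse(lapply(seq_len(nrow(d)), function(i)
        ellipse_from_cov(matrix(c(d$cov_xx[i], d$cov_xy[i], d$cov_xy[i],
                                  d$cov_yy[i]), 2, 2),
                         normalized = TRUE)))
      data.frame(target = d$target[1], condition = d$condition[1],
                 n_participants = nrow(d),
                 orientation_deg = avg$orientation_deg,
                 lambda1 = avg$eigenvalues[1], lambda2 = avg$eigenvalues[2],
                 degenerate = avg$degenerate, stringsAsFactors = FALSE)
    }))
  rownames(condition_summary) <- NULL

  # --- Monte-Carlo orientation tests --------------------------------------
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  pairs <- utils::combn(sort(unique(endpoints$condition)), 2)
  test_targets <- if (include_peripheral) unique(endpoints$target)
                  else central_target
  perm_rows <- list()
  for (tg in test_targets) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      res <- permutation_orientation_test(
        endpoint_sets[[paste(tg, a, sep = ".")]],
        endpoint_sets[[paste(tg, b, sep = ".")]],
        n_sims = config$n_permutations,
        seed = sample.int(.Machine$integer.max, 1),
        condition_pair = paste(a, "vs", b))
      perm_rows[[length(perm_rows) + 1L]] <- data.frame(
        analysis = "endpoint_orientation", target = tg,
        pair = res$condition_pair,
        orientation_a = res$orientation_a, orientation_b = res$orientation_b,
        observed_diff_deg = res$observed_diff_deg,
        N = res$exceed_count, n_sims = res$n_sims, p_value = res$p_value,
        seed = res$seed, stringsAsFactors = FALSE)
    }
  }

  # --- initial trunk orientation ------------------------------------------
  trunk_table <- do.call(rbind, lapply(
    split(vp, list(vp$participant, vp$condition), drop = TRUE),
    function(d) data.frame(participant = d$participant[1],
                           condition = d$condition[1], n_trials = nrow(d),
                           trunk_deg = axial_mean_deg(d$trunk_deg),
                           stringsAsFactors = FALSE)))
  rownames(trunk_table) <- NULL
  trunk_sets <- lapply(split(vp, vp$condition), function(d)
    lapply(split(d, d$participant), `[[`, "trunk_deg"))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    res <- permutation_angle_test(
      trunk_sets[[a]], trunk_sets[[b]], n_sims = config$n_permutations,
      seed = sample.int(.Machine$integer.max, 1),
      condition_pair = paste(a, "vs", b))
    perm_rows[[length(perm_rows) + 1L]] <- data.frame(
      analysis = "trunk_orientation", target = "",
      pair = res$condition_pair,
      orientation_a = res$orientation_a, orientation_b = res$orientation_b,
      observed_diff_deg = res$observed_diff_deg,
      N = res$exceed_count, n_sims = res$n_sims, p_value = res$p_value,
      seed = res$seed, stringsAsFactors = FALSE)
  }
  permutation_table <- do.call(rbind, perm_rows)

  # --- per-trial accounting ----------------------------------------------
  n_outlier <- if (is.null(ellipse_table)) 0L else sum(ellipse_table$n_excluded)
  counts <- data.frame(
    ingested = length(trials),
    valid = sum(params$valid),
    invalid_multi_peak = sum(params$invalid_reason == "multiple velocity peaks"),
    invalid_onset_before_release =
      sum(params$invalid_reason == "onset precedes button release"),
    endpoints_excluded_outlier = n_outlier,
    outlier_fraction = n_outlier / max(1L, sum(params$valid)))

  structure(
    list(temporal_parameters = params,
         temporal_summary = temporal_summary,
         temporal_anova = temporal_tests,
         pointwise_anova_x = pw$x,
         pointwise_anova_y = pw$y,
         pointwise_anova_z = pw$z,
         ellipse_table = ellipse_table,
         condition_summary = condition_summary,
         permutation_table = permutation_table,
         trunk_table = trunk_table,
         counts = counts,
         endpoint_sets = endpoint_sets,
         config = config),
    class = "pointing_analysis")
}

#' Results tables of an analysis, ready for writing
#'
#' Extracts the data-frame tables of a \code{\link{analyze_experiment}}
#' result as a named list accepted by \code{\link{write_results}}.
#'
#' @param analysis A \code{"pointing_analysis"} object.
#' @return Named list of data frames.
#' @export
results_bundle <- function(analysis) {
  stopifnot(inherits(analysis, "pointing_analysis"))
  keep <- vapply(analysis, is.data.frame, TRUE)
  analysis[keep]
}

#' @export
print.pointing_analysis <- function(x, ...) {
  cat("Pointing analysis\n")
  cat(sprintf("  trials: %d ingested, %d valid, %d excluded endpoints (%.1f%% outliers)\n",
              x$counts$ingested, x$counts$valid,
              x$counts$endpoints_excluded_outlier,
              100 * x$counts$outlier_fraction))
  cs <- x$condition_summary
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-10s %-9s average ellipse orientation %6.1f deg\n",
                cs$target[i], cs$condition[i], cs$orientation_deg[i]))
  pt <- x$permutation_table
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  %-22s %-20s diff %5.1f deg  p = %.4g\n",
                pt$analysis[i], pt$pair[i], pt$observed_diff_deg[i],
                pt$p_value[i]))
  invisible(x)
}
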