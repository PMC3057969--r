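# One-way repeated-measures ANOVA on unit x condition means.
#
# `df` must have columns unit, condition, value with exactly one value per
# unit x condition cell (aggregate first). Fits
# aov(value ~ condition + Error(unit)) and extracts the condition F test from
# the within stratum. Degenerate cases are resolved before calling aov: if the
# between-condition mean square is (numerically) zero the test statistic is 0
# with p = 1.
rm_anova_cell_means <- function(df) {
  stopifnot(all(c("unit", "condition", "value") %in% names(df)))
  df$unit <- factor(df$unit)
  df$condition <- factor(df$condition)
  tab <- table(df$unit, df$condition)
  if (any(tab != 1L)) {
    off <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop("unit '", rownames(tab)[off[1]], "' has ", tab[off[1], off[2]],
         " values for condition '", colnames(tab)[off[2]],
         "' (expected exactly 1)")
  }
  nc <- nlevels(df$condition)
  nu <- nlevels(df$unit)
  if (nc < 2L) stop("need at least 2 conditions")
  if (nu < 2L) stop("need at least 2 units")
  df1 <- nc - 1L
  df2 <- (nu - 1L) * (nc - 1L)
  cond_means <- tapply(df$value, df$condition, mean)
  scale <- stats::var(df$value)
  if (!is.finite(scale) || scale == 0 ||
      stats::var(as.numeric(cond_means)) < 1e-14 * max(scale, 1e-300)) {
    return(data.frame(F = 0, df1 = df1, df2 = df2, p = 1))
  }
  fit <- stats::aov(value ~ condition + Error(unit), data = df)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  Fv <- within["condition", "F value"]
  pv <- within["condition", "Pr(>F)"]
  if (!is.finite(Fv)) { Fv <- Inf; pv <- 0 }
  data.frame(F = Fv, df1 = df1, df2 = df2, p = pv)
}

#' Condition ANOVA of temporal movement parameters
#'
#' Tests each temporal parameter for a condition effect with a one-way
#' repeated-measures ANOVA: values are first averaged per analysis unit
#' (participant for the within-participant analysis, target for the
#' within-item analysis) and condition, then condition is tested against the
#' unit-by-condition interaction.
#'
#' @param params A data frame of per-trial temporal parameters (rows of
#'   \code{\link{temporal_parameters}}); invalid trials are dropped.
#' @param parameters Character vector of parameter columns to test.
#' @param unit \code{"participant"} or \code{"target"}.
#' @param alpha Significance level used for the \code{significant} flag.
#' @return Data frame with one row per parameter: parameter, F, df1, df2, p,
#'   significant.
#' @export
temporal_anova <- function(params,
                           parameters = c("cRT_ms", "dur_ms", "ttp_ms",
                                          "maxvel_mm_s", "meanvel_mm_s",
                                          "distance_mm"),
                           unit = c("participant", "target"),
                           alpha = 0.05) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(params), all(parameters %in% names(params)))
  if ("valid" %in% names(params)) params <- params[params$valid, ]
  check_complete_design(params, unit)
  out <- do.call(rbind, lapply(parameters, function(pm) {
    cells <- stats::aggregate(params[[pm]],
                              by = list(unit = params[[unit]],
                                        condition = params$condition),
                              FUN = mean)
    names(cells)[3] <- "value"
    cbind(data.frame(parameter = pm), rm_anova_cell_means(cells))
  }))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Pointwise condition ANOVA along time-normalized trajectories
#'
#' For each of the resampled trajectory points, tests the chosen coordinate
#' for a condition effect with a one-way repeated-measures ANOVA over
#' per-unit condition means.
#'
#' @param resampled Long-format data frame with columns participant (and/or
#'   target), condition, point, and coordinate columns x, y, z — one row per
#'   trial and resampled point (see \code{\link{analyze_experiment}}).
#' @param axis Which coordinate to test: "x", "y" or "z".
#' @param unit Analysis unit, as in \code{\link{temporal_anova}}.
#' @param alpha Significance level for the flag.
#' @return Data frame with one row per point: point, mean coordinates per
#'   condition, F, df1, df2, p, significant.
#' @export
pointwise_condition_anova <- function(resampled, axis = c("x", "y", "z"),
                                      unit = c("participant", "target"),
                                      alpha = 0.05) {
  axis <- match.arg(axis)
  unit <- match.arg(unit)
  stopifnot(is.data.frame(resampled),
            all(c("condition", "point", axis, unit) %in% names(resampled)))
  npts <- sort(unique(resampled$point))
  check_complete_design(resampled, unit)
  out <- do.call(rbind, lapply(npts, function(k) {
    d <- resampled[resampled$point == k, ]
    cells <- stats::aggregate(d[[axis]],
                              by = list(unit = d[[unit]],
                                        condition = d$condition),
                              FUN = mean)
    names(cells)[3] <- "value"
    cond_means <- tapply(cells$value, cells$condition, mean)
    res <- rm_anova_cell_means(cells)
    means <- as.data.frame(as.list(round(cond_means, 6)))
    names(means) <- paste0("mean_", names(cond_means))
    cbind(data.frame(point = k), means, res)
  }))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

# Every unit must appear in every condition.
check_complete_design <- function(df, unit) {
  tab <- table(df[[unit]], df$condition)
  if (any(tab == 0L)) {
    off <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop(unit, " '", rownames(tab)[off[1]],
         "' has no data for condition '", colnames(tab)[off[2]], "'")
  }
  invisible(TRUE)
}
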