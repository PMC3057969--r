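#' Analysis configuration
#'
#' Collects every tunable constant of the analysis pipeline in one place.
#' Defaults reproduce the standard settings: exponential filter coefficient
#' 0.1, movement onset/offset at 5% of peak tangential velocity, 20
#' time-normalized trajectory points, Cook's-distance cutoff 0.25 for endpoint
#' outliers, and 10,000 Monte-Carlo resamples for orientation tests.
#'
#' @param filter_coefficient Blend fraction of the exponential smoothing
#'   filter, in (0, 1]. 1 leaves the series unchanged.
#' @param velocity_threshold_frac Movement onset/offset threshold as a
#'   fraction of peak tangential velocity, in (0, 1].
#' @param resample_points Number of time-normalized trajectory points.
#' @param cooks_cutoff Cook's-distance cutoff above which an endpoint is
#'   excluded as an outlier.
#' @param n_permutations Number of Monte-Carlo resamples per orientation test.
#' @param rng_seed Integer seed controlling every stochastic step of an
#'   analysis run, or NULL.
#' @param peak_multiplicity_frac Fraction of the global velocity maximum above
#'   which additional local maxima mark a trial invalid, in (0, 1].
#' @param alpha Significance level used to flag tests.
#' @param filter_form \code{"recursive"} for the exponential (infinite
#'   impulse response) filter; \code{"two_tap"} for the literal two-point
#'   blend of the raw previous sample.
#' @param cooks_method \code{"per_axis"} computes Cook's distance from
#'   intercept-only fits of each coordinate; \code{"mahalanobis"} uses a joint
#'   bivariate influence measure.
#'
#' @return An object of class \code{"run_config"}: a validated named list.
#' @examples
#' cfg <- run_config(n_permutations = 1000, rng_seed = 1)
#' cfg$velocity_threshold_frac
#' @export
run_config <- function(filter_coefficient = 0.1,
                       velocity_threshold_frac = 0.05,
                       resample_points = 20L,
                       cooks_cutoff = 0.25,
                       n_permutations = 10000L,
                       rng_seed = NULL,
                       peak_multiplicity_frac = 0.5,
                       alpha = 0.05,
                       filter_form = c("recursive", "two_tap"),
                       cooks_method = c("per_axis", "mahalanobis")) {
  filter_form <- match.arg(filter_form)
  cooks_method <- match.arg(cooks_method)
  cfg <- list(
    filter_coefficient = as.numeric(filter_coefficient),
    velocity_threshold_frac = as.numeric(velocity_threshold_frac),
    resample_points = as.integer(resample_points),
    cooks_cutoff = as.numeric(cooks_cutoff),
    n_permutations = as.integer(n_permutations),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    peak_multiplicity_frac = as.numeric(peak_multiplicity_frac),
    alpha = as.numeric(alpha),
    filter_form = filter_form,
    cooks_method = cooks_method
  )
  for (f in c("filter_coefficient", "velocity_threshold_frac",
              "peak_multiplicity_frac")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0 || v > 1)
      stop(sprintf("'%s' must lie in (0, 1], got %s", f, format(v)))
  }
  if (cfg$resample_points < 2L)
    stop("'resample_points' must be at least 2")
  if (cfg$n_permutations < 1L)
    stop("'n_permutations' must be at least 1")
  if (!is.finite(cfg$cooks_cutoff) || cfg$cooks_cutoff <= 0)
    stop("'cooks_cutoff' must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Read or write a configuration file
#'
#' Flat key/value text format, one \code{key = value} pair per line. Unknown
#' keys are rejected; missing keys fall back to the defaults of
#' \code{\link{run_config}}.
#'
#' @param path File path.
#' @param config A \code{run_config} object (for writing).
#' @return \code{read_config} returns a \code{run_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- formals(run_config)
  unknown <- setdiff(keys, names(args))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  parsed <- lapply(seq_along(keys), function(i) {
    k <- keys[i]; v <- vals[i]
    if (k %in% c("filter_form", "cooks_method")) v
    else if (v == "NULL") NULL
    else as.numeric(v)
  })
  names(parsed) <- keys
  do.call(run_config, parsed)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("%s = %s", nm,
            if (is.null(v)) "NULL"
            else if (is.character(v)) v
            else format(v, digits = 17))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
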