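# On-disk dataset layout: one directory per experiment containing
#   manifest.csv  (participant, condition, target, block, rt_raw_ms,
#                  sampling_rate_hz, trial_file)
#   one delimited trial file per row of the manifest with columns
#   t, x1, y1, z1, led2, x3, y3, z3, x4, y4, z4
# UTF-8, comma-delimited, "." decimal separator. Doubles are written with 17
# significant digits so that write -> read round-trips bit-identically.

TRIAL_COLUMNS <- c("t", "x1", "y1", "z1", "led2",
                   "x3", "y3", "z3", "x4", "y4", "z4")
MANIFEST_COLUMNS <- c("participant", "condition", "target", "block",
                      "rt_raw_ms", "sampling_rate_hz", "trial_file")

# Format a data.frame for lossless delimited-text output.
format_precise <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

write_table_precise <- function(df, path) {
  utils::write.csv(format_precise(df), path, row.names = FALSE, quote = FALSE)
}

#' Read a directory of pointing trials
#'
#' Reads the manifest and every per-trial marker file of a dataset directory
#' (the format written by \code{\link{write_trials}} and
#' \code{\link{generate_experiment}}), validating each trial's invariants.
#' Errors name the offending file and line.
#'
#' @param path Dataset directory containing \code{manifest.csv}.
#' @return A list of \code{\link{trial_recording}} objects.
#' @export
read_trials <- function(path) {
  manifest_path <- file.path(path, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("no manifest.csv under ", path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(missing) > 0)
    stop("manifest.csv is missing column(s): ",
         paste(missing, collapse = ", "), " [", manifest_path, "]")
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(path, man$trial_file[i])
    if (!file.exists(f))
      stop("trial file not found: ", f,
           " [", manifest_path, ", line ", i + 1L, "]")
    header <- strsplit(readLines(f, n = 1L), ",", fixed = TRUE)[[1]]
    if (!identical(trimws(header), TRIAL_COLUMNS))
      stop("malformed header (expected '",
           paste(TRIAL_COLUMNS, collapse = ","), "') [", f, ", line 1]")
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    for (cc in TRIAL_COLUMNS) {
      if (!is.numeric(d[[cc]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))[1]
        stop("non-numeric value in column '", cc, "' [", f, ", line ",
             if (is.na(bad)) "?" else bad + 1L, "]")
      }
    }
    if (!all(d$led2 %in% c(0, 1)))
      stop("led2 must be 0 or 1 [", f, ", line ",
           which(!(d$led2 %in% c(0, 1)))[1] + 1L, "]")
    tr <- structure(
      list(participant = as.character(man$participant[i]),
           condition = as.character(man$condition[i]),
           target = as.character(man$target[i]),
           block = as.integer(man$block[i]),
           rt_raw_ms = as.numeric(man$rt_raw_ms[i]),
           t = d$t,
           led1 = as.matrix(d[, c("x1", "y1", "z1")]),
           led2_on = d$led2 == 1,
           led3 = as.matrix(d[, c("x3", "y3", "z3")]),
           led4 = as.matrix(d[, c("x4", "y4", "z4")]),
           sampling_rate_hz = as.numeric(man$sampling_rate_hz[i])),
      class = "trial_recording")
    dimnames(tr$led1) <- dimnames(tr$led3) <- dimnames(tr$led4) <- NULL
    validate_trial(tr, where = f)
    trials[[i]] <- tr
  }
  trials
}

#' Write pointing trials to a dataset directory
#'
#' Inverse of \code{\link{read_trials}}: writes one marker file per trial plus
#' a manifest. Values round-trip bit-identically.
#'
#' @param trials List of \code{\link{trial_recording}} objects.
#' @param path Output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(length(trials) > 0)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  files <- sprintf("trial_%05d.csv", seq_along(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    validate_trial(tr)
    d <- data.frame(t = tr$t,
                    x1 = tr$led1[, 1], y1 = tr$led1[, 2], z1 = tr$led1[, 3],
                    led2 = as.integer(tr$led2_on),
                    x3 = tr$led3[, 1], y3 = tr$led3[, 2], z3 = tr$led3[, 3],
                    x4 = tr$led4[, 1], y4 = tr$led4[, 2], z4 = tr$led4[, 3])
    write_table_precise(d, file.path(path, files[i]))
  }
  man <- data.frame(
    participant = vapply(trials, `[[`, "", "participant"),
    condition = vapply(trials, `[[`, "", "condition"),
    target = vapply(trials, `[[`, "", "target"),
    block = vapply(trials, function(x) x$block, 1L),
    rt_raw_ms = vapply(trials, function(x) x$rt_raw_ms, 1),
    sampling_rate_hz = vapply(trials, function(x) x$sampling_rate_hz, 1),
    trial_file = files)
  write_table_precise(man, file.path(path, "manifest.csv"))
  invisible(path)
}

#' Write or read a bundle of results tables
#'
#' A results bundle is a named list of data frames (temporal parameters,
#' per-point trajectory ANOVAs, ellipse table, permutation table, ...). Each
#' table is written as \code{<name>.csv} with fixed column order; doubles are
#' written with 17 significant digits so re-reading reproduces the values
#' exactly. Zero-row tables yield header-only files.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @return \code{write_results} returns \code{path} invisibly;
#'   \code{read_results} returns a named list of data frames.
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables))
  if (length(tables) > 0 &&
      (is.null(names(tables)) || any(!nzchar(names(tables)))))
    stop("every results table must be named")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    write_table_precise(tables[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  out <- lapply(files, utils::read.csv, stringsAsFactors = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
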