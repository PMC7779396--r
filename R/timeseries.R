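# Node time-series preprocessing and connectivity estimation.
#
# The pipeline starts at extracted node time courses (one column per atlas
# node): image-level steps (slice timing, realignment, normalisation,
# smoothing) belong to the scanner-side preprocessing and are out of scope.

#' Construct a node time-series object
#'
#' @param data numeric matrix, time points in rows, nodes in columns.
#' @param fd per-volume framewise displacement in mm (first volume 0 by
#'   convention). Defaults to all zeros.
#' @param tr repetition time, seconds per volume.
#' @param subject_id identifier.
#' @param rotation_max,translation_max maximum head rotation (degrees) and
#'   translation (mm) over the run, used by [motion_exclude()].
#' @return Object of class `cpm_timeseries`.
#' @export
time_series <- function(data, fd = NULL, tr = 2, subject_id = "sub001",
                        rotation_max = 0, translation_max = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (is.null(fd)) fd <- rep(0, nrow(data))
  if (length(fd) != nrow(data))
    stop("`fd` must have one value per time point", call. = FALSE)
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  structure(
    list(subject_id = subject_id, data = data, tr = tr, fd = as.numeric(fd),
         rotation_max = rotation_max, translation_max = translation_max),
    class = "cpm_timeseries"
  )
}

#' @export
print.cpm_timeseries <- function(x, ...) {
  cat("Node time series", x$subject_id, ":", nrow(x$data), "volumes x",
      ncol(x$data), "nodes, TR =", x$tr, "s, mean FD =",
      round(mean(x$fd), 3), "mm\n")
  invisible(x)
}

#' Motion scrubbing: delete high-motion volumes
#'
#' Removes every volume whose framewise displacement strictly exceeds
#' `fd_threshold` (default 0.5 mm), preserving temporal order of the
#' retained volumes.
#'
#' @param ts a [time_series].
#' @param fd_threshold FD cutoff in mm; comparison is strict (`>`).
#' @return The scrubbed [time_series].
#' @export
scrub <- function(ts, fd_threshold = 0.5) {
  stopifnot(inherits(ts, "cpm_timeseries"))
  if (fd_threshold <= 0) stop("fd_threshold must be positive", call. = FALSE)
  keep <- ts$fd <= fd_threshold
  if (!any(keep))
    stop("scrubbing removed every volume (all FD > ", fd_threshold, " mm)",
         call. = FALSE)
  ts$data <- ts$data[keep, , drop = FALSE]
  ts$fd <- ts$fd[keep]
  ts
}

#' Subject-level motion exclusion rule
#'
#' A subject is excluded if head rotation exceeds `rot_max` degrees,
#' translation exceeds `trans_max` mm, or mean framewise displacement
#' exceeds `mean_fd_max` mm. All comparisons are strict, so a subject at
#' exactly a threshold is kept. Mean FD is computed on the unscrubbed trace.
#'
#' @param ts a [time_series].
#' @param rot_max,trans_max,mean_fd_max exclusion thresholds (defaults:
#'   2 degrees, 2 mm, 0.15 mm).
#' @return `TRUE` if the subject should be excluded.
#' @export
motion_exclude <- function(ts, rot_max = 2, trans_max = 2,
                           mean_fd_max = 0.15) {
  stopifnot(inherits(ts, "cpm_timeseries"))
  if (rot_max <= 0 || trans_max <= 0 || mean_fd_max <= 0)
    stop("thresholds must be positive", call. = FALSE)
  ts$rotation_max > rot_max ||
    ts$translation_max > trans_max ||
    mean(ts$fd) > mean_fd_max
}

#' Detrend, regress out nuisance signals, and band-pass filter
#'
#' Per node, in order: (1) remove a linear trend by least squares (if
#' `detrend`), (2) project out the column space of `nuisance` (with an
#' intercept) by least squares, (3) zero-phase band-pass filter with a
#' second-order Butterworth design applied forward and backward
#' (`signal::filtfilt`), which doubles the effective order and cancels
#' phase distortion. Output length equals input length.
#'
#' With extracted node time series there is no voxelwise global signal; the
#' mean time course across nodes is the usual stand-in nuisance regressor,
#' but any regressor matrix (motion parameters, tissue signals) can be
#' supplied.
#'
#' @param ts a [time_series].
#' @param nuisance optional time x k numeric matrix of nuisance regressors.
#' @param band length-2 numeric, band-pass corner frequencies in Hz; must
#'   satisfy `0 <= low < high < 1/(2*tr)`. `NULL` skips filtering.
#' @param detrend remove a per-node linear trend first.
#' @return The cleaned [time_series].
#' @export
clean <- function(ts, nuisance = NULL, band = c(0.01, 0.1), detrend = TRUE) {
  stopifnot(inherits(ts, "cpm_timeseries"))
  x <- ts$data
  tt <- nrow(x)
  if (!is.null(band)) {
    nyquist <- 1 / (2 * ts$tr)
    if (length(band) != 2L || band[1] < 0 || band[1] >= band[2] ||
        band[2] >= nyquist)
      stop("band must satisfy 0 <= low < high < Nyquist (",
           signif(nyquist, 3), " Hz for tr = ", ts$tr, " s)", call. = FALSE)
  }
  if (detrend) {
    t_c <- seq_len(tt) - (tt + 1) / 2
    beta <- crossprod(t_c, x) / sum(t_c^2)
    x <- sweep(x, 2, colMeans(x)) - outer(t_c, drop(beta))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != tt)
      stop("nuisance regressors must have one row per time point",
           call. = FALSE)
    x <- stats::lm.fit(cbind(1, nuisance), x)$residuals
  }
  if (!is.null(band)) {
    bf <- signal::butter(2, band * 2 * ts$tr, type = "pass")
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  ts$data <- x
  ts
}

#' Fisher-z functional connectivity matrix from node time series
#'
#' Computes pairwise Pearson correlations between node time courses and
#' applies Fisher's z-transform `z = arctanh(r)`. Correlations are clipped
#' to `|r| <= 1 - 1e-7` before the transform so perfectly correlated nodes
#' yield a large finite weight rather than infinity. Nodes with zero
#' temporal variance produce undefined correlations; their edges are set to
#' z = 0 with a warning so the subject stays in the cohort. The diagonal is
#' exactly 0.
#'
#' @param ts a [time_series] with at least 3 time points and 2 nodes.
#' @return A symmetric matrix of Fisher-z weights (class `matrix`), with
#'   attribute `subject_id`.
#' @examples
#' ts <- time_series(matrix(rnorm(300), 100, 3))
#' z <- connectivity(ts)
#' all(diag(z) == 0)
#' @export
connectivity <- function(ts) {
  stopifnot(inherits(ts, "cpm_timeseries"))
  if (nrow(ts$data) < 3L)
    stop("need at least 3 time points to estimate connectivity",
         call. = FALSE)
  if (ncol(ts$data) < 2L)
    stop("need at least 2 nodes", call. = FALSE)
  r <- suppressWarnings(stats::cor(ts$data))
  if (anyNA(r)) {
    bad <- which(apply(ts$data, 2, stats::sd) == 0)
    warning("zero-variance node(s) ", paste(bad, collapse = ", "),
            " for subject ", ts$subject_id, "; their edges set to z = 0",
            call. = FALSE)
    r[is.na(r)] <- 0
  }
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  attr(z, "subject_id") <- ts$subject_id
  z
}

#' Run the full time-series-to-connectome path for a set of subjects
#'
#' Applies, per subject: motion exclusion screen, scrubbing, cleaning, and
#' connectivity estimation, then assembles the retained subjects into a
#' [cohort].
#'
#' @param ts_list list of [time_series] objects.
#' @param scores behavioural score per subject (aligned with `ts_list`).
#' @param fd_threshold scrubbing cutoff, mm.
#' @param exclude apply the subject-level motion exclusion rule.
#' @param nuisance_fun function of a time series matrix returning the
#'   nuisance regressor matrix; default uses the mean time course across
#'   nodes (global-signal stand-in). `NULL` for no nuisance regression.
#' @param band,detrend passed to [clean()].
#' @return A [cohort] of the retained subjects.
#' @export
build_cohort <- function(ts_list, scores, fd_threshold = 0.5,
                         exclude = TRUE,
                         nuisance_fun = function(x) rowMeans(x),
                         band = c(0.01, 0.1), detrend = TRUE) {
  stopifnot(length(ts_list) == length(scores))
  keep <- if (exclude) !vapply(ts_list, motion_exclude, logical(1))
          else rep(TRUE, length(ts_list))
  if (!any(keep)) stop("every subject excluded for motion", call. = FALSE)
  mats <- lapply(ts_list[keep], function(ts) {
    ts <- scrub(ts, fd_threshold)
    nuis <- if (!is.null(nuisance_fun)) nuisance_fun(ts$data)
    ts <- clean(ts, nuisance = nuis, band = band, detrend = detrend)
    connectivity(ts)
  })
  ids <- vapply(ts_list[keep], `[[`, character(1), "subject_id")
  mean_fd <- vapply(ts_list[keep], function(t) mean(t$fd), numeric(1))
  cohort(mats, scores[keep],
         covariates = data.frame(mean_fd = mean_fd),
         subject_ids = ids)
}
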