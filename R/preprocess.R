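# ROI-level denoising and motion QC. Fixed stage order:
# drop initial frames -> FD/DVARS (on pre-interpolation data) -> flag ->
# interpolate -> nuisance regression -> band-pass.

#' Drop initial frames from a run
#'
#' Removes the first `n` frames (non-steady-state volumes) from the signal
#' matrix and the usability mask. Aligned motion or confound matrices must
#' be shortened with [drop_initial_rows()].
#'
#' @param ts A [roi_timeseries()].
#' @param n Number of frames to drop (default 4).
#' @return The shortened time series.
#' @export
drop_initial_frames <- function(ts, n = 4) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (n < 0 || n != round(n)) stop("n must be a nonnegative integer", call. = FALSE)
  if (n_frames(ts) <= n)
    stop("cannot drop ", n, " frames from a ", n_frames(ts), "-frame run", call. = FALSE)
  if (n == 0) return(ts)
  keep <- (n + 1):n_frames(ts)
  roi_timeseries(ts$values[keep, , drop = FALSE], tr_seconds = ts$tr_seconds,
                 roi_ids = ts$roi_ids, run_label = ts$run_label,
                 frame_usable = ts$frame_usable[keep])
}

#' @rdname drop_initial_frames
#' @param x A matrix (or [motion_trace()]) aligned frame-for-frame with the
#'   time series.
#' @export
drop_initial_rows <- function(x, n = 4) {
  if (inherits(x, "motion_trace")) {
    if (nrow(x$params) <= n) stop("cannot drop ", n, " rows", call. = FALSE)
    return(motion_trace(x$params[-seq_len(n), , drop = FALSE]))
  }
  if (nrow(x) <= n) stop("cannot drop ", n, " rows", call. = FALSE)
  x[-seq_len(n), , drop = FALSE]
}

#' Framewise displacement
#'
#' FD at frame t is the sum of absolute frame-to-frame changes in the three
#' translations (mm) plus `head_radius` times the sum of absolute changes in
#' the three rotations (radians), i.e. rotations are converted to arc
#' displacement on a sphere of `head_radius` mm. The first frame is defined
#' as 0.
#'
#' @param motion A [motion_trace()] or frames x 6 matrix.
#' @param head_radius Head radius in mm (default 50).
#' @return Numeric vector of per-frame FD (mm).
#' @export
compute_fd <- function(motion, head_radius = 50) {
  p <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
  if (ncol(p) != 6) stop("motion matrix must have 6 columns", call. = FALSE)
  if (!all(is.finite(p))) stop("non-finite motion parameters", call. = FALSE)
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
             head_radius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' DVARS: RMS of the temporal signal derivative
#'
#' Signals are first rescaled so the run-wide median ROI value equals
#' `scale_to` (making the conventional threshold of 50 meaningful), then
#' DVARS at frame t is the root mean square over ROIs of the frame-to-frame
#' signal difference. The first frame is defined as 0.
#'
#' @param ts A [roi_timeseries()].
#' @param scale_to Target run-wide median intensity (default 1000); set to
#'   `NA` to skip rescaling.
#' @return Numeric vector of per-frame DVARS.
#' @export
compute_dvars <- function(ts, scale_to = 1000) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (n_frames(ts) < 2) stop("DVARS needs at least 2 frames", call. = FALSE)
  v <- ts$values
  if (!is.na(scale_to)) {
    med <- stats::median(v)
    if (abs(med) < .Machine$double.eps * 100)
      stop("run-wide median is zero; cannot rescale for DVARS", call. = FALSE)
    v <- v * (scale_to / med)
  }
  d <- diff(v)
  c(0, sqrt(rowMeans(d^2)))
}

#' Flag high-motion frames with neighborhood expansion
#'
#' Seed frames are those with `fd > fd_thresh` OR `dvars > dvars_thresh`.
#' The censor mask is the union of every seed with its predecessor and two
#' successors (one before, two after), clipped to run bounds.
#'
#' @param fd Per-frame FD vector.
#' @param dvars Per-frame DVARS vector (same length).
#' @param fd_thresh FD threshold in mm (default 0.2).
#' @param dvars_thresh DVARS threshold (default 50).
#' @return Logical censor mask (`TRUE` = censored).
#' @export
flag_frames <- function(fd, dvars, fd_thresh = 0.2, dvars_thresh = 50) {
  if (length(fd) != length(dvars))
    stop("fd and dvars must have equal length", call. = FALSE)
  n <- length(fd)
  seeds <- which(fd > fd_thresh | dvars > dvars_thresh)
  mask <- rep(FALSE, n)
  if (length(seeds) > 0) {
    idx <- unique(c(seeds - 1L, seeds, seeds + 1L, seeds + 2L))
    idx <- idx[idx >= 1L & idx <= n]
    mask[idx] <- TRUE
  }
  mask
}

#' Interpolate censored frames from surrounding data
#'
#' Censored frames are replaced per ROI by linear interpolation between the
#' nearest usable neighbors; censored runs at either edge take the nearest
#' usable value. Replaced frames are marked unusable in `frame_usable`.
#'
#' @param ts A [roi_timeseries()].
#' @param mask Logical censor mask from [flag_frames()].
#' @return Time series with censored frames replaced.
#' @export
interpolate_frames <- function(ts, mask) {
  stopifnot(inherits(ts, "roi_timeseries"))
  mask <- as.logical(mask)
  if (length(mask) != n_frames(ts))
    stop("mask length must equal frame count", call. = FALSE)
  if (!any(mask)) return(ts)
  if (all(mask)) stop("all frames censored; nothing to interpolate from", call. = FALSE)
  good <- which(!mask)
  t_all <- seq_len(n_frames(ts))
  v <- ts$values
  if (length(good) == 1) {
    v[mask, ] <- rep(v[good, ], each = sum(mask))
  } else {
    for (j in seq_len(ncol(v))) {
      v[mask, j] <- stats::approx(x = good, y = v[good, j], xout = t_all[mask],
                                  method = "linear", rule = 2)$y
    }
  }
  roi_timeseries(v, tr_seconds = ts$tr_seconds, roi_ids = ts$roi_ids,
                 run_label = ts$run_label,
                 frame_usable = ts$frame_usable & !mask)
}

#' Frame-retention exclusion rule
#'
#' A scan is excluded when fewer than 50% of its frames survive censoring;
#' the boundary is inclusive (exactly 50% retained is kept). Evaluated per
#' scan; a participant failing any scan is excluded upstream.
#'
#' @param mask Logical censor mask.
#' @param total_frames Total frame count of the (post-drop) run; defaults to
#'   `length(mask)`.
#' @param min_fraction Minimum retained fraction (default 0.5).
#' @return List: `decision` (`"include"`/`"exclude"`) and `retained_fraction`.
#' @export
retention_check <- function(mask, total_frames = length(mask), min_fraction = 0.5) {
  retained <- sum(!mask) / total_frames
  list(decision = if (retained < min_fraction) "exclude" else "include",
       retained_fraction = retained)
}

#' Expand 6 rigid-body parameters to the 12-parameter motion model
#'
#' The 6 measured parameters plus their first backward differences (first
#' row of the differences defined as 0).
#'
#' @param motion A [motion_trace()] or frames x 6 matrix.
#' @return frames x 12 numeric matrix.
#' @export
expand_motion_params <- function(motion) {
  p <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
  d <- rbind(0, diff(p))
  colnames(d) <- paste0(colnames(p), "_deriv")
  cbind(p, d)
}

#' Regress nuisance signals from ROI time series
#'
#' Per-ROI ordinary-least-squares residuals against an intercept plus the
#' supplied confound columns (nuisance signals and the 12-parameter motion
#' model). A rank-deficient design is an error naming the collinear columns.
#'
#' @param ts A [roi_timeseries()].
#' @param confounds frames x K numeric matrix, aligned to the time series.
#' @return Residual time series (same dimensions).
#' @export
nuisance_regress <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_timeseries"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != n_frames(ts))
    stop("confounds must be aligned to the time series frames", call. = FALSE)
  if (ncol(confounds) >= n_frames(ts))
    stop("more confounds than frames", call. = FALSE)
  if (is.null(colnames(confounds)))
    colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
  X <- cbind(`(Intercept)` = 1, confounds)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qr_x, ts$values)
  roi_timeseries(res, tr_seconds = ts$tr_seconds, roi_ids = ts$roi_ids,
                 run_label = ts$run_label, frame_usable = ts$frame_usable)
}

# Zero-phase IIR filtering applied to every column of a matrix at once;
# numerically identical to running signal::filtfilt per column (asserted in
# the test suite) but avoids per-ROI dispatch overhead.
mat_sigfilter <- function(b, a, X) {
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
  X1 <- stats::filter(Xp, b / a[1], sides = 1, method = "convolution")
  X1 <- X1[nb:nrow(X1), , drop = FALSE]
  as.matrix(stats::filter(X1, -a[-1] / a[1], method = "recursive"))
}

mat_filtfilt <- function(b, a, X) {
  n <- nrow(X)
  pad <- 2 * max(length(a), length(b))
  Y <- mat_sigfilter(b, a, rbind(X, matrix(0, pad, ncol(X))))
  Y <- mat_sigfilter(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y[nrow(Y):1, , drop = FALSE][seq_len(n), , drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass applied forward-backward (zero phase)
#' per ROI; the mean is removed. Band edges must lie inside (0, Nyquist).
#'
#' @param ts A [roi_timeseries()].
#' @param low Low cutoff in Hz (default 0.009).
#' @param high High cutoff in Hz (default 0.08).
#' @param order Filter order (default 4).
#' @return Filtered time series.
#' @export
bandpass_filter <- function(ts, low = 0.009, high = 0.08, order = 4) {
  stopifnot(inherits(ts, "roi_timeseries"))
  fs <- 1 / ts$tr_seconds
  nyq <- fs / 2
  if (!(low > 0 && high > low && high < nyq))
    stop(sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz", low, high, nyq),
         call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  v <- ts$values
  v <- sweep(v, 2, colMeans(v))
  out <- mat_filtfilt(bf$b, bf$a, v)
  out <- sweep(out, 2, colMeans(out))
  roi_timeseries(out, tr_seconds = ts$tr_seconds, roi_ids = ts$roi_ids,
                 run_label = ts$run_label, frame_usable = ts$frame_usable)
}

#' Run the full preprocessing chain on one scan
#'
#' Fixed order: drop initial frames; compute FD and DVARS on the
#' pre-interpolation data; flag high-motion frames with 1-before/2-after
#' expansion; interpolate censored frames; regress nuisance signals (three
#' nuisance columns plus the 12-parameter motion model); band-pass filter.
#'
#' @param ts A [roi_timeseries()].
#' @param motion A [motion_trace()] aligned with `ts`.
#' @param nuisance frames x 3 matrix of global/white-matter/CSF signals
#'   (may have zero columns).
#' @param n_drop Initial frames to drop (default 4).
#' @param fd_thresh,dvars_thresh Censoring thresholds.
#' @param low,high Band-pass edges in Hz.
#' @return List: `ts` (preprocessed series), `fd`, `dvars`, `mask`,
#'   `mean_fd`, `n_censored`, `retained_fraction`, `decision`.
#' @export
preprocess_scan <- function(ts, motion, nuisance = NULL, n_drop = 4,
                            fd_thresh = 0.2, dvars_thresh = 50,
                            low = 0.009, high = 0.08) {
  ts <- drop_initial_frames(ts, n_drop)
  motion <- drop_initial_rows(motion, n_drop)
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0)
    nuisance <- drop_initial_rows(as.matrix(nuisance), n_drop)
  fd <- compute_fd(motion)
  dvars <- compute_dvars(ts)
  mask <- flag_frames(fd, dvars, fd_thresh, dvars_thresh)
  ret <- retention_check(mask)
  if (ret$decision == "exclude") {
    # scan fails QC; denoising a mostly-censored run is meaningless
    return(list(ts = NULL, fd = fd, dvars = dvars, mask = mask,
                mean_fd = mean(fd[-1]), n_censored = sum(mask),
                retained_fraction = ret$retained_fraction,
                decision = "exclude"))
  }
  ts <- interpolate_frames(ts, mask)
  conf <- expand_motion_params(motion)
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0)
    conf <- cbind(as.matrix(nuisance), conf)
  ts <- nuisance_regress(ts, conf)
  ts <- bandpass_filter(ts, low, high)
  list(ts = ts, fd = fd, dvars = dvars, mask = mask,
       mean_fd = mean(fd[-1]), n_censored = sum(mask),
       retained_fraction = ret$retained_fraction, decision = ret$decision)
}
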