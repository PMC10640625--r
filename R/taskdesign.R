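# Canonical-HRF task regressors built from button events, and residualization
# of task time series against them before task-FC computation.

#' Canonical double-gamma HRF kernel
#'
#' The standard double-gamma response (peak delay 6 s, undershoot delay
#' 16 s, peak/undershoot ratio 6, unit dispersions) sampled at the scan TR
#' and scaled to unit peak. The temporal-derivative kernel is the backward
#' finite difference of the main kernel divided by TR.
#'
#' @param tr_seconds Sampling interval (scan TR) in seconds.
#' @param length_seconds Kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma means in seconds (defaults 6, 16).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return List with `time` (sample times), `main` (unit-peak kernel) and
#'   `derivative` (finite-difference kernel).
#' @export
canonical_hrf <- function(tr_seconds, length_seconds = 32,
                          peak_delay = 6, undershoot_delay = 16, ratio = 6) {
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  if (length_seconds < peak_delay)
    stop("kernel length shorter than the response peak delay", call. = FALSE)
  t <- seq(0, length_seconds, by = tr_seconds)
  # unit-rate gamma densities with mode (= shape - 1) at the stated delays
  h <- stats::dgamma(t, shape = peak_delay + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay + 1, rate = 1) / ratio
  h <- h / max(h)
  d <- c(0, diff(h)) / tr_seconds
  list(time = t, main = h, derivative = d)
}

#' Build a task design matrix from a button log
#'
#' Each button type becomes one event type: a zero-duration delta train at
#' the event onset frames, convolved with the canonical HRF and with its
#' temporal derivative, truncated to the run. All columns are mean-centered.
#' Event types with zero events are omitted with a warning; a log with no
#' events at all is an error.
#'
#' @param log A [button_log()].
#' @param frames Number of frames in the (post-drop) run.
#' @param tr_seconds Scan TR in seconds.
#' @param collapse_buttons Model all buttons as a single event type
#'   (default `FALSE`: one pair of regressors per button type).
#' @param hrf Kernel list from [canonical_hrf()]; built from `tr_seconds`
#'   when `NULL`.
#' @param drop_first Number of initial frames removed by preprocessing:
#'   the design is built on the full acquisition grid (onsets are measured
#'   from run start), then its first `drop_first` rows are dropped and the
#'   columns re-centered, keeping it aligned with the trimmed series.
#' @return Object of class `task_design`: list with `X` (frames x K
#'   mean-centered matrix, labeled `<type>_main` / `<type>_deriv`),
#'   `tr_seconds`, `hrf`.
#' @export
build_design <- function(log, frames, tr_seconds, collapse_buttons = FALSE,
                         hrf = NULL, drop_first = 0) {
  stopifnot(inherits(log, "button_log"))
  if (length(log$button) == 0) stop("no events: nothing to regress", call. = FALSE)
  if (max(log$onset_seconds) >= frames * tr_seconds)
    stop("event onset beyond the run", call. = FALSE)
  if (is.null(hrf)) hrf <- canonical_hrf(tr_seconds)
  types <- if (collapse_buttons) list(press = seq_along(log$button)) else
    split(seq_along(log$button), log$button)
  cols <- list()
  for (ty in names(types)) {
    idx <- types[[ty]]
    if (length(idx) == 0) { warning("event type '", ty, "' has zero events; column omitted"); next }
    train <- numeric(frames)
    fr <- floor(log$onset_seconds[idx] / tr_seconds) + 1L
    for (f in fr) train[f] <- train[f] + 1
    main <- stats::convolve(train, rev(hrf$main), type = "open")[seq_len(frames)]
    deriv <- stats::convolve(train, rev(hrf$derivative), type = "open")[seq_len(frames)]
    cols[[paste0(ty, "_main")]] <- as.numeric(main)
    cols[[paste0(ty, "_deriv")]] <- as.numeric(deriv)
  }
  if (length(cols) == 0) stop("no events: nothing to regress", call. = FALSE)
  X <- do.call(cbind, cols)
  if (drop_first > 0) {
    if (drop_first >= frames) stop("drop_first >= frames", call. = FALSE)
    X <- X[-seq_len(drop_first), , drop = FALSE]
  }
  X <- sweep(X, 2, colMeans(X))
  # an event truncated at the run edge can leave a near-zero or collinear
  # column pair; pivot those out rather than fail downstream
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    warning("dropping rank-deficient design column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0) stop("task design is empty after dropping degenerate columns",
                         call. = FALSE)
  structure(list(X = X, tr_seconds = tr_seconds, hrf = hrf),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design: %d frames x %d regressors (%s)>\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Write a design matrix to TSV for audit
#' @param design A `task_design`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  write_tsv(as.data.frame(design$X, check.names = FALSE), path)
}

#' Regress task activations from a task time series
#'
#' Per-ROI OLS residuals of the preprocessed task series against an
#' intercept plus the task design (main + derivative HRF regressors), so
#' that task FC reflects background connectivity rather than evoked
#' responses.
#'
#' @param ts A [roi_timeseries()] (task run, preprocessed).
#' @param design A `task_design` from [build_design()].
#' @return Residual time series.
#' @export
regress_task_activations <- function(ts, design) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(design, "task_design"))
  if (nrow(design$X) != n_frames(ts))
    stop("design and time series frame counts differ", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, design$X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient task design", call. = FALSE)
  res <- qr.resid(qr_x, ts$values)
  roi_timeseries(res, tr_seconds = ts$tr_seconds, roi_ids = ts$roi_ids,
                 run_label = ts$run_label, frame_usable = ts$frame_usable)
}
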