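# Data model and TSV readers/writers for everything the pipeline touches:
# ROI time series, network maps, motion/confound tables, button-event logs
# and participant manifests.

#' ROI time-series object
#'
#' Container for a frames x ROIs signal matrix from one scan run, together
#' with its repetition time, ROI identifiers, per-frame usability mask and
#' run label. This is the object that flows through all preprocessing steps.
#'
#' @param values Numeric matrix, frames x ROIs. Column names, if present,
#'   must match `roi_ids`.
#' @param tr_seconds Positive scalar repetition time in seconds.
#' @param roi_ids Character vector of unique ROI identifiers, one per column.
#' @param run_label One of `"rest"` or `"task"`.
#' @param frame_usable Logical vector, one entry per frame; `FALSE` marks
#'   motion-flagged/interpolated frames. Defaults to all `TRUE`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr_seconds, roi_ids = colnames(values),
                           run_label = c("rest", "task"),
                           frame_usable = rep(TRUE, nrow(values))) {
  run_label <- match.arg(run_label)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(roi_ids)) stop("roi_ids required (no column names on values)", call. = FALSE)
  roi_ids <- as.character(roi_ids)
  if (nrow(values) < 2) stop("time series needs more than one frame", call. = FALSE)
  if (ncol(values) < 2) stop("time series needs more than one ROI", call. = FALSE)
  if (length(roi_ids) != ncol(values))
    stop("roi_ids length (", length(roi_ids), ") != ROI count (", ncol(values), ")", call. = FALSE)
  if (anyDuplicated(roi_ids))
    stop("duplicate roi_ids: ", paste(unique(roi_ids[duplicated(roi_ids)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("time series contains missing or non-finite values", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar", call. = FALSE)
  frame_usable <- as.logical(frame_usable)
  if (length(frame_usable) != nrow(values) || anyNA(frame_usable))
    stop("frame_usable must be a logical vector with one entry per frame", call. = FALSE)
  colnames(values) <- roi_ids
  structure(list(values = values, tr_seconds = tr_seconds, roi_ids = roi_ids,
                 frame_usable = frame_usable, run_label = run_label),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries: %d frames x %d ROIs, TR = %.3f s, run = %s, %d unusable frames>\n",
              nrow(x$values), ncol(x$values), x$tr_seconds, x$run_label,
              sum(!x$frame_usable)))
  invisible(x)
}

n_frames <- function(ts) nrow(ts$values)
n_rois <- function(ts) ncol(ts$values)

#' Read an ROI time-series TSV
#'
#' The file must be tab-separated with a header row of ROI identifiers and
#' one row per frame. Blank or non-numeric cells are hard errors naming the
#' offending row and column; nothing is imputed.
#'
#' @param path Path to the TSV file.
#' @param tr_seconds Repetition time in seconds.
#' @param run_label `"rest"` or `"task"`.
#' @return A [roi_timeseries()] with all frames marked usable.
#' @export
read_timeseries <- function(path, tr_seconds, run_label = c("rest", "task")) {
  run_label <- match.arg(run_label)
  df <- read_tsv_strict(path)
  m <- df_to_matrix(df, path)
  roi_timeseries(m, tr_seconds = tr_seconds, roi_ids = colnames(m),
                 run_label = run_label)
}

#' Write an ROI time-series TSV
#'
#' @param ts A [roi_timeseries()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(ts$values, check.names = FALSE)
  write_tsv(df, path)
}

#' Network map: ROI to network assignment
#'
#' @param roi_id Character vector of unique ROI identifiers (defines the
#'   canonical ROI order for the whole analysis).
#' @param network Character vector assigning each ROI to one network.
#' @param cortical Logical vector flagging cortical ROIs. Defaults to
#'   `network != "subcortical"`.
#' @return An object of class `network_map`: a data.frame with columns
#'   `roi_id`, `network`, `cortical`.
#' @export
network_map <- function(roi_id, network, cortical = NULL) {
  roi_id <- as.character(roi_id)
  network <- as.character(network)
  if (length(roi_id) != length(network))
    stop("roi_id and network must have equal length", call. = FALSE)
  if (anyDuplicated(roi_id))
    stop("duplicate roi_id in network map: ",
         paste(unique(roi_id[duplicated(roi_id)]), collapse = ", "), call. = FALSE)
  if (anyNA(roi_id) || anyNA(network) || any(!nzchar(network)))
    stop("network map contains missing roi_id or network labels", call. = FALSE)
  if (is.null(cortical)) cortical <- network != "subcortical"
  tab <- table(network)
  if (any(tab == 0)) stop("empty network in map", call. = FALSE)
  structure(data.frame(roi_id = roi_id, network = network,
                       cortical = as.logical(cortical),
                       stringsAsFactors = FALSE),
            class = c("network_map", "data.frame"))
}

#' Read a network-map TSV (columns roi_id, network)
#'
#' @param path Path to a two-column TSV.
#' @return A [network_map()] with ROIs in file order.
#' @export
read_network_map <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("roi_id", "network") %in% names(df)))
    stop("network map must have columns roi_id and network", call. = FALSE)
  network_map(df$roi_id, df$network,
              cortical = if ("cortical" %in% names(df)) as.logical(df$cortical) else NULL)
}

#' @rdname read_network_map
#' @param map A [network_map()].
#' @export
write_network_map <- function(map, path) {
  write_tsv(as.data.frame(map), path)
}

#' Networks present in a map
#' @param map A [network_map()].
#' @return Character vector of network labels, in order of first appearance.
#' @export
networks <- function(map) unique(map$network)

network_rois <- function(map, network) {
  if (!network %in% map$network)
    stop("network '", network, "' not in map", call. = FALSE)
  which(map$network == network)
}

#' Conform a time series to the ROI order of a network map
#'
#' ROI ordering is defined by the network map and enforced on every time
#' series at load, so downstream connectivity code can assume a consistent
#' order. A time-series ROI absent from the map (or vice versa) is an error.
#'
#' @param ts A [roi_timeseries()].
#' @param map A [network_map()].
#' @return The time series with columns reordered to map order.
#' @export
conform_timeseries <- function(ts, map) {
  missing_in_map <- setdiff(ts$roi_ids, map$roi_id)
  if (length(missing_in_map) > 0)
    stop("ROI(s) in time series but absent from network map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "), call. = FALSE)
  missing_in_ts <- setdiff(map$roi_id, ts$roi_ids)
  if (length(missing_in_ts) > 0)
    stop("ROI(s) in network map but absent from time series: ",
         paste(utils::head(missing_in_ts, 5), collapse = ", "), call. = FALSE)
  idx <- match(map$roi_id, ts$roi_ids)
  roi_timeseries(ts$values[, idx, drop = FALSE], tr_seconds = ts$tr_seconds,
                 roi_ids = map$roi_id, run_label = ts$run_label,
                 frame_usable = ts$frame_usable)
}

#' Motion trace: rigid-body parameters with FD/DVARS slots
#'
#' @param params Numeric matrix, frames x 6: columns `trans_x`, `trans_y`,
#'   `trans_z` (mm), `rot_x`, `rot_y`, `rot_z` (radians).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  want <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (ncol(params) != 6)
    stop("motion trace needs 6 columns (3 translations, 3 rotations)", call. = FALSE)
  if (is.null(colnames(params))) colnames(params) <- want
  if (!identical(colnames(params), want))
    params <- params[, want, drop = FALSE]
  if (!all(is.finite(params)))
    stop("non-finite motion parameters", call. = FALSE)
  structure(list(params = params, fd = NULL, dvars = NULL),
            class = "motion_trace")
}

#' Read a confounds TSV (motion + nuisance signals)
#'
#' Expects columns `trans_x`..`rot_z` and, if present, `global_signal`,
#' `white_matter`, `csf`.
#'
#' @param path Path to the TSV.
#' @return List with `motion` (a [motion_trace()]) and `nuisance` (numeric
#'   matrix of the nuisance-signal columns, possibly zero columns).
#' @export
read_confounds <- function(path) {
  want <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  df <- read_tsv_strict(path)
  if (!all(want %in% names(df)))
    stop("confounds file must contain columns ", paste(want, collapse = ", "), call. = FALSE)
  nuis_cols <- intersect(c("global_signal", "white_matter", "csf"), names(df))
  m <- df_to_matrix(df[c(want, nuis_cols)], path)
  list(motion = motion_trace(m[, want, drop = FALSE]),
       nuisance = m[, nuis_cols, drop = FALSE])
}

#' Button-press event log
#'
#' Ordered button events from a breath-counting run. Events arriving out of
#' onset order are sorted with a warning; onsets outside `[0, run_duration)`
#' are errors.
#'
#' @param onset_seconds Numeric vector of event onsets (seconds from run start).
#' @param button Character vector in `{"count", "nine", "lost"}`.
#' @param run_duration_seconds Scalar run duration.
#' @return An object of class `button_log`.
#' @export
button_log <- function(onset_seconds, button, run_duration_seconds) {
  onset_seconds <- as.numeric(onset_seconds)
  button <- as.character(button)
  if (length(onset_seconds) != length(button))
    stop("onset and button vectors must have equal length", call. = FALSE)
  bad <- setdiff(unique(button), c("count", "nine", "lost"))
  if (length(bad) > 0)
    stop("unknown button value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(onset_seconds) || any(!is.finite(onset_seconds)))
    stop("non-finite onsets", call. = FALSE)
  if (any(onset_seconds < 0) || any(onset_seconds >= run_duration_seconds))
    stop("onset outside [0, run_duration)", call. = FALSE)
  if (is.unsorted(onset_seconds)) {
    warning("event onsets were not sorted; sorting by onset")
    o <- order(onset_seconds)
    onset_seconds <- onset_seconds[o]
    button <- button[o]
  }
  structure(list(onset_seconds = onset_seconds, button = button,
                 run_duration_seconds = run_duration_seconds),
            class = "button_log")
}

#' @export
print.button_log <- function(x, ...) {
  cat(sprintf("<button_log: %d events over %.1f s (%d count / %d nine / %d lost)>\n",
              length(x$button), x$run_duration_seconds,
              sum(x$button == "count"), sum(x$button == "nine"),
              sum(x$button == "lost")))
  invisible(x)
}

#' Read a BIDS-style events TSV into a button log
#'
#' Expects columns `onset`, `duration`, `trial_type`. `trial_type` values are
#' mapped to buttons through `trial_type_map`; unmapped values are an error
#' listing the offending labels.
#'
#' @param path Path to the events TSV.
#' @param run_duration_seconds Run duration in seconds.
#' @param trial_type_map Named character vector mapping trial_type values to
#'   `{"count", "nine", "lost"}`.
#' @return A [button_log()].
#' @export
read_events <- function(path, run_duration_seconds,
                        trial_type_map = c(count = "count", nine = "nine", lost = "lost")) {
  df <- read_tsv_strict(path, numeric_cols = "onset")
  if (!all(c("onset", "trial_type") %in% names(df)))
    stop("events file must have columns onset and trial_type", call. = FALSE)
  tt <- as.character(df$trial_type)
  unmapped <- setdiff(unique(tt), names(trial_type_map))
  if (length(unmapped) > 0)
    stop("unmapped trial_type value(s): ", paste(unmapped, collapse = ", "), call. = FALSE)
  button_log(df$onset, unname(trial_type_map[tt]), run_duration_seconds)
}

#' @rdname read_events
#' @param log A [button_log()].
#' @export
write_events <- function(log, path) {
  write_tsv(data.frame(onset = log$onset_seconds, duration = 0,
                       trial_type = log$button), path)
}

#' Read a participant manifest TSV
#'
#' Columns: `participant_id`, `group` (`MBTI`/`SHEEP`), `age` (years),
#' `gender` (binary code, 1 = female).
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with validated columns.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_strict(path, numeric_cols = c("age", "gender"))
  need <- c("participant_id", "group", "age", "gender")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id in manifest", call. = FALSE)
  bad <- setdiff(unique(df$group), c("MBTI", "SHEEP"))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Default 430-ROI, 9-network map
#'
#' Builds the package's standard ROI -> network assignment abstraction:
#' 8 cortical networks (sizes summing to `n_cortical`) plus one subcortical
#' network, mirroring a 400-parcel cortical atlas with 30 subcortical
#' regions grouped into 9 networks. Only the assignment is modeled, not
#' atlas geometry.
#'
#' @param n_cortical Total cortical ROI count (default 400).
#' @param n_subcortical Subcortical ROI count (default 30).
#' @return A [network_map()] with 9 networks.
#' @export
default_network_map <- function(n_cortical = 400, n_subcortical = 30) {
  base_sizes <- c(visual = 58, somatomotor = 70, dorsal_attention = 46,
                  salience = 47, limbic = 26, executive_control = 52,
                  default_mode = 77, temporal_parietal = 24)
  sizes <- round(base_sizes / sum(base_sizes) * n_cortical)
  sizes[length(sizes)] <- sizes[length(sizes)] + (n_cortical - sum(sizes))
  if (any(sizes < 1)) stop("n_cortical too small for 8 networks", call. = FALSE)
  net <- c(rep(names(sizes), sizes), rep("subcortical", n_subcortical))
  ids <- sprintf("ROI_%03d", seq_along(net))
  network_map(ids, net)
}
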