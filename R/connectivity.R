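# Fisher-z functional connectivity matrices and network-averaged FC.

#' Fisher-z FC matrix from an ROI time series
#'
#' Pairwise Pearson correlations over frames, clipped to |r| <= 1 - 1e-7
#' (so the transform stays finite on degenerate fixtures), then Fisher
#' r-to-z transformed (atanh). The diagonal is stored as 0 and never used.
#'
#' @param ts A [roi_timeseries()].
#' @param condition Condition label; defaults to the run label.
#' @param clip Correlation clip bound (default `1 - 1e-7`).
#' @return Object of class `fc_matrix`: list with `z` (R x R symmetric
#'   matrix), `condition`, `roi_ids`.
#' @export
compute_fc <- function(ts, condition = ts$run_label, clip = 1 - 1e-7) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (n_frames(ts) < 3) stop("FC needs at least 3 frames", call. = FALSE)
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant ROI time series: ",
         paste(ts$roi_ids[sds == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(ts$values)
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  fc_matrix(z, condition = condition, roi_ids = ts$roi_ids)
}

#' Construct an FC matrix object
#'
#' @param z R x R symmetric numeric matrix of Fisher-z values, zero diagonal.
#' @param condition `"rest"` or `"task"`.
#' @param roi_ids ROI identifiers bound to the row/column order.
#' @return An `fc_matrix`.
#' @export
fc_matrix <- function(z, condition = c("rest", "task"), roi_ids = colnames(z)) {
  condition <- match.arg(condition)
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("FC matrix must be square", call. = FALSE)
  if (is.null(roi_ids)) roi_ids <- sprintf("ROI_%03d", seq_len(ncol(z)))
  if (max(abs(z - t(z))) > 1e-12) stop("FC matrix not symmetric", call. = FALSE)
  if (!all(is.finite(z))) stop("non-finite FC values", call. = FALSE)
  dimnames(z) <- list(roi_ids, roi_ids)
  structure(list(z = z, condition = condition, roi_ids = as.character(roi_ids)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix: %d x %d ROIs, condition = %s>\n",
              nrow(x$z), ncol(x$z), x$condition))
  invisible(x)
}

#' Write / read an FC matrix as square TSV with ROI header row and column
#' @param fc An `fc_matrix`.
#' @param path File path.
#' @export
write_fc <- function(fc, path) {
  df <- data.frame(roi_id = fc$roi_ids, fc$z, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_fc
#' @param condition Condition label for the matrix being read.
#' @export
read_fc <- function(path, condition = c("rest", "task")) {
  condition <- match.arg(condition)
  df <- read_tsv_strict(path)
  ids <- as.character(df$roi_id)
  m <- df_to_matrix(df[setdiff(names(df), "roi_id")], path)
  fc_matrix(m, condition = condition, roi_ids = ids)
}

#' Network-averaged FC
#'
#' Mean Fisher-z FC over a network's edge set: for `scope = "intra"` the
#' n(n-1)/2 unique within-network values; for `scope = "inter"` the
#' n x (R - n) values linking the network's ROIs to all other ROIs.
#'
#' @param fc An `fc_matrix`.
#' @param map A [network_map()] sharing the ROI order.
#' @param network Network label.
#' @param scope `"intra"` or `"inter"`.
#' @return Scalar mean z value.
#' @export
network_mean_fc <- function(fc, map, network, scope = c("intra", "inter")) {
  scope <- match.arg(scope)
  mean(vectorize_block(fc, map, network, scope, min_intra = 2))
}
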