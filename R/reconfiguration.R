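# The core statistic: network-level rest-task FC similarity
# ("reconfiguration efficiency"), intranetwork and internetwork.

#' Extract a network's FC values as an ordered vector
#'
#' Canonical vector orders (frozen so rest and task vectors are always
#' index-aligned): for `scope = "intra"`, the n(n-1)/2 unique upper-triangle
#' values of the within-network block enumerated row-major ((1,2), (1,3),
#' ..., (2,3), ...); for `scope = "inter"`, the n x (R - n) cross-block
#' values (network ROIs as rows, all remaining ROIs in map order as
#' columns) flattened column-major.
#'
#' @param fc An `fc_matrix`.
#' @param map A [network_map()] sharing the ROI order.
#' @param network Network label.
#' @param scope `"intra"` or `"inter"`.
#' @param min_intra Minimum network size for the intra scope (default 3,
#'   below which the downstream spatial correlation is degenerate).
#' @return Numeric vector of Fisher-z FC values.
#' @export
vectorize_block <- function(fc, map, network, scope = c("intra", "inter"),
                            min_intra = 3) {
  scope <- match.arg(scope)
  stopifnot(inherits(fc, "fc_matrix"))
  if (!identical(fc$roi_ids, map$roi_id))
    stop("FC matrix ROI order does not match the network map", call. = FALSE)
  idx <- network_rois(map, network)
  if (scope == "intra") {
    if (length(idx) < min_intra)
      stop("network '", network, "' has fewer than ", min_intra,
           " ROIs; intranetwork block degenerate", call. = FALSE)
    block <- t(fc$z[idx, idx, drop = FALSE])  # row-major upper triangle
    block[lower.tri(block)]
  } else {
    other <- setdiff(seq_len(nrow(fc$z)), idx)
    if (length(other) == 0)
      stop("network '", network, "' spans all ROIs; no internetwork edges", call. = FALSE)
    as.vector(fc$z[idx, other, drop = FALSE])
  }
}

#' Rest-task FC similarity for one network
#'
#' The Pearson correlation between a network's FC values in the resting
#' state and the same (index-aligned) FC values in the task state, Fisher
#' r-to-z transformed. Higher similarity means less rest-task
#' reconfiguration, i.e. more efficient reconfiguration.
#'
#' @param fc_rest,fc_task `fc_matrix` objects sharing the map's ROI order.
#' @param map A [network_map()].
#' @param network Network label.
#' @param scope `"intra"` or `"inter"`.
#' @param clip Correlation clip bound before atanh (default `1 - 1e-7`).
#' @return Scalar `similarity_z`.
#' @export
similarity <- function(fc_rest, fc_task, map, network,
                       scope = c("intra", "inter"), clip = 1 - 1e-7) {
  scope <- match.arg(scope)
  a <- vectorize_block(fc_rest, map, network, scope)
  b <- vectorize_block(fc_task, map, network, scope)
  if (length(a) < 3) stop("similarity needs at least 3 FC values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance FC block for network '", network, "'", call. = FALSE)
  r <- stats::cor(a, b)
  atanh(pmin(pmax(r, -clip), clip))
}

#' Build the long similarity table for a cohort
#'
#' For every participant with complete data (both timepoints, both
#' conditions), computes one `similarity_z` per timepoint x network x scope.
#' Participants with a missing condition are skipped with a logged reason.
#'
#' @param fc_pairs Named list (by participant id); each element a list with
#'   elements `pre` and `post`, each a list with `rest` and `task`
#'   `fc_matrix` objects.
#' @param map A [network_map()].
#' @param manifest Manifest data.frame with `participant_id` and `group`
#'   (used to annotate rows); optional.
#' @return List: `table` (data.frame with columns participant_id, group,
#'   timepoint, network, scope, similarity_z) and `skipped` (data.frame of
#'   skipped participants and reasons).
#' @export
build_similarity_table <- function(fc_pairs, map, manifest = NULL) {
  nets <- networks(map)
  rows <- list()
  skipped <- list()
  for (pid in names(fc_pairs)) {
    pp <- fc_pairs[[pid]]
    missing <- character(0)
    for (tp in c("pre", "post")) for (cond in c("rest", "task"))
      if (is.null(pp[[tp]][[cond]])) missing <- c(missing, paste(tp, cond))
    if (length(missing) > 0) {
      skipped[[pid]] <- data.frame(participant_id = pid,
                                   reason = paste("missing", paste(missing, collapse = "; ")),
                                   stringsAsFactors = FALSE)
      next
    }
    grp <- if (!is.null(manifest))
      manifest$group[match(pid, manifest$participant_id)] else NA_character_
    for (tp in c("pre", "post")) for (net in nets) for (sc in c("intra", "inter")) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, group = grp, timepoint = tp, network = net,
        scope = sc,
        similarity_z = similarity(pp[[tp]]$rest, pp[[tp]]$task, map, net, sc),
        stringsAsFactors = FALSE)
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(participant_id = character(0), group = character(0),
                    timepoint = character(0), network = character(0),
                    scope = character(0), similarity_z = numeric(0)),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(participant_id = character(0), reason = character(0)))
}
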