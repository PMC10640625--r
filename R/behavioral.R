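# Behavioral scoring: breath-counting task (BCT) cycles and accuracy,
# FFMQ facet/total sums, and behavioral exclusion rules.

#' Segment a button log into breath-counting cycles
#'
#' Cycles are delimited purely by terminator presses: each cycle runs from
#' the first event after the previous terminator up to and including the
#' next `nine` or `lost` press. A trailing run of count presses with no
#' terminator is returned with `terminator = "end"` and is incomplete.
#'
#' @param log A [button_log()].
#' @return Data frame with one row per cycle: `n_count` (count-press tally)
#'   and `terminator` (`"nine"`, `"lost"` or `"end"`). Zero rows for an
#'   empty log.
#' @export
parse_cycles <- function(log) {
  stopifnot(inherits(log, "button_log"))
  btn <- log$button
  out_n <- integer(0); out_t <- character(0)
  tally <- 0L; open <- FALSE
  for (b in btn) {
    if (b == "count") {
      tally <- tally + 1L; open <- TRUE
    } else {                      # terminator: nine or lost
      out_n <- c(out_n, tally); out_t <- c(out_t, b)
      tally <- 0L; open <- FALSE
    }
  }
  if (open) { out_n <- c(out_n, tally); out_t <- c(out_t, "end") }
  data.frame(n_count = out_n, terminator = out_t, stringsAsFactors = FALSE)
}

#' Score breath-counting-task accuracy
#'
#' A correct cycle is exactly eight count presses followed by one press of
#' the second ("nine") button. Lost-count cycles end the cycle and count it
#' as incorrect (configurable via `count_lost_cycles`). The trailing
#' incomplete cycle is excluded from numerator and denominator. Accuracy is
#' correct cycles / completed cycles; with zero completed cycles the
#' accuracy is undefined and returned as `NA` (never 0/0).
#'
#' @param log A [button_log()].
#' @param count_lost_cycles Should lost-count cycles enter the denominator?
#'   Default `TRUE`.
#' @return List of class `bct_score`: `n_cycles`, `n_correct`, `accuracy`
#'   (`NA_real_` when undefined).
#' @export
score_bct <- function(log, count_lost_cycles = TRUE) {
  cyc <- parse_cycles(log)
  cyc <- cyc[cyc$terminator != "end", , drop = FALSE]
  if (!count_lost_cycles)
    cyc <- cyc[cyc$terminator != "lost", , drop = FALSE]
  n_cycles <- nrow(cyc)
  n_correct <- sum(cyc$n_count == 8L & cyc$terminator == "nine")
  structure(list(n_cycles = n_cycles, n_correct = n_correct,
                 accuracy = if (n_cycles > 0) n_correct / n_cycles else NA_real_),
            class = "bct_score")
}

#' @export
print.bct_score <- function(x, ...) {
  cat(sprintf("<bct_score: %d/%d correct cycles, accuracy %s>\n",
              x$n_correct, x$n_cycles,
              if (is.na(x$accuracy)) "undefined" else sprintf("%.3f", x$accuracy)))
  invisible(x)
}

#' Breath-counting-task exclusion rule
#'
#' Participants with less than 50% task accuracy are excluded; the boundary
#' is inclusive (accuracy exactly 0.50 is kept). Undefined accuracy (no
#' completed cycles) excludes.
#'
#' @param score A `bct_score` from [score_bct()].
#' @param threshold Accuracy threshold, default 0.5.
#' @return List: `decision` (`"include"`/`"exclude"`) and `reason`.
#' @export
bct_exclusion <- function(score, threshold = 0.5) {
  stopifnot(inherits(score, "bct_score"))
  if (is.na(score$accuracy))
    return(list(decision = "exclude", reason = "no completed cycles"))
  if (score$accuracy < threshold)
    return(list(decision = "exclude",
                reason = sprintf("accuracy %.3f < %.2f", score$accuracy, threshold)))
  list(decision = "include", reason = "")
}

#' FFMQ-39 item-to-facet assignment
#'
#' The published 39-item key: Observing, Describing, Acting with awareness
#' and Nonjudging have 8 items each; Nonreactivity has 7.
#'
#' @return Named list of integer item indices per facet.
#' @export
ffmq_facets <- function() {
  list(observing     = c(1L, 6L, 11L, 15L, 20L, 26L, 31L, 36L),
       describing    = c(2L, 7L, 12L, 16L, 22L, 27L, 32L, 37L),
       awareness     = c(5L, 8L, 13L, 18L, 23L, 28L, 34L, 38L),
       nonjudging    = c(3L, 10L, 14L, 17L, 25L, 30L, 35L, 39L),
       nonreactivity = c(4L, 9L, 19L, 21L, 24L, 29L, 33L))
}

#' Published FFMQ-39 reverse-keyed item set
#'
#' Scoring defaults to plain sums (empty reverse-key set); pass this set to
#' [score_ffmq()] to apply the published key.
#'
#' @return Integer vector of reverse-keyed item indices.
#' @export
ffmq_reverse_items <- function() {
  sort(c(12L, 16L, 22L,                         # describing
         5L, 8L, 13L, 18L, 23L, 28L, 34L, 38L,  # awareness
         3L, 10L, 14L, 17L, 25L, 30L, 35L, 39L)) # nonjudging
}

#' Score a 39-item FFMQ response
#'
#' Reverse-keyed items are mapped r -> 6 - r before summation. Subscale
#' scores are sums of item ratings within each facet; the total is the sum
#' of the five subscale scores (range 39-195).
#'
#' @param ratings Integer vector of 39 item ratings, each in 1-5.
#' @param reverse_items Integer vector of reverse-keyed item indices
#'   (default empty: plain sums).
#' @param facets Item-to-facet assignment, default [ffmq_facets()].
#' @return List of class `ffmq_score`: the five facet sums and `total`.
#' @export
score_ffmq <- function(ratings, reverse_items = integer(0), facets = ffmq_facets()) {
  ratings <- as.numeric(ratings)
  if (length(ratings) != 39)
    stop("FFMQ response must have 39 items, got ", length(ratings), call. = FALSE)
  bad <- which(is.na(ratings) | ratings < 1 | ratings > 5 | ratings != round(ratings))
  if (length(bad) > 0)
    stop("invalid FFMQ rating at item ", bad[1], ": must be an integer in 1-5",
         call. = FALSE)
  if (!identical(sort(unlist(facets, use.names = FALSE)), 1:39))
    stop("facet assignment must partition items 1-39", call. = FALSE)
  r <- ratings
  r[reverse_items] <- 6 - r[reverse_items]
  sums <- vapply(facets, function(idx) sum(r[idx]), numeric(1))
  structure(c(as.list(sums), list(total = sum(sums))), class = "ffmq_score")
}

#' Screen a measure vector for >3 SD outliers
#'
#' Values more than `k` standard deviations from the mean (mean and SD over
#' the supplied vector) are flagged for exclusion. A zero-variance vector
#' yields no exclusions; fewer than 3 values is an error (the SD criterion
#' is undefined).
#'
#' @param values Numeric vector, one value per participant.
#' @param k SD multiplier, default 3.
#' @return Logical inclusion mask (`TRUE` = keep), same length as `values`.
#' @export
outlier_filter <- function(values, k = 3) {
  values <- as.numeric(values)
  if (length(values) < 3)
    stop("outlier screen needs at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("outlier screen: missing values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}
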