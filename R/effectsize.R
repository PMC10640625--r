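# Nonparametric effect size and baseline group comparisons.

#' Cliff's delta
#'
#' delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y), in [-1, 1].
#' Positive values mean `x` tends to exceed `y`; for a post-vs-pre
#' comparison pass post as `x` and pre as `y`.
#'
#' @param x,y Nonempty numeric samples.
#' @return List of class `effect_size`: `cliffs_delta` and `comparison`.
#' @param comparison Optional label for the comparison.
#' @export
cliffs_delta <- function(x, y, comparison = "x-y") {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  d <- mean(sign(outer(x, y, "-")))
  structure(list(cliffs_delta = d, comparison = comparison),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<Cliff's delta (%s) = %.3f>\n", x$comparison, x$cliffs_delta))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Uses exact enumeration
#' when `n_x * n_y <= 400` and there are no ties, otherwise the
#' tie-corrected normal approximation with continuity correction. U is the
#' number of (x, y) pairs with x > y (+ half the ties).
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
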