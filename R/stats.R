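#' Two-sided Wilcoxon rank-sum comparison of edge-weight multisets
#'
#' Reports the rank-sum statistic `W` of the first sample (midranks for
#' ties).  For small samples (`n1 + n2 <= 20`) without ties the p-value is
#' exact, by enumeration over the `choose(n1 + n2, n1)` equally likely rank
#' assignments; otherwise the normal approximation with variance tie
#' correction and continuity correction is used.  p-values below `1e-300`
#' are flagged as underflowed (reported as computed, but at that magnitude
#' the value is a floating-point floor rather than a meaningful tail mass).
#'
#' @param x,y non-empty numeric vectors (e.g. from [group_edge_weights()]).
#' @return object of class `"wilcoxon_result"`: list(statistic, n1, n2,
#'   p_two_sided, method, underflow).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("wilcoxon_rank_sum needs two non-empty samples")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2 <= 20) && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  p <- min(1, wt$p.value)
  structure(list(statistic = unname(wt$statistic) + n1 * (n1 + 1) / 2,
                 n1 = n1, n2 = n2, p_two_sided = p,
                 method = if (exact) "exact" else "normal_approx",
                 underflow = p < 1e-300),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon rank-sum (", x$method, "): W = ", x$statistic,
      ", n = ", x$n1, "+", x$n2, ", two-sided p = ",
      format(x$p_two_sided, digits = 4),
      if (x$underflow) " [underflow floor]" else "", "\n", sep = "")
  invisible(x)
}
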