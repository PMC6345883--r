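#' Fisher exact static pairwise comparison
#'
#' The robust static comparator: for each feature, counts are summed within
#' the two time-point groups and tested against the remaining library mass
#' in a 2x2 table
#' `{feature count in group 0, in group 1; rest of group 0, rest of group 1}`.
#' The two-sided p-value is computed by hypergeometric point-mass summation:
#' the probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's are summed.
#' Benjamini-Hochberg adjusted q-values are returned alongside. A group with
#' zero total counts yields p = 1 and is flagged.
#'
#' @param cm pooled [count_matrix].
#' @param st [sample_table] for its columns.
#' @param t0,t1 the two compared time-point labels.
#' @return data.frame with `feature_id`, group sums, `log2_fc` (computed
#'   with a 0.5 pseudocount on the group proportions), `p_value`, `q_value`
#'   and `flagged`.
#' @export
fisher_exact_static <- function(cm, st, t0, t1) {
  st <- st[match(colnames(cm), st$sample_id), , drop = FALSE]
  st <- st[!st$excluded, , drop = FALSE]
  g0 <- st$sample_id[st$time_point == t0]
  g1 <- st$sample_id[st$time_point == t1]
  if (!length(g0) || !length(g1)) stop("both groups must be non-empty")
  n0 <- rowSums(unclass(cm)[, g0, drop = FALSE])
  n1 <- rowSums(unclass(cm)[, g1, drop = FALSE])
  N0 <- sum(n0); N1 <- sum(n1)
  flagged <- N0 == 0 || N1 == 0
  p <- if (flagged) rep(1, length(n0)) else
    mapply(fisher_p2, n0, n1, MoreArgs = list(N0 = N0, N1 = N1))
  log2_fc <- log2(((n1 + 0.5) / (N1 + 1)) / ((n0 + 0.5) / (N0 + 1)))
  data.frame(feature_id = rownames(cm),
             count_t0 = n0, count_t1 = n1, log2_fc = log2_fc,
             p_value = p, q_value = stats::p.adjust(p, "BH"),
             flagged = flagged, stringsAsFactors = FALSE)
}

# Two-sided Fisher exact p for the table (x0, x1; N0 - x0, N1 - x1):
# X ~ Hypergeometric with m = x0 + x1 draws from an urn of N0 + N1, summing
# point masses <= the observed one (with a small relative slack against
# floating-point ties, as is conventional).
fisher_p2 <- function(x0, x1, N0, N1) {
  m <- x0 + x1
  if (m == 0) return(1)
  support <- max(0, m - N1):min(m, N0)
  d <- stats::dhyper(support, N0, N1, m)
  sum(d[d <= d[support == x0] * (1 + 1e-7)])
}
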