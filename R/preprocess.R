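#' Pool technical replicates by summing counts
#'
#' Technical replicates of one biological sample (shared `tech_rep_group`)
#' are pooled by summing their mapped-read counts into one column, which
#' increases effective depth without averaging away the count nature of the
#' data. Samples flagged `excluded` are dropped first. The pooled sample
#' table keeps one row per group; lane and batch become `"mixed"` when the
#' replicates of a group disagree.
#'
#' @param cm a [count_matrix].
#' @param st a [sample_table] covering the columns of `cm`.
#' @return list with elements `counts` (pooled [count_matrix], one column
#'   per `tech_rep_group`) and `samples` (pooled [sample_table]).
#' @export
pool_technical_replicates <- function(cm, st) {
  if (!all(colnames(cm) %in% st$sample_id))
    stop("sample(s) missing from the sample table: ",
         paste(setdiff(colnames(cm), st$sample_id), collapse = ", "))
  st <- st[match(colnames(cm), st$sample_id), , drop = FALSE]
  keep <- !st$excluded
  if (!any(keep)) stop("all samples are excluded")
  cm_use <- cm[, keep, drop = FALSE]
  st_use <- st[keep, , drop = FALSE]
  groups <- unique(st_use$tech_rep_group)
  empty <- setdiff(unique(st$tech_rep_group), groups)
  if (length(empty))
    stop("tech_rep_group(s) empty after exclusions: ", paste(empty, collapse = ", "))

  g <- factor(st_use$tech_rep_group, levels = groups)
  pooled <- vapply(groups, function(gr)
    as.integer(rowSums(cm_use[, g == gr, drop = FALSE])),
    integer(nrow(cm_use)))
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = nrow(cm_use))
  dimnames(pooled) <- list(rownames(cm_use), groups)

  mix <- function(x) if (length(unique(x)) == 1L) x[1] else "mixed"
  meta <- do.call(rbind, lapply(groups, function(gr) {
    rows <- st_use[g == gr, , drop = FALSE]
    data.frame(sample_id = gr,
               subject_id = rows$subject_id[1],
               time_point = as.character(rows$time_point[1]),
               lane = mix(as.character(rows$lane)),
               batch = mix(as.character(rows$batch)),
               tech_rep_group = gr,
               excluded = FALSE,
               stringsAsFactors = FALSE)
  }))
  list(counts = count_matrix(pooled, attr(cm, "feature_level") %||% "gene"),
       samples = sample_table(meta, time_levels = levels(st$time_point)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter features by minimum expression
#'
#' Keeps features with counts of at least `min_count` in at least
#' `min_samples` samples; row order is preserved.
#'
#' @param cm a [count_matrix].
#' @param min_count minimum count per sample.
#' @param min_samples minimum number of samples reaching `min_count`.
#' @return the filtered [count_matrix] (possibly with zero rows).
#' @export
filter_low_expression <- function(cm, min_count = 1L, min_samples = 1L) {
  if (min_count < 0 || min_samples < 0) stop("thresholds must be >= 0")
  keep <- rowSums(cm >= min_count) >= min_samples
  out <- cm[keep, , drop = FALSE]
  count_matrix(out, attr(cm, "feature_level") %||% "gene")
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed as in the median-of-ratios
#' scheme: the reference is the per-feature geometric mean over samples,
#' restricted to features positive in every sample; each sample's factor is
#' the median of its count-to-reference ratios, rescaled so the factors
#' have geometric mean 1.
#'
#' @param cm a [count_matrix].
#' @return named numeric vector of class `size_factors` (all positive,
#'   geometric mean 1), with attribute `method`.
#' @export
size_factors <- function(cm) {
  m <- unclass(cm)
  storage.mode(m) <- "double"
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no feature has positive counts in all samples; filter the matrix first")
  lref <- rowMeans(log(m[pos, , drop = FALSE]))
  f <- apply(exp(sweep(log(m[pos, , drop = FALSE]), 1, lref)), 2, stats::median)
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, colnames(m)), method = "median-of-ratios",
            class = "size_factors")
}

#' Log2 normalized expression matrix
#'
#' `log2(count / size_factor + pseudocount)`, the working scale for sample
#' diagnostics and unwanted-variation estimation.
#'
#' @param cm a [count_matrix].
#' @param sf [size_factors] for its columns (computed if omitted).
#' @param pseudocount positive offset, default 1.
#' @return numeric matrix with the dimensions and dimnames of `cm`.
#' @export
log_normalized <- function(cm, sf = NULL, pseudocount = 1) {
  if (is.null(sf)) sf <- size_factors(cm)
  if (length(sf) != ncol(cm))
    stop("size factors do not match the number of samples")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  m <- sweep(unclass(cm), 2, as.numeric(sf), "/")
  log2(m + pseudocount)
}
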