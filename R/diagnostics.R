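#' Pearson correlation between sample columns
#'
#' The sample-by-sample correlation matrix underlying the reproducibility
#' heatmap. Zero-variance samples have undefined correlations; their
#' off-diagonal entries are reported as `NA` and the offending sample ids
#' are recorded in the `"degenerate"` attribute (such samples are
#' auto-flagged by [flag_outliers()]).
#'
#' @param logmat numeric matrix (features x samples), e.g. from
#'   [log_normalized()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(logmat) {
  if (ncol(logmat) < 2L || nrow(logmat) < 2L)
    stop("need at least 2 samples and 2 features")
  sds <- apply(logmat, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  cc <- suppressWarnings(stats::cor(logmat))
  cc[zero, ] <- NA_real_
  cc[, zero] <- NA_real_
  diag(cc) <- 1
  attr(cc, "degenerate") <- colnames(logmat)[zero]
  cc
}

# Fix the sign of each embedding axis so its largest-magnitude coordinate is
# positive; classical MDS and PCA are otherwise determined only up to sign.
fix_axis_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    v <- coords[, j]
    if (all(!is.finite(v)) || all(v == 0)) next
    if (v[which.max(abs(v))] < 0) coords[, j] <- -v
  }
  coords
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS on the distance `1 - correlation`: the squared-distance
#' matrix is double-centered and eigendecomposed, and the top-`d`
#' eigenvector columns scaled by the square root of their eigenvalues are
#' returned. Deterministic; each axis is oriented so its largest-magnitude
#' coordinate is positive.
#'
#' @param corr sample correlation matrix from [sample_correlation()].
#' @param d number of dimensions (2 or 3).
#' @return samples x d coordinate matrix (fewer columns, with a warning,
#'   when fewer positive eigenvalues exist).
#' @export
mds_embedding <- function(corr, d = 2L) {
  if (!d %in% c(2L, 3L)) stop("d must be 2 or 3")
  if (anyNA(corr))
    stop("correlation matrix contains NA (degenerate samples); drop them first")
  dist <- 1 - corr
  k <- min(d, ncol(corr) - 1L)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = k, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < d)
    warning("only ", ncol(coords), " positive eigenvalue(s); returning ",
            ncol(coords), " axis/axes")
  rownames(coords) <- rownames(corr)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  fix_axis_signs(coords)
}

#' Principal component embedding of samples
#'
#' Feature-centered PCA of the samples: each feature (row of `logmat`) is
#' centered and the samples' scores on the top-`d` components are returned
#' together with the per-component explained-variance fractions. Axes follow
#' the same sign convention as [mds_embedding()].
#'
#' @param logmat numeric matrix (features x samples).
#' @param d number of components.
#' @return list with `coords` (samples x d) and `explained` (fractions,
#'   non-increasing, summing to at most 1).
#' @export
pca_embedding <- function(logmat, d = 2L) {
  if (ncol(logmat) < 2L) stop("need at least 2 samples")
  p <- stats::prcomp(t(logmat), center = TRUE, scale. = FALSE)
  d <- min(d, ncol(p$x))
  coords <- fix_axis_signs(p$x[, seq_len(d), drop = FALSE])
  rownames(coords) <- colnames(logmat)
  explained <- (p$sdev^2 / sum(p$sdev^2))[seq_len(d)]
  list(coords = coords, explained = explained)
}

#' Flag outlier samples by median correlation
#'
#' A sample is flagged when the median of its off-diagonal correlations to
#' all other samples falls below `threshold`. The default 0.7 sits between
#' typical within-lane reproducibility (~0.9) and cross-lane correlations
#' (~0.5) of degraded libraries, so it targets sample-quality outliers
#' rather than lane structure. Samples with undefined (NA) correlations are
#' always flagged. Raising the threshold never unflags a sample.
#'
#' @param corr sample correlation matrix.
#' @param threshold median-correlation threshold, default 0.7.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(corr, threshold = 0.7) {
  n <- ncol(corr)
  med <- vapply(seq_len(n), function(j) stats::median(corr[-j, j]), numeric(1))
  flagged <- is.na(med) | med < threshold
  colnames(corr)[flagged]
}

#' Full sample-diagnostics report
#'
#' Runs the exploratory pipeline stage in one call: size factors, log2
#' normalization, sample correlations, MDS and PCA embeddings, per-sample
#' median correlations and outlier flags.
#'
#' @param cm a [count_matrix].
#' @param d embedding dimension (2 or 3).
#' @param pseudocount pseudocount for [log_normalized()].
#' @param outlier_threshold threshold for [flag_outliers()].
#' @return list of class `diagnostics_report` with elements `correlation`,
#'   `mds`, `pca`, `explained`, `median_correlation`, `flagged_outliers`,
#'   `size_factors`.
#' @export
diagnostics_report <- function(cm, d = 2L, pseudocount = 1,
                               outlier_threshold = 0.7) {
  sf <- size_factors(cm)
  lm <- log_normalized(cm, sf, pseudocount)
  cc <- sample_correlation(lm)
  med <- vapply(seq_len(ncol(cc)), function(j) stats::median(cc[-j, j]), numeric(1))
  names(med) <- colnames(cc)
  flagged <- flag_outliers(cc, outlier_threshold)
  cc_mds <- cc
  if (length(attr(cc, "degenerate"))) {
    keep <- setdiff(colnames(cc), attr(cc, "degenerate"))
    cc_mds <- cc[keep, keep]
  }
  structure(list(correlation = cc,
                 mds = mds_embedding(cc_mds, d),
                 pca = pca_embedding(lm, d)$coords,
                 explained = pca_embedding(lm, d)$explained,
                 median_correlation = med,
                 flagged_outliers = flagged,
                 size_factors = sf),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("diagnostics report:", ncol(x$correlation), "samples\n")
  cat("  median inter-sample correlation:",
      signif(stats::median(x$median_correlation, na.rm = TRUE), 3), "\n")
  if (length(x$flagged_outliers))
    cat("  flagged outliers:", paste(x$flagged_outliers, collapse = ", "), "\n")
  else cat("  flagged outliers: none\n")
  invisible(x)
}
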