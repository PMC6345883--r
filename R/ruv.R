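#' Estimate unwanted-variation covariates from replicate structure
#'
#' Factor-analytic estimation of systematic artifacts (lane, library prep,
#' sequencing date) in the style of replicate-based removal of unwanted
#' variation: log expression values are centered within each replicate
#' group -- samples that share the same biology, i.e. technical replicates
#' or same subject-and-time samples -- so the residual matrix retains only
#' non-biological variation; its singular value decomposition then yields
#' orthonormal sample-space factors. Alternatively, when a set of
#' negative-control features (believed unaffected by the biology) is given,
#' the factors are estimated from the column-centered control-feature
#' submatrix instead.
#'
#' @param logmat numeric matrix (features x samples), e.g. from
#'   [log_normalized()].
#' @param groups factor/character vector of replicate-group labels, one per
#'   sample (column). Ignored when `control_features` is given.
#' @param k number of factors to estimate (>= 1).
#' @param control_features optional character vector of feature ids to use
#'   as negative controls instead of replicate-group centering.
#' @return list of class `nuisance_factors` with `W` (samples x k,
#'   orthonormal columns, rownames = sample ids), `d` (singular values),
#'   `k`, `grouping` and `degenerate` (TRUE when the residual matrix was
#'   all zero).
#' @export
estimate_unwanted_factors <- function(logmat, groups = NULL, k = 1L,
                                      control_features = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- ncol(logmat)
  if (!is.null(control_features)) {
    miss <- setdiff(control_features, rownames(logmat))
    if (length(miss)) stop("unknown control feature(s): ", paste(miss, collapse = ", "))
    resid <- logmat[control_features, , drop = FALSE]
    resid <- resid - rowMeans(resid)
    grouping <- "controls"
  } else {
    if (is.null(groups)) stop("supply either groups or control_features")
    if (length(groups) != n) stop("groups must have one label per sample")
    g <- factor(groups)
    if (all(tabulate(g) == 1L)) {
      # no replication to cancel the biology: fall back to globally
      # feature-centered data rather than centering each column on itself
      warning("all replicate groups are singletons; biological signal may leak into W")
      resid <- logmat - rowMeans(logmat)
    } else {
      resid <- logmat
      for (lev in levels(g)) {
        idx <- which(g == lev)
        resid[, idx] <- logmat[, idx, drop = FALSE] -
          rowMeans(logmat[, idx, drop = FALSE])
      }
    }
    grouping <- "replicate-groups"
  }
  if (k > min(n, nrow(resid)))
    stop("k exceeds min(samples, features used)")
  degenerate <- all(abs(resid) < 1e-12)
  if (degenerate)
    warning("residual matrix is zero; factors are degenerate")
  sv <- svd(t(resid), nu = k, nv = 0)
  W <- sv$u[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(logmat)
  colnames(W) <- paste0("W", seq_len(k))
  structure(list(W = W, d = sv$d[seq_len(k)], k = k, grouping = grouping,
                 degenerate = degenerate),
            class = "nuisance_factors")
}

#' Remove fitted unwanted variation from a log expression matrix
#'
#' Regresses each feature's log values on the unwanted-variation covariates
#' `W` (ordinary least squares; `W` has orthonormal columns so this is a
#' projection) and subtracts the fitted component. Used for the
#' before/after-correction diagnostic contrast; the AR model itself consumes
#' `W` directly as covariates rather than corrected counts.
#'
#' @param logmat numeric matrix (features x samples).
#' @param W a `nuisance_factors` object or a samples x k matrix with
#'   orthonormal columns.
#' @param k number of factors to use (defaults to all columns of `W`);
#'   `k = 0` returns `logmat` unchanged.
#' @return corrected matrix; each feature row has zero projection onto the
#'   used columns of `W`.
#' @export
corrected_logmat <- function(logmat, W, k = NULL) {
  if (inherits(W, "nuisance_factors")) W <- W$W
  if (is.null(k)) k <- ncol(W)
  if (k == 0L) return(logmat)
  if (k > ncol(W)) stop("k exceeds the number of estimated factors")
  W <- W[, seq_len(k), drop = FALSE]
  if (nrow(W) != ncol(logmat)) stop("W rows do not align with the samples")
  logmat - (logmat %*% W) %*% t(W)
}
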