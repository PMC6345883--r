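#' Simulation configuration for longitudinal count data
#'
#' Describes a meta-framed within-subject longitudinal RNA-seq design: each
#' subject is measured at every time point, each biological sample is split
#' into technical replicates sequenced on different lanes/dates, a
#' multiplicative lane effect acts on one lane, one library may be degraded
#' (the outlier), and a minority of features carry a true temporal effect
#' shared across all post-baseline time points.
#'
#' Baseline means are log-normal with median 50 and `sdlog` 1.5 (spanning
#' roughly three orders of magnitude, as in filtered bulk RNA-seq); the
#' frailty shape 10 gives ~32% biological coefficient of variation; the lane
#' effect is 0.5 on the natural-log scale; library sizes are log-normal with
#' `sdlog` 0.3. The outlier degradation thins counts binomially to 10% and
#' zeroes 30% of features, reproducing a globally low-correlation library.
#'
#' @param n_features number of features.
#' @param n_subjects biological replicates per time point (default 8).
#' @param time_points ordered labels (default D0, D1, D3, D7, D14).
#' @param n_tech_reps technical replicates per biological sample.
#' @param prop_de expected fraction of truly temporal features.
#' @param effect_range range of `|phi|` for temporal features (random sign).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean
#'   distribution.
#' @param frailty_shape gamma frailty shape `a`.
#' @param lane_log_effect lane-effect scale `m`: each feature's natural-log
#'   lane-L2 effect is drawn from `N(m, m^2)`, so `m` sets both the average
#'   depth shift of lane L2 and the feature-to-feature heterogeneity that
#'   makes the lane visible in correlations and embeddings (a uniform
#'   multiplicative lane effect would be indistinguishable from a library
#'   size change). `m = 0` disables the lane effect.
#' @param lane_rule `"techrep"` (replicate r goes to lane r, the paired-lane
#'   design) or `"sample_block"` (first half of biological samples on L1,
#'   second half on L2).
#' @param lane_of optional explicit per-sample lane vector (1 or 2),
#'   overriding `lane_rule`; recycled/validated against the sample count.
#' @param batch_labels labels of the two sequencing dates, indexed by lane.
#' @param libsize_sdlog log-normal sd of per-library size factors.
#' @param outlier_sample column index of the degraded library; `NULL` picks
#'   index 29 when the design has at least 29 samples (else the last
#'   sample); `NA` disables the outlier.
#' @param outlier_thin binomial thinning rate of the outlier's counts.
#' @param outlier_dropout fraction of the outlier's features set to zero.
#' @param time_profile multiplier of `phi` per post-baseline time point
#'   (default all 1, i.e. a sustained effect; pass an increasing ramp for a
#'   monotone signal).
#' @param rng_seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_features = 1000L, n_subjects = 8L,
                       time_points = c("D0", "D1", "D3", "D7", "D14"),
                       n_tech_reps = 2L, prop_de = 0.1,
                       effect_range = c(1, 2),
                       baseline_meanlog = log(50), baseline_sdlog = 1.5,
                       frailty_shape = 10, lane_log_effect = 0.5,
                       lane_rule = c("techrep", "sample_block"),
                       lane_of = NULL,
                       batch_labels = c("2014-10-24", "2015-01-08"),
                       libsize_sdlog = 0.3, outlier_sample = NULL,
                       outlier_thin = 0.1, outlier_dropout = 0.3,
                       time_profile = NULL, rng_seed = 1L) {
  lane_rule <- match.arg(lane_rule)
  if (prop_de < 0 || prop_de > 1) stop("prop_de must lie in [0, 1]")
  if (length(time_points) < 2L) stop("need at least two time points")
  stopifnot(n_features >= 1, n_subjects >= 1, n_tech_reps >= 1,
            frailty_shape > 0, baseline_sdlog >= 0, libsize_sdlog >= 0,
            outlier_thin > 0, outlier_thin <= 1,
            outlier_dropout >= 0, outlier_dropout <= 1,
            all(effect_range > 0), length(effect_range) == 2)
  n_samples <- n_subjects * length(time_points) * n_tech_reps
  if (is.null(outlier_sample))
    outlier_sample <- if (n_samples >= 29L) 29L else n_samples
  if (!is.na(outlier_sample) &&
      (outlier_sample < 1L || outlier_sample > n_samples))
    stop("outlier_sample out of range")
  if (is.null(time_profile)) time_profile <- rep(1, length(time_points) - 1L)
  if (length(time_profile) != length(time_points) - 1L)
    stop("time_profile must have one entry per post-baseline time point")
  structure(list(n_features = as.integer(n_features),
                 n_subjects = as.integer(n_subjects),
                 time_points = time_points,
                 n_tech_reps = as.integer(n_tech_reps),
                 prop_de = prop_de, effect_range = sort(effect_range),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 frailty_shape = frailty_shape,
                 lane_log_effect = lane_log_effect,
                 lane_rule = lane_rule, lane_of = lane_of,
                 batch_labels = batch_labels,
                 libsize_sdlog = libsize_sdlog,
                 outlier_sample = as.integer(outlier_sample),
                 outlier_thin = outlier_thin,
                 outlier_dropout = outlier_dropout,
                 time_profile = time_profile,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate a longitudinal RNA-seq experiment with ground truth
#'
#' The generative core mirrors the fitted model: per feature and subject a
#' gamma frailty `lambda ~ Gamma(a, a/mu)` is shared across all time points
#' (within-subject correlation), and each library's count is Poisson with
#' rate `s * lambda * exp(phi(t) + lane effect)`. On top of that core sit
#' the layers the model does not know about: technical replicates split
#' across lanes, a lane-linked sequencing batch, log-normal library sizes,
#' and one degraded outlier library.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (a [count_matrix]), `samples` (a
#'   [sample_table]), and `truth` (class `sim_truth`: per-feature `de_label`
#'   and `phi` matrix, one column per post-baseline comparison; per-sample
#'   lane, batch, size factor and outlier flag).
#' @export
simulate_longitudinal <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  G <- cfg$n_features; J <- cfg$n_subjects
  tps <- cfg$time_points; Tn <- length(tps); R <- cfg$n_tech_reps
  n_bio <- J * Tn
  n_samples <- n_bio * R

  mu <- stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
  de <- stats::runif(G) < cfg$prop_de
  sgn <- ifelse(stats::runif(G) < 0.5, -1, 1)
  mag <- stats::runif(G, cfg$effect_range[1], cfg$effect_range[2])
  phi <- ifelse(de, sgn * mag, 0)
  phi_mat <- outer(phi, cfg$time_profile)      # features x later time points
  colnames(phi_mat) <- paste0(tps[1], "_vs_", tps[-1])

  a <- cfg$frailty_shape
  lam <- matrix(stats::rgamma(G * J, a, a / mu), G, J)

  # sample layout: biological samples ordered time-major, replicates within
  bio_time <- rep(seq_len(Tn), each = J)
  bio_subj <- rep(seq_len(J), times = Tn)
  time_idx <- rep(bio_time, each = R)
  subj_idx <- rep(bio_subj, each = R)
  bio_idx <- rep(seq_len(n_bio), each = R)
  rep_idx <- rep(seq_len(R), times = n_bio)

  lane <- switch(cfg$lane_rule,
                 techrep = ((rep_idx - 1L) %% 2L) + 1L,
                 sample_block = ifelse(bio_idx <= n_bio / 2, 1L, 2L))
  if (!is.null(cfg$lane_of)) {
    if (length(cfg$lane_of) != n_samples)
      stop("lane_of must have one entry per sample")
    lane <- as.integer(cfg$lane_of)
    if (!all(lane %in% c(1L, 2L))) stop("lane_of entries must be 1 or 2")
  }

  s <- stats::rlnorm(n_samples, 0, cfg$libsize_sdlog)
  sample_id <- sprintf("B%d_L%d_%d", bio_idx, lane, rep_idx)

  m <- cfg$lane_log_effect
  lane_delta <- stats::rnorm(G, m, abs(m))   # per-feature lane-L2 effect

  counts <- matrix(0L, G, n_samples,
                   dimnames = list(sprintf("g%04d", seq_len(G)), sample_id))
  for (col in seq_len(n_samples)) {
    tshift <- if (time_idx[col] == 1L) 0 else phi_mat[, time_idx[col] - 1L]
    rate <- s[col] * lam[, subj_idx[col]] *
      exp(tshift + if (lane[col] == 2L) lane_delta else 0)
    counts[, col] <- stats::rpois(G, rate)
  }

  outlier <- rep(FALSE, n_samples)
  if (!is.na(cfg$outlier_sample)) {
    o <- cfg$outlier_sample
    outlier[o] <- TRUE
    counts[, o] <- stats::rbinom(G, counts[, o], cfg$outlier_thin)
    drop <- sample.int(G, round(cfg$outlier_dropout * G))
    counts[drop, o] <- 0L
  }

  st <- sample_table(data.frame(
    sample_id = sample_id,
    subject_id = sprintf("subj%02d", subj_idx),
    time_point = tps[time_idx],
    lane = paste0("L", lane),
    batch = cfg$batch_labels[lane],
    tech_rep_group = sprintf("B%d", bio_idx),
    excluded = FALSE, stringsAsFactors = FALSE), time_levels = tps)

  truth <- structure(list(
    features = data.frame(feature_id = rownames(counts), de_label = de,
                          mu = mu, lane_delta = lane_delta,
                          stringsAsFactors = FALSE),
    phi = phi_mat,
    samples = data.frame(sample_id = sample_id, lane = paste0("L", lane),
                         batch = cfg$batch_labels[lane], size_factor = s,
                         outlier = outlier, stringsAsFactors = FALSE),
    frailty_shape = a), class = "sim_truth")

  list(counts = count_matrix(counts, "gene"), samples = st, truth = truth)
}

#' Confusion counts against simulation ground truth
#'
#' @param calls logical DE calls: a named logical vector, a vector aligned
#'   to the truth's feature order, or a result data.frame with `feature_id`
#'   and `de_call` columns. `NA` counts as "not called".
#' @param truth a `sim_truth` object (or a logical vector of true labels).
#' @return list with `tp`, `fp`, `fn`, `tn`, `fdr` (`FP / max(FP + TP, 1)`)
#'   and `sensitivity` (`TP / max(TP + FN, 1)`).
#' @export
truth_confusion <- function(calls, truth) {
  if (inherits(truth, "sim_truth")) {
    ids <- truth$features$feature_id
    labels <- truth$features$de_label
  } else {
    ids <- names(truth)
    labels <- as.logical(truth)
  }
  if (is.data.frame(calls)) {
    if (!all(c("feature_id", "de_call") %in% names(calls)))
      stop("calls data.frame needs feature_id and de_call columns")
    idx <- match(ids, calls$feature_id)
    if (anyNA(idx)) stop("calls and truth feature ids do not align")
    calls <- calls$de_call[idx]
  } else if (!is.null(names(calls)) && !is.null(ids)) {
    idx <- match(ids, names(calls))
    if (anyNA(idx)) stop("calls and truth feature ids do not align")
    calls <- calls[idx]
  } else if (length(calls) != length(labels)) {
    stop("calls and truth have different lengths")
  }
  calls <- !is.na(calls) & calls
  tp <- sum(calls & labels); fp <- sum(calls & !labels)
  fn <- sum(!calls & labels); tn <- sum(!calls & !labels)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       fdr = fp / max(fp + tp, 1),
       sensitivity = tp / max(tp + fn, 1))
}
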