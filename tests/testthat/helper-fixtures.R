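# Shared fixture builders for the test suite.

# A count matrix with auto-generated ids when none are supplied.
make_cm <- function(m, features = NULL, samples = NULL, level = "gene") {
  m <- as.matrix(m)
  rownames(m) <- features %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  count_matrix(m, level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pooled paired design: n_subj subjects, one sample per subject at each of
# two time points; sample ids are t0_1..t0_n then t1_1..t1_n.
paired_design <- function(n_subj, t0 = "T0", t1 = "T1") {
  ids <- c(paste0(t0, "_", seq_len(n_subj)), paste0(t1, "_", seq_len(n_subj)))
  st <- sample_table(data.frame(
    sample_id = ids,
    subject_id = rep(paste0("subj", seq_len(n_subj)), 2),
    time_point = rep(c(t0, t1), each = n_subj),
    lane = "L1", batch = "b1", tech_rep_group = ids,
    stringsAsFactors = FALSE), time_levels = c(t0, t1))
  list(ids0 = ids[seq_len(n_subj)], ids1 = ids[n_subj + seq_len(n_subj)],
       ids = ids, st = st)
}

unit_sf <- function(ids) {
  structure(stats::setNames(rep(1, length(ids)), ids),
            method = "unit", class = "size_factors")
}

# Paired count matrix straight from the frailty model (no simulator layers):
# useful when the test needs exact control over mu, phi and a.
frailty_counts <- function(n_feat, n_subj, mu = NULL, phi = 0, a = 10,
                           seed = 1) {
  set.seed(seed)
  # mu = NULL draws a realistic log-normal baseline (median 50)
  mu <- if (is.null(mu)) stats::rlnorm(n_feat, log(50), 1.5) else
    rep_len(mu, n_feat)
  phi <- rep_len(phi, n_feat)
  lam <- matrix(stats::rgamma(n_feat * n_subj, a, a / mu), n_feat)
  y0 <- matrix(stats::rpois(n_feat * n_subj, lam), n_feat)
  y1 <- matrix(stats::rpois(n_feat * n_subj, lam * exp(phi)), n_feat)
  d <- paired_design(n_subj)
  yy <- cbind(y0, y1)
  colnames(yy) <- d$ids
  rownames(yy) <- sprintf("g%04d", seq_len(n_feat))
  list(cm = count_matrix(yy), st = d$st, sf = unit_sf(d$ids),
       mu = mu, phi = phi)
}
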