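#' MCMC configuration for the AR model
#'
#' Defaults follow the method's standard run length: 10,000 iterations with
#' the first 8,000 discarded as burn-in. Random-walk step sizes for the
#' `log mu`, `log a` and `beta` blocks are adapted in windows of
#' `adapt_window` iterations during burn-in only (so detailed balance holds
#' for the retained draws).
#'
#' @param iterations total iterations per feature chain.
#' @param burn_in discarded iterations (< `iterations`).
#' @param rng_seed integer seed; identical inputs and seed give bit-identical
#'   draws.
#' @param adapt_window iterations per adaptation batch.
#' @param step_lmu,step_la,step_beta initial random-walk step sizes.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 10000L, burn_in = 8000L, rng_seed = 1L,
                        adapt_window = 50L, step_lmu = 0.3, step_la = 0.3,
                        step_beta = 0.2) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (burn_in < 0L || burn_in >= iterations)
    stop("burn_in must satisfy 0 <= burn_in < iterations")
  if (any(c(step_lmu, step_la, step_beta) <= 0)) stop("step sizes must be > 0")
  structure(list(iterations = iterations, burn_in = burn_in,
                 rng_seed = as.integer(rng_seed),
                 adapt_window = as.integer(adapt_window),
                 step_lmu = step_lmu, step_la = step_la,
                 step_beta = step_beta),
            class = "mcmc_config")
}

#' Prior specification for the AR model
#'
#' The temporal effect `phi` carries a two-component prior: point mass `pi0`
#' at 0 (no temporal change) and, with probability `1 - pi0`, a
#' `Normal(0, tau^2)` slab. `pi0` encodes that only a minority of features
#' respond to the stimulus; with `pi0 = 0` the prior reduces to the pure
#' Gaussian. Nuisance coefficients are standard normal; `log mu` is normal
#' with sd `mu_sd` centered at each feature's log mean normalized count;
#' `log a` is normal with mean `a_mean` and sd `a_sd`.
#'
#' @param tau slab standard deviation for `phi`.
#' @param pi0 prior mass at `phi = 0`, in `[0, 1)`.
#' @param mu_sd prior sd of `log mu`.
#' @param a_mean,a_sd prior mean and sd of `log a`.
#' @return list of class `ar_prior`.
#' @export
ar_prior <- function(tau = 1, pi0 = 0.9, mu_sd = 2, a_mean = 0, a_sd = 2) {
  if (tau <= 0) stop("tau must be > 0")
  if (pi0 < 0 || pi0 >= 1) stop("pi0 must lie in [0, 1)")
  if (mu_sd <= 0 || a_sd <= 0) stop("prior sds must be > 0")
  structure(list(tau = tau, pi0 = pi0, mu_sd = mu_sd,
                 a_mean = a_mean, a_sd = a_sd),
            class = "ar_prior")
}

# Vectorized Metropolis-within-Gibbs sampler for the pairwise Poisson-gamma
# frailty model, run simultaneously for all features.
#
# Model, per feature i and subject j:
#   lambda_ij ~ Gamma(a_i, a_i / mu_i)                     (shared frailty)
#   y0_ij ~ Poisson(s0_j * lambda_ij * exp(w0_j' beta_i))
#   y1_ij ~ Poisson(s1_j * lambda_ij * exp(phi_i + w1_j' beta_i))
#
# Blocks: lambda by its exact conditional Gamma; phi by independence
# Metropolis from the Gamma-shaped conditional likelihood of exp(phi), with
# reversible spike<->slab swap moves when pi0 > 0; beta, log mu, log a by
# adaptive Gaussian random walks (adaptation during burn-in only).
.ar_mcmc <- function(y0, y1, s0, s1, W0 = NULL, W1 = NULL,
                     prior = ar_prior(), cfg = mcmc_config()) {
  G <- nrow(y0); J <- ncol(y0)
  k <- if (is.null(W0)) 0L else ncol(W0)
  set.seed(cfg$rng_seed)

  tau <- prior$tau; pi0 <- prior$pi0
  pv_mu <- prior$mu_sd^2; pv_a <- prior$a_sd^2
  log_pi0 <- log(pi0); log_1mpi0 <- log1p(-pi0)

  ry0 <- rowSums(y0); ry1 <- rowSums(y1)
  qa <- ry1 + 0.5

  S0mat <- matrix(s0, G, J, byrow = TRUE)
  S1mat <- matrix(s1, G, J, byrow = TRUE)

  # empirical prior center for log mu: log mean depth-normalized count
  mm <- (rowSums(sweep(y0, 2, s0, "/")) + rowSums(sweep(y1, 2, s1, "/"))) / (2 * J)
  m0 <- log(mm + 0.1)

  # deterministic, data-driven initial state
  lmu <- m0
  la <- rep(0, G)
  phi <- log((ry1 / sum(s1) + 0.5)) - log((ry0 / sum(s0) + 0.5))
  phi <- pmin(pmax(phi, -5), 5)
  in_slab <- rep(TRUE, G)
  B <- if (k) matrix(0, G, k) else NULL
  eta0 <- if (k) matrix(0, G, J) else NULL
  eta1 <- if (k) matrix(0, G, J) else NULL
  lam <- (y0 + y1 + 0.5) / (S0mat + S1mat)

  ls_lmu <- rep(log(cfg$step_lmu), G)
  ls_la <- rep(log(cfg$step_la), G)
  ls_b <- rep(log(cfg$step_beta), G)

  ndraw <- cfg$iterations - cfg$burn_in
  draws <- matrix(NA_real_, ndraw, G)
  acc_phi <- acc_lmu <- acc_la <- acc_b <- numeric(G)
  w_phi <- w_lmu <- w_la <- w_b <- numeric(G)   # adaptation-window counters
  batch <- 0L

  ldnorm <- function(x, sd) -0.5 * (x / sd)^2 - log(sd) - 0.9189385332046727

  for (it in seq_len(cfg$iterations)) {
    a <- exp(la)
    ephi <- exp(phi)
    C0 <- if (k) exp(eta0) * S0mat else S0mat
    C1 <- if (k) exp(eta1) * S1mat else S1mat

    ## lambda | rest : exact conditional Gamma
    shape <- a + y0 + y1
    rate <- exp(la - lmu) + C0 + ephi * C1
    lam <- matrix(stats::rgamma(G * J, shape, rate), G, J)
    Sl <- rowSums(lam)
    Sll <- rowSums(log(lam))
    S1l <- rowSums(C1 * lam)

    ## phi | rest : independence Metropolis from Gamma(qa, S1l) on exp(phi),
    ## plus spike<->slab reversible swaps when pi0 > 0.
    phip <- log(stats::rgamma(G, qa, S1l))
    lnp <- ldnorm(phip, tau)
    u_phi <- log(stats::runif(G))
    gshift <- qa * log(S1l) - lgamma(qa)      # log q(phi) - log L(phi) offset
    gstar <- phip * (ry1 - qa) - gshift       # log L(phi*) - log q(phi*)
    if (pi0 > 0) {
      swap <- stats::runif(G) < 0.5
      gcur <- phi * (ry1 - qa) - gshift
      lncur <- ldnorm(phi, tau)
      la_refresh <- gstar + lnp - gcur - lncur
      la_out <- log_pi0 - log_1mpi0 - S1l - lncur - gcur
      la_in <- log_1mpi0 - log_pi0 + gstar + lnp + S1l
      logacc <- ifelse(swap, ifelse(in_slab, la_out, la_in),
                       ifelse(in_slab, la_refresh, -Inf))
      acc <- u_phi < logacc
      newslab <- ifelse(acc, ifelse(swap, !in_slab, TRUE), in_slab)
      phi <- ifelse(acc, ifelse(swap & in_slab, 0, phip), phi)
      phi[!newslab] <- 0
      in_slab <- newslab
    } else {
      gcur <- phi * (ry1 - qa) - gshift
      acc <- u_phi < (gstar + lnp - gcur - ldnorm(phi, tau))
      phi[acc] <- phip[acc]
    }
    w_phi <- w_phi + acc
    if (it > cfg$burn_in) acc_phi <- acc_phi + acc

    ## beta | rest : joint Gaussian random walk per feature
    if (k) {
      step_b <- exp(ls_b)
      Bp <- B + matrix(stats::rnorm(G * k), G, k) * step_b
      eta0p <- Bp %*% t(W0); eta1p <- Bp %*% t(W1)
      C0p <- exp(eta0p) * S0mat; C1p <- exp(eta1p) * S1mat
      ephi <- exp(phi)
      dll <- rowSums(y0 * (eta0p - eta0) + y1 * (eta1p - eta1)) -
        rowSums(lam * (C0p - C0)) - ephi * rowSums(lam * (C1p - C1)) -
        0.5 * (rowSums(Bp^2) - rowSums(B^2))
      acc <- log(stats::runif(G)) < dll
      if (any(acc)) {
        B[acc, ] <- Bp[acc, ]
        eta0[acc, ] <- eta0p[acc, ]; eta1[acc, ] <- eta1p[acc, ]
        C1 <- exp(eta1) * S1mat
        S1l <- rowSums(C1 * lam)
      }
      w_b <- w_b + acc
      if (it > cfg$burn_in) acc_b <- acc_b + acc
    }

    ## log mu | lambda, a : Gaussian random walk
    a <- exp(la)
    lmup <- lmu + stats::rnorm(G) * exp(ls_lmu)
    dll <- -J * a * (lmup - lmu) - a * Sl * (exp(-lmup) - exp(-lmu)) -
      ((lmup - m0)^2 - (lmu - m0)^2) / (2 * pv_mu)
    acc <- log(stats::runif(G)) < dll
    lmu[acc] <- lmup[acc]
    w_lmu <- w_lmu + acc
    if (it > cfg$burn_in) acc_lmu <- acc_lmu + acc

    ## log a | lambda, mu : Gaussian random walk
    lap <- la + stats::rnorm(G) * exp(ls_la)
    ap <- exp(lap); a <- exp(la); emu <- exp(-lmu)
    h <- function(aa, laa) J * (aa * (laa - lmu) - lgamma(aa)) +
      (aa - 1) * Sll - aa * emu * Sl
    dll <- h(ap, lap) - h(a, la) -
      ((lap - prior$a_mean)^2 - (la - prior$a_mean)^2) / (2 * pv_a)
    acc <- log(stats::runif(G)) < dll
    la[acc] <- lap[acc]
    w_la <- w_la + acc
    if (it > cfg$burn_in) acc_la <- acc_la + acc

    ## step-size adaptation, burn-in only
    if (it <= cfg$burn_in && it %% cfg$adapt_window == 0L) {
      batch <- batch + 1L
      delta <- min(0.25, 1 / sqrt(batch))
      ls_lmu <- pmin(pmax(ls_lmu + delta * sign(w_lmu / cfg$adapt_window - 0.44), -7), 2)
      ls_la <- pmin(pmax(ls_la + delta * sign(w_la / cfg$adapt_window - 0.44), -7), 2)
      if (k) ls_b <- pmin(pmax(ls_b + delta * sign(w_b / cfg$adapt_window - 0.3), -7), 2)
      w_lmu[] <- 0; w_la[] <- 0; w_b[] <- 0; w_phi[] <- 0
    }

    if (it > cfg$burn_in) draws[it - cfg$burn_in, ] <- phi
  }

  list(draws = draws,
       acceptance = list(phi = acc_phi / ndraw,
                         lmu = acc_lmu / ndraw,
                         la = acc_la / ndraw,
                         beta = if (k) acc_b / ndraw else NULL))
}

# Effective sample size from a lag-1 autoregressive approximation of the
# chain autocorrelation; adequate for Monte Carlo standard errors here
# because the phi sampler is a near-independence Metropolis step.
.ess_ar1 <- function(draws) {
  n <- nrow(draws)
  apply(draws, 2, function(x) {
    v <- stats::var(x)
    if (!is.finite(v) || v == 0) return(n)
    r1 <- stats::cor(x[-1], x[-n])
    if (!is.finite(r1)) return(n)
    r1 <- min(max(r1, 0), 0.999)
    max(1, n * (1 - r1) / (1 + r1))
  })
}

#' Tail probabilities of the temporal parameter
#'
#' Fractions of posterior draws of `phi` strictly above and strictly below
#' zero. With a spike-and-slab prior some draws are exactly 0, so the two
#' tails may sum to less than 1; the remainder is the posterior mass at 0.
#'
#' @param phi_draws numeric vector of posterior draws (or a draws x features
#'   matrix, in which case a features x 2 matrix is returned).
#' @return named numeric `c(tail_pos, tail_neg)` (or matrix).
#' @export
tail_probability <- function(phi_draws) {
  if (is.matrix(phi_draws)) {
    out <- cbind(tail_pos = colMeans(phi_draws > 0),
                 tail_neg = colMeans(phi_draws < 0))
    rownames(out) <- colnames(phi_draws)
    return(out)
  }
  if (!length(phi_draws)) stop("need at least one draw")
  c(tail_pos = mean(phi_draws > 0), tail_neg = mean(phi_draws < 0))
}

#' Call temporally differential expression from tail probabilities
#'
#' A feature is called differentially expressed when at least `1 - cutoff`
#' of its posterior mass for `phi` lies strictly on one side of zero, i.e.
#' `max(tail_pos, tail_neg) >= 1 - cutoff`. For a continuous posterior this
#' is exactly `min(tail_pos, tail_neg) <= cutoff`; under spike mass at 0 it
#' is the form that still demands dominant one-sided evidence. Lowering the
#' cutoff never adds a call.
#'
#' @param result an `ar_fit` object or its `results` data.frame.
#' @param cutoff tail-probability cutoff in (0, 0.5), default 0.1.
#' @return logical vector, one call per feature (`NA` for untested
#'   features).
#' @export
call_de <- function(result, cutoff = 0.1) {
  if (!(cutoff > 0 && cutoff < 0.5)) stop("cutoff must lie in (0, 0.5)")
  res <- if (inherits(result, "ar_fit")) result$results else result
  pmax(res$tail_pos, res$tail_neg) >= 1 - cutoff
}

#' Fit the pairwise Bayesian AR model for one time-point comparison
#'
#' For each feature, fits the Poisson-gamma frailty model comparing the
#' baseline time point `t0` against a later time point `t1`: each subject's
#' gamma frailty is shared between its two samples (inducing the
#' within-subject dependence and negative-binomial marginals) and the
#' log-scale temporal effect `phi` is inferred by MCMC, with optional
#' unwanted-variation covariates `W` entering on the log-rate scale.
#' Differential expression is called from the posterior tail probabilities
#' of `phi`.
#'
#' Subjects missing a pooled sample at either time point are dropped with a
#' warning; features with all-zero counts in both groups are skipped and
#' reported as not testable (all-`NA` row, `convergence_flag = FALSE`).
#'
#' @param cm pooled [count_matrix] (one column per biological sample).
#' @param st [sample_table] for its columns.
#' @param t0,t1 baseline and compared time-point labels.
#' @param W optional `nuisance_factors` (or samples x k matrix with sample
#'   ids as rownames) from [estimate_unwanted_factors()].
#' @param sf optional [size_factors]; computed from `cm` when omitted
#'   (falling back to unit factors, with a warning, if no feature is
#'   positive in all samples).
#' @param cfg an [mcmc_config()].
#' @param prior an [ar_prior()].
#' @param tail_cutoff cutoff for the differential expression calls.
#' @return list of class `ar_fit` with `results` (one row per feature:
#'   posterior mean/sd/95% credible interval of `phi`, tail probabilities,
#'   mass at 0, call, direction, convergence flag), `phi_draws`
#'   (post-burn-in draws, one column per tested feature), `ess`,
#'   `acceptance`, `subjects`, and the configuration used.
#' @export
fit_pairwise_ar <- function(cm, st, t0, t1, W = NULL, sf = NULL,
                            cfg = mcmc_config(), prior = ar_prior(),
                            tail_cutoff = 0.1) {
  if (!all(colnames(cm) %in% st$sample_id))
    stop("sample(s) missing from the sample table: ",
         paste(setdiff(colnames(cm), st$sample_id), collapse = ", "))
  st <- st[match(colnames(cm), st$sample_id), , drop = FALSE]
  st <- st[!st$excluded, , drop = FALSE]
  for (tp in c(t0, t1)) if (!tp %in% levels(st$time_point))
    stop("unknown time point: ", tp)

  pick <- function(tp) st[st$time_point == tp, c("sample_id", "subject_id")]
  a0 <- pick(t0); a1 <- pick(t1)
  if (anyDuplicated(a0$subject_id) || anyDuplicated(a1$subject_id))
    stop("a subject has multiple samples at one time point; pool technical replicates first")
  subjects <- intersect(a0$subject_id, a1$subject_id)
  dropped <- setdiff(union(a0$subject_id, a1$subject_id), subjects)
  if (length(dropped))
    warning("subject(s) missing a time point dropped: ", paste(dropped, collapse = ", "))
  if (length(subjects) < 2L) stop("need at least 2 subjects with both time points")
  ids0 <- a0$sample_id[match(subjects, a0$subject_id)]
  ids1 <- a1$sample_id[match(subjects, a1$subject_id)]

  if (is.null(sf)) {
    sf <- tryCatch(size_factors(cm), error = function(e) {
      warning("size factors unavailable (", conditionMessage(e),
              "); using unit factors")
      structure(stats::setNames(rep(1, ncol(cm)), colnames(cm)),
                method = "unit", class = "size_factors")
    })
  }
  if (is.null(names(sf))) stop("size factors must be named by sample id")
  s0 <- as.numeric(sf[ids0]); s1 <- as.numeric(sf[ids1])
  if (anyNA(s0) || anyNA(s1)) stop("size factors missing for some samples")

  W0 <- W1 <- NULL
  if (!is.null(W)) {
    Wm <- if (inherits(W, "nuisance_factors")) W$W else W
    if (is.null(rownames(Wm)) || !all(c(ids0, ids1) %in% rownames(Wm)))
      stop("W is not aligned to the retained samples (missing sample ids)")
    W0 <- Wm[ids0, , drop = FALSE]; W1 <- Wm[ids1, , drop = FALSE]
  }

  y0 <- unclass(cm)[, ids0, drop = FALSE]; storage.mode(y0) <- "double"
  y1 <- unclass(cm)[, ids1, drop = FALSE]; storage.mode(y1) <- "double"
  tested <- rowSums(y0) + rowSums(y1) > 0
  label <- paste0(t0, "_vs_", t1)
  G_all <- nrow(cm)

  res <- data.frame(feature_id = rownames(cm), comparison_label = label,
                    phi_mean = NA_real_, phi_sd = NA_real_,
                    phi_ci_low = NA_real_, phi_ci_high = NA_real_,
                    tail_pos = NA_real_, tail_neg = NA_real_,
                    null_mass = NA_real_, de_call = NA,
                    direction = NA_real_, convergence_flag = FALSE,
                    stringsAsFactors = FALSE)
  draws <- NULL; ess <- rep(NA_real_, G_all); acceptance <- NULL

  if (any(tested)) {
    mc <- .ar_mcmc(y0[tested, , drop = FALSE], y1[tested, , drop = FALSE],
                   s0, s1, W0, W1, prior = prior, cfg = cfg)
    draws <- mc$draws
    colnames(draws) <- rownames(cm)[tested]
    acceptance <- mc$acceptance
    tp <- tail_probability(draws)
    ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    ess_t <- .ess_ar1(draws)
    res$phi_mean[tested] <- colMeans(draws)
    res$phi_sd[tested] <- apply(draws, 2, stats::sd)
    res$phi_ci_low[tested] <- ci[1, ]
    res$phi_ci_high[tested] <- ci[2, ]
    res$tail_pos[tested] <- tp[, "tail_pos"]
    res$tail_neg[tested] <- tp[, "tail_neg"]
    res$null_mass[tested] <- 1 - tp[, "tail_pos"] - tp[, "tail_neg"]
    res$convergence_flag[tested] <- ess_t >= 100
    ess[tested] <- ess_t
  }
  res$de_call <- call_de(res, tail_cutoff)
  res$de_call[!tested] <- NA
  res$direction <- sign(res$phi_mean)

  structure(list(results = res, phi_draws = draws, ess = ess,
                 acceptance = acceptance, comparison_label = label,
                 subjects = subjects,
                 samples = list(t0 = ids0, t1 = ids1),
                 cfg = cfg, prior = prior, tail_cutoff = tail_cutoff),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  r <- x$results
  cat("Bayesian AR fit", x$comparison_label, "--",
      nrow(r), "features,", length(x$subjects), "subjects\n")
  cat("  tested:", sum(!is.na(r$tail_pos)),
      " called DE:", sum(r$de_call, na.rm = TRUE),
      " (tail cutoff", x$tail_cutoff, ")\n")
  invisible(x)
}

#' Fit the full baseline-versus-later-times series
#'
#' Runs [fit_pairwise_ar()] for the baseline time point against each later
#' time point in order. Comparison `t` uses seed `rng_seed + (t_index - 1)`,
#' so each element is bit-identical to the standalone pairwise fit with the
#' matching seed.
#'
#' @inheritParams fit_pairwise_ar
#' @param baseline baseline time-point label; defaults to the first level.
#' @return named list of `ar_fit` objects, one per comparison.
#' @export
fit_series_ar <- function(cm, st, baseline = NULL, W = NULL, sf = NULL,
                          cfg = mcmc_config(), prior = ar_prior(),
                          tail_cutoff = 0.1) {
  lev <- levels(st$time_point)
  lev <- lev[lev %in% unique(as.character(st$time_point))]
  if (is.null(baseline)) baseline <- lev[1]
  later <- setdiff(lev, baseline)
  if (length(later) < 1L) stop("no later time points to compare")
  fits <- lapply(seq_along(later), function(i) {
    cfg_i <- cfg
    cfg_i$rng_seed <- cfg$rng_seed + (i - 1L)
    fit_pairwise_ar(cm, st, baseline, later[i], W = W, sf = sf,
                    cfg = cfg_i, prior = prior, tail_cutoff = tail_cutoff)
  })
  names(fits) <- paste0(baseline, "_vs_", later)
  fits
}
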