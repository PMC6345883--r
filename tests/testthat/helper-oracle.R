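# Independent numerical oracles used by the tests. These share no code with
# the package: the posterior oracle integrates the single-feature model on a
# dense grid (with the subject frailties integrated out analytically), and
# the Fisher oracle enumerates the hypergeometric support via lchoose.

# Dense-grid posterior for one feature of the pairwise model. lambda_j is
# integrated analytically: its Gamma(a, a/mu) prior is conjugate to the two
# Poisson factors, leaving the negative-binomial-type marginal
#   p(y0j, y1j | phi, mu, a) = c0^y0j c1^y1j / (y0j! y1j!) *
#     (a/mu)^a / Gamma(a) * Gamma(a + y0j + y1j) / (a/mu + c0 + c1)^(a+y0j+y1j)
# with c0 = s0j, c1 = s1j e^phi. (phi, log mu, log a) are then integrated on
# a grid against their priors, with the spike at phi = 0 handled as a
# separate plane.
grid_oracle <- function(y0, y1, s0, s1, prior = ar_prior(),
                        n_phi = 241, n_lmu = 101, n_la = 101, span = 6) {
  J <- length(y0)
  mm <- mean(c(y0 / s0, y1 / s1))
  m0 <- log(mm + 0.1)
  phi_g <- seq(-span, span, length.out = n_phi)
  lmu_g <- seq(m0 - span, m0 + span, length.out = n_lmu)
  la_g <- seq(prior$a_mean - span, prior$a_mean + span, length.out = n_la)

  A <- exp(la_g)                       # a over the log-a grid
  AE <- outer(exp(-lmu_g), A)          # a * exp(-lmu), n_lmu x n_la
  lamu <- outer(-lmu_g, la_g, "+")     # la - lmu
  lgA <- matrix(lgamma(A), n_lmu, n_la, byrow = TRUE)
  pr <- outer(stats::dnorm(lmu_g, m0, prior$mu_sd, log = TRUE),
              stats::dnorm(la_g, prior$a_mean, prior$a_sd, log = TRUE), "+")
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

  # log integral over (log mu, log a) of likelihood x priors, fixed phi
  inner <- function(phi) {
    c1 <- s1 * exp(phi)
    ll <- matrix(0, n_lmu, n_la)
    for (j in seq_len(J)) {
      nj <- y0[j] + y1[j]
      ll <- ll + y0[j] * log(s0[j]) + y1[j] * log(c1[j]) -
        lgamma(y0[j] + 1) - lgamma(y1[j] + 1) +
        sweep(lamu, 2, A, "*") - lgA +
        matrix(lgamma(A + nj), n_lmu, n_la, byrow = TRUE) -
        sweep(log(AE + s0[j] + c1[j]), 2, A + nj, "*")
    }
    lse(ll + pr) + log(diff(lmu_g)[1]) + log(diff(la_g)[1])
  }

  linner <- vapply(phi_g, inner, numeric(1))
  lslab <- linner + stats::dnorm(phi_g, 0, prior$tau, log = TRUE)
  lM_slab <- lse(lslab) + log(diff(phi_g)[1])

  if (prior$pi0 > 0) {
    lw_null <- log(prior$pi0) + inner(0)
    lw_slab <- log(1 - prior$pi0) + lM_slab
    ldenom <- lse(c(lw_null, lw_slab))
    post_null <- exp(lw_null - ldenom)
  } else {
    lw_slab <- lM_slab
    ldenom <- lM_slab
    post_null <- 0
  }
  wslab <- exp(lslab - lse(lslab))        # normalized slab density on grid
  slab_share <- exp(lw_slab - ldenom)
  # the grid point at phi = 0 carries ~density(0)*dphi of slab mass that a
  # continuous draw would split evenly between the tails
  at0 <- sum(wslab[phi_g == 0])
  list(post_null = post_null,
       phi_mean = slab_share * sum(wslab * phi_g),
       tail_pos = slab_share * (sum(wslab[phi_g > 0]) + at0 / 2),
       tail_neg = slab_share * (sum(wslab[phi_g < 0]) + at0 / 2))
}

# Two-sided Fisher exact p by explicit enumeration of the hypergeometric
# support with lchoose (no dhyper), summing masses <= the observed one with
# the conventional (1 + 1e-7) tie slack.
fisher_enum <- function(x0, x1, N0, N1) {
  m <- x0 + x1
  if (m == 0) return(1)
  xs <- max(0, m - N1):min(m, N0)
  p <- exp(lchoose(N0, xs) + lchoose(N1, m - xs) - lchoose(N0 + N1, m))
  sum(p[p <= p[xs == x0] * (1 + 1e-7)])
}

# Batch-means Monte Carlo standard error of the mean of a draw sequence
# (robust to autocorrelation, unlike the naive sd/sqrt(n)).
batch_se <- function(x, n_batches = 50) {
  b <- floor(length(x) / n_batches)
  m <- colMeans(matrix(x[seq_len(n_batches * b)], b))
  stats::sd(m) / sqrt(n_batches)
}

# Vectorized variant: two-sided p for every x0 in the support of the margins
# (N0, N1, m) at once, via sorted cumulative sums.
fisher_enum_all <- function(N0, N1, m) {
  if (m == 0) return(1)
  xs <- max(0, m - N1):min(m, N0)
  p <- exp(lchoose(N0, xs) + lchoose(N1, m - xs) - lchoose(N0 + N1, m))
  o <- order(p)
  cs <- cumsum(p[o])
  idx <- findInterval(p * (1 + 1e-7), p[o])
  stats::setNames(cs[idx], xs)
}
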