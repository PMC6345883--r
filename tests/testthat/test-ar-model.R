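test_that("tail_probability counts draw signs", {
  expect_equal(tail_probability(c(0.2, 1, 3)),
               c(tail_pos = 1, tail_neg = 0))
  expect_equal(tail_probability(c(rep(-1, 3), rep(1, 7))),
               c(tail_pos = 0.7, tail_neg = 0.3))
  expect_equal(tail_probability(c(-2, -1, 1, 2)),
               c(tail_pos = 0.5, tail_neg = 0.5))
  # exact zeros (spike draws) belong to neither tail
  expect_equal(unname(sum(tail_probability(c(-1, 0, 0, 1)))), 0.5)
  m <- cbind(f1 = c(-1, 1), f2 = c(1, 1))
  expect_equal(tail_probability(m),
               rbind(f1 = c(tail_pos = 0.5, tail_neg = 0.5),
                     f2 = c(tail_pos = 1, tail_neg = 0)))
  expect_error(tail_probability(numeric(0)), "at least one")
})

test_that("call_de demands dominant one-sided posterior mass", {
  res <- data.frame(tail_pos = c(0.98, 0.5, 0.05, 0.89),
                    tail_neg = c(0.02, 0.5, 0.95, 0.02))
  expect_identical(call_de(res, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(call_de(res, 0.49), c(TRUE, FALSE, TRUE, TRUE))
  # lowering the cutoff never adds a call
  cuts <- seq(0.45, 0.01, by = -0.04)
  calls <- vapply(cuts, function(ct) call_de(res, ct), logical(4))
  for (i in seq_along(cuts)[-1])
    expect_true(all(calls[, i] <= calls[, i - 1]))
  expect_error(call_de(res, 0.6), "cutoff")
})

test_that("identical inputs and seed give bit-identical draws", {
  fx <- frailty_counts(30, 4, mu = 50, phi = rep(c(0, 1), 15), seed = 9)
  cfg <- mcmc_config(iterations = 500, burn_in = 200, rng_seed = 5)
  f1 <- fit_pairwise_ar(fx$cm, fx$st, "T0", "T1", sf = fx$sf, cfg = cfg)
  f2 <- fit_pairwise_ar(fx$cm, fx$st, "T0", "T1", sf = fx$sf, cfg = cfg)
  expect_identical(f1$phi_draws, f2$phi_draws)
  expect_identical(f1$results, f2$results)
  # a different seed gives different draws
  cfg2 <- mcmc_config(iterations = 500, burn_in = 200, rng_seed = 6)
  f3 <- fit_pairwise_ar(fx$cm, fx$st, "T0", "T1", sf = fx$sf, cfg = cfg2)
  expect_false(identical(f1$phi_draws, f3$phi_draws))
})

test_that("the fit object satisfies the result-table invariants", {
  fx <- frailty_counts(40, 4, mu = 30, phi = rep(c(0, 0, 0, 2), 10), seed = 14)
  fit <- fit_pairwise_ar(fx$cm, fx$st, "T0", "T1", sf = fx$sf,
                         cfg = mcmc_config(iterations = 1500, burn_in = 500))
  r <- fit$results
  expect_true(all(r$tail_pos >= 0 & r$tail_pos <= 1))
  expect_true(all(r$tail_neg >= 0 & r$tail_neg <= 1))
  expect_true(all(r$tail_pos + r$tail_neg <= 1 + 1e-12))
  expect_equal(r$tail_pos + r$tail_neg + r$null_mass, rep(1, 40))
  expect_identical(nrow(fit$phi_draws), 1000L)
  expect_true(all(unlist(fit$acceptance) >= 0 & unlist(fit$acceptance) <= 1))
  expect_true(all(r$phi_ci_low <= r$phi_ci_high))
  expect_identical(r$direction, sign(r$phi_mean))
  expect_output(print(fit), "T0_vs_T1")
})

test_that("all-zero features are skipped and reported untestable", {
  fx <- frailty_counts(5, 3, mu = 40, phi = 0, seed = 6)
  m <- unclass(fx$cm)
  m[2, ] <- 0L
  cm <- count_matrix(m)
  fit <- fit_pairwise_ar(cm, fx$st, "T0", "T1", sf = fx$sf,
                         cfg = mcmc_config(iterations = 300, burn_in = 100))
  r <- fit$results
  expect_true(is.na(r$de_call[2]))
  expect_true(is.na(r$phi_mean[2]))
  expect_false(r$convergence_flag[2])
  expect_false(anyNA(r$phi_mean[-2]))
  expect_false("g0002" %in% colnames(fit$phi_draws))
})

test_that("subjects missing a time point are dropped with a warning", {
  fx <- frailty_counts(8, 4, mu = 50, phi = 0, seed = 7)
  cm <- count_matrix(unclass(fx$cm)[, -1])   # drop subj1's T0 sample
  expect_warning(
    fit <- fit_pairwise_ar(cm, fx$st, "T0", "T1", sf = fx$sf,
                           cfg = mcmc_config(iterations = 300, burn_in = 100)),
    "subj1")
  expect_length(fit$subjects, 3L)
})

test_that("unpooled duplicates and misaligned W are rejected", {
  d <- paired_design(2)
  st_dup <- d$st
  st_dup$subject_id[2] <- "subj1"   # two T0 samples for subj1
  cm <- make_cm(matrix(5L, 3, 4), samples = d$ids)
  expect_error(fit_pairwise_ar(cm, st_dup, "T0", "T1", sf = unit_sf(d$ids)),
               "pool technical replicates")
  W_bad <- matrix(rnorm(4), 4, 1, dimnames = list(paste0("x", 1:4), "W1"))
  expect_error(fit_pairwise_ar(cm, d$st, "T0", "T1", sf = unit_sf(d$ids),
                               W = W_bad, cfg = mcmc_config(iterations = 200,
                                                            burn_in = 50)),
               "not aligned")
  expect_error(fit_pairwise_ar(cm, d$st, "T0", "D9", sf = unit_sf(d$ids)),
               "unknown time point")
})

test_that("MCMC matches the grid-integration oracle (spike-and-slab)", {
  y0 <- c(5, 9); y1 <- c(14, 20); s0 <- c(1, 1.2); s1 <- c(0.9, 1.1)
  ids <- c("a0", "b0", "a1", "b1")
  cm <- count_matrix(matrix(as.integer(c(y0, y1)), 1, 4,
                            dimnames = list("g1", ids)))
  st <- sample_table(data.frame(sample_id = ids,
                                subject_id = c("s1", "s2", "s1", "s2"),
                                time_point = c("T0", "T0", "T1", "T1"),
                                lane = "L1", batch = "b",
                                tech_rep_group = ids))
  sf <- structure(stats::setNames(c(s0, s1), ids), class = "size_factors")
  or <- grid_oracle(y0, y1, s0, s1)
  fit <- fit_pairwise_ar(cm, st, "T0", "T1", sf = sf,
                         cfg = mcmc_config(iterations = 30000,
                                           burn_in = 6000, rng_seed = 7))
  r <- fit$results
  d <- fit$phi_draws[, 1]
  expect_lt(abs(r$phi_mean - or$phi_mean), 3 * batch_se(d) + 1e-4)
  expect_lt(abs(r$tail_pos - or$tail_pos), 3 * batch_se(d > 0) + 1e-4)
  expect_lt(abs(r$null_mass - or$post_null), 3 * batch_se(d == 0) + 1e-4)
})

test_that("MCMC matches the grid-integration oracle (pure normal prior)", {
  y0 <- c(7, 2, 11); y1 <- c(4, 1, 6); s0 <- c(1, 1, 1); s1 <- c(1.3, 0.8, 1)
  ids <- c("a0", "b0", "c0", "a1", "b1", "c1")
  cm <- count_matrix(matrix(as.integer(c(y0, y1)), 1, 6,
                            dimnames = list("g1", ids)))
  st <- sample_table(data.frame(sample_id = ids,
                                subject_id = rep(c("s1", "s2", "s3"), 2),
                                time_point = rep(c("T0", "T1"), each = 3),
                                lane = "L1", batch = "b",
                                tech_rep_group = ids))
  sf <- structure(stats::setNames(c(s0, s1), ids), class = "size_factors")
  pr <- ar_prior(pi0 = 0)
  or <- grid_oracle(y0, y1, s0, s1, prior = pr)
  fit <- fit_pairwise_ar(cm, st, "T0", "T1", sf = sf, prior = pr,
                         cfg = mcmc_config(iterations = 30000,
                                           burn_in = 6000, rng_seed = 11))
  r <- fit$results
  d <- fit$phi_draws[, 1]
  expect_lt(abs(r$phi_mean - or$phi_mean), 3 * batch_se(d) + 1e-4)
  expect_lt(abs(r$tail_pos - or$tail_pos), 3 * batch_se(d > 0) + 1e-4)
  expect_equal(r$null_mass, 0)   # continuous prior: no mass at exactly 0
})

test_that("null features are rarely called; strong effects always are", {
  # 200 null features
  fx <- frailty_counts(200, 8, mu = 50, phi = 0, seed = 41)
  fit <- fit_pairwise_ar(fx$cm, fx$st, "T0", "T1", sf = fx$sf,
                         cfg = mcmc_config(rng_seed = 2))
  false_rate <- mean(fit$results$de_call, na.rm = TRUE)
  expect_lte(false_rate, 0.05)

  # phi = 2 at mu = 100: called positive with a negligible opposite tail
  fx2 <- frailty_counts(20, 8, mu = 100, phi = 2, seed = 42)
  fit2 <- fit_pairwise_ar(fx2$cm, fx2$st, "T0", "T1", sf = fx2$sf,
                          cfg = mcmc_config(rng_seed = 3))
  expect_true(all(fit2$results$de_call))
  expect_true(all(fit2$results$tail_neg < 0.001))
  expect_true(all(fit2$results$direction == 1))
})

test_that("posterior concentrates on the truth with much data", {
  # phi = 1, mu = 1000, 16 subjects: 95% CI covers 1 for nearly all features
  fx <- frailty_counts(10, 16, mu = 1000, phi = 1, seed = 43)
  fit <- fit_pairwise_ar(fx$cm, fx$st, "T0", "T1", sf = fx$sf,
                         cfg = mcmc_config(iterations = 4000, burn_in = 2000,
                                           rng_seed = 4))
  r <- fit$results
  covered <- r$phi_ci_low <= 1 & r$phi_ci_high >= 1
  expect_gte(sum(covered), 8)
  expect_lt(max(abs(r$phi_mean - 1)), 0.25)
})

test_that("a lane effect supplied as W is absorbed; omitted, it corrupts", {
  G <- 300
  lane_of <- c(rep(1L, 8), rep(1L, 4), rep(2L, 4))  # L2 hits T1 of subj 5-8
  mk <- function(lane_eff) simulate_longitudinal(sim_config(
    n_features = G, n_subjects = 8, time_points = c("D0", "D7"),
    n_tech_reps = 1, prop_de = 0, lane_log_effect = lane_eff,
    lane_of = lane_of, outlier_sample = NA, rng_seed = 21))
  rate <- function(sim, W) {
    pooled <- pool_technical_replicates(sim$counts, sim$samples)
    fit <- fit_pairwise_ar(pooled$counts, pooled$samples, "D0", "D7", W = W,
                           sf = size_factors(pooled$counts),
                           cfg = mcmc_config(rng_seed = 2))
    mean(fit$results$de_call, na.rm = TRUE)
  }
  sim_clean <- mk(0); sim_lane <- mk(0.5)
  pooled <- pool_technical_replicates(sim_lane$counts, sim_lane$samples)
  lane <- as.numeric(pooled$samples$lane == "L2")
  v <- (lane - mean(lane)) / sqrt(sum((lane - mean(lane))^2))
  Wm <- matrix(v, dimnames = list(pooled$samples$sample_id, "W1"))

  p_clean <- rate(sim_clean, NULL)
  p_omitted <- rate(sim_lane, NULL)
  p_given <- rate(sim_lane, Wm)
  se <- sqrt(max(p_clean, 1 / G) * (1 - max(p_clean, 1 / G)) / G)
  expect_lte(p_given, p_clean + 2 * se + 2 / G)  # W restores calibration
  expect_gt(p_omitted, p_given + 0.05)           # omitting W inflates calls
})

test_that("fit_series_ar reproduces the standalone pairwise fits", {
  sim <- simulate_longitudinal(sim_config(n_features = 40, n_subjects = 4,
                                          time_points = c("D0", "D1", "D3"),
                                          n_tech_reps = 1, outlier_sample = NA,
                                          rng_seed = 9))
  pooled <- pool_technical_replicates(sim$counts, sim$samples)
  cfg <- mcmc_config(iterations = 500, burn_in = 200, rng_seed = 5)
  fits <- fit_series_ar(pooled$counts, pooled$samples, cfg = cfg)
  expect_named(fits, c("D0_vs_D1", "D0_vs_D3"))

  f1 <- fit_pairwise_ar(pooled$counts, pooled$samples, "D0", "D1", cfg = cfg)
  cfg2 <- cfg; cfg2$rng_seed <- 6L
  f2 <- fit_pairwise_ar(pooled$counts, pooled$samples, "D0", "D3", cfg = cfg2)
  expect_identical(fits[["D0_vs_D1"]]$phi_draws, f1$phi_draws)
  expect_identical(fits[["D0_vs_D3"]]$phi_draws, f2$phi_draws)
})

test_that("a monotone signal is detected increasingly often over time", {
  sim <- simulate_longitudinal(sim_config(
    n_features = 150, n_subjects = 8, time_points = c("D0", "D1", "D3", "D7"),
    n_tech_reps = 1, prop_de = 0.3, effect_range = c(1, 2),
    time_profile = c(0.2, 0.6, 1), lane_log_effect = 0, outlier_sample = NA,
    rng_seed = 31))
  pooled <- pool_technical_replicates(sim$counts, sim$samples)
  fits <- fit_series_ar(pooled$counts, pooled$samples,
                        sf = size_factors(pooled$counts),
                        cfg = mcmc_config(iterations = 4000, burn_in = 2000,
                                          rng_seed = 3))
  de <- sim$truth$features$de_label
  hit <- vapply(fits, function(f) sum(f$results$de_call[de], na.rm = TRUE),
                numeric(1))
  expect_true(all(diff(hit) >= 0))
})
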