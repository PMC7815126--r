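test_that("near-zero observation variance makes the posterior track the data", {
  g <- generate_adjacency(4, "grid")
  set.seed(21)
  surf <- sample_true_surface(g, 4, default_hyper(), mu = -2, seed = 21)
  obs <- make_gaussian_obs(surf, v = 1e-8)
  fit <- suppressWarnings(fit_smoothing_model(
    obs, g, smoothing_spec(chains = 1, warmup = 300, draws = 300, seed = 1)))
  pm <- apply(fit$lambda, c(2, 3), mean)
  ps <- apply(fit$lambda, c(2, 3), sd)
  y <- matrix(NA_real_, 4, 4)
  y[cbind(match(obs$admin1, g$nodes), obs$period)] <- obs$logit_q
  expect_true(all(abs(pm - y) <= 3 * ps + 1e-6))
  expect_lt(max(abs(pm - y)), 1e-2)
})

test_that("constant data with huge variance shrinks everything to the level", {
  g <- generate_adjacency(4, "grid")
  cells <- expand.grid(i = 1:4, t = 1:4)
  obs <- data.frame(admin1 = g$nodes[cells$i], period = cells$t,
                    logit_q = -2.5, var_logit_q = 25, status = "ok")
  fit <- suppressWarnings(fit_smoothing_model(
    obs, g, smoothing_spec(chains = 1, warmup = 300, draws = 400, seed = 2)))
  pm <- apply(fit$lambda, c(2, 3), mean)
  ps <- apply(fit$lambda, c(2, 3), sd)
  expect_true(all(abs(pm - (-2.5)) <= 3 * ps))
  # component draws shrink toward zero
  expect_lt(mean(abs(fit$theta)), 0.5)
  expect_lt(mean(abs(fit$alpha)), 0.5)
})

test_that("draws satisfy constraints and reassemble lambda to 1e-10", {
  g <- generate_adjacency(5, "random_planar", seed = 3)
  set.seed(22)
  surf <- sample_true_surface(g, 4, default_hyper(), mu = -2, seed = 22)
  obs <- make_gaussian_obs(surf, v = 0.05)
  fit <- fit_smoothing_model(
    obs, g, smoothing_spec(chains = 2, warmup = 250, draws = 150, seed = 3))
  S <- dim(fit$lambda)[1]
  for (s in c(1L, S %/% 2L, S)) {
    expect_equal(sum(fit$gamma[s, ]), 0, tolerance = 1e-8)
    expect_equal(sum(fit$phi[s, ]), 0, tolerance = 1e-8)
    expect_equal(rowSums(fit$delta[s, , ]), rep(0, g$n), tolerance = 1e-8)
    expect_equal(colSums(fit$delta[s, , ]), rep(0, 4), tolerance = 1e-8)
    recon <- fit$mu[s] +
      outer(fit$theta[s, ] + fit$phi[s, ], fit$alpha[s, ] + fit$gamma[s, ], "+") +
      fit$delta[s, , ]
    expect_equal(fit$lambda[s, , ], recon, tolerance = 1e-10)
  }
  expect_true(all(fit$q > 0 & fit$q < 1))
})

test_that("smoothing reduces uncertainty relative to the input variances", {
  w <- make_world(n_areas = 4, seed = 23, clusters_per_stratum = 14,
                  clusters_sampled = 7, women_per_cluster = 16)
  d <- estimate_direct(w$records, "u5")
  p <- pool_direct(d)
  fit <- suppressWarnings(fit_smoothing_model(
    p, w$graph, smoothing_spec(chains = 1, warmup = 300, draws = 300, seed = 4)))
  ok <- p$status == "ok"
  post_var <- apply(fit$lambda, c(2, 3), var)
  ia <- match(p$admin1[ok], w$graph$nodes)
  expect_lt(mean(post_var[cbind(ia, p$period[ok])]), mean(p$var_logit_q[ok]))
})

test_that("suppressing the interaction forces parallel area trends", {
  g <- generate_adjacency(6, "grid")
  set.seed(24)
  surf <- sample_true_surface(g, 5, default_hyper(sigma2_delta = 0.05),
                              mu = -2, seed = 24)
  obs <- make_gaussian_obs(surf, v = 0.02)
  dev_of <- function(s2d) {
    fit <- fit_smoothing_model(obs, g, fixed_spec(
      default_hyper(sigma2_delta = s2d), warmup = 150, draws = 150, seed = 5))
    pm <- apply(fit$lambda, c(2, 3), mean)
    ctr <- sweep(pm, 1, rowMeans(pm))          # remove area level
    max(abs(sweep(ctr, 2, colMeans(ctr))))     # deviation from common trend
  }
  d_small <- dev_of(1e-8)
  d_large <- dev_of(0.05)
  expect_lt(d_small, 0.05)
  expect_lt(d_small, d_large / 5)
})

test_that("missing cells borrow strength from the structure", {
  g <- generate_adjacency(4, "grid")
  set.seed(25)
  surf <- sample_true_surface(g, 4, default_hyper(), mu = -2, seed = 25)
  obs <- make_gaussian_obs(surf, v = 0.02)
  drop_idx <- which(obs$admin1 == "A1" & obs$period == 2)
  obs$status[drop_idx] <- "missing"
  fit <- suppressWarnings(fit_smoothing_model(
    obs, g, smoothing_spec(chains = 1, warmup = 300, draws = 300, seed = 6)))
  lam_missing <- fit$lambda[, 1, 2]
  expect_true(all(is.finite(lam_missing)))
  # wider than a comparable observed cell, but still informative
  expect_gt(sd(lam_missing), sd(fit$lambda[, 2, 2]))
  expect_lt(sd(lam_missing), 5)
  expect_error(fit_smoothing_model(obs[0, ], g), "no non-missing")
})

test_that("posterior summaries are coherent and monotone in the quantiles", {
  # hand-built fit object: known draws
  set.seed(26)
  S <- 10000
  lam <- array(rnorm(S), c(S, 1, 3))
  lam[, 1, 2] <- 0.5                     # constant draws in one cell
  lam[, 1, 3] <- rnorm(S, -2, 0.3)
  fit <- structure(list(lambda = lam, q = expit(lam), areas = "A1", T = 3,
                        period_labels = paste0("T", 1:3)),
                   class = "mort_fit")
  s <- posterior_summaries(fit, quantiles = c(0.025, 0.5, 0.975))
  expect_lt(abs(s$median[1] - 0.5), 0.01)              # expit of N(0,1) median
  expect_equal(s$q0.5[2], expit(0.5), tolerance = 1e-12)
  expect_equal(s$q0.025[2], s$q0.975[2])               # constant draws
  expect_true(all(s$q0.025 <= s$q0.5 & s$q0.5 <= s$q0.975))
})
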