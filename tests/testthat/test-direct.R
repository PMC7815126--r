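pm_table <- function(n, events, weight = 1, band = 1L, stratum = "s1",
                     cluster = "c1") {
  data.table::data.table(
    survey_id = "S1", stratum = stratum, cluster = cluster,
    woman_id = paste0("W", seq_len(n)), weight = weight, admin1 = "A1",
    birth_cmc = 1200L, age_months = 0L, band = band,
    period = 1L, event = rep(c(1L, 0L), c(events, n - events)))
}

test_that("saturated weighted logistic has the closed-form solution", {
  fit <- fit_band_logits(pm_table(1000, 2), n_bands = 1)
  expect_equal(fit$beta, logit(0.002), tolerance = 1e-12)
  expect_equal(fit$p, 0.002)
  expect_equal(fit$n_events, 2)
  expect_equal(fit$n_personmonths, 1000)
})

test_that("bands with no events or no survivors are flagged non-estimable", {
  fit0 <- fit_band_logits(pm_table(50, 0), n_bands = 1)
  expect_false(fit0$estimable)
  expect_true(is.na(fit0$beta))
  fit1 <- fit_band_logits(pm_table(50, 50), n_bands = 1)
  expect_false(fit1$estimable)
  sch <- age_scheme("u5")
  expect_equal(combine_bands_to_q(fit0, sch)$status, "missing")
})

test_that("element-level PSUs reproduce the iid binomial-logistic variance", {
  # single cluster per stratum: every person-month is its own PSU/stratum
  n <- 2000; d <- 37
  pm <- pm_table(n, d, stratum = paste0("s", seq_len(n)),
                 cluster = paste0("c", seq_len(n)))
  fit <- fit_band_logits(pm, n_bands = 1)
  p <- d / n
  expect_equal(drop(fit$cov), 1 / (n * p * (1 - p)), tolerance = 0.02)
})

test_that("estimates are invariant to a global weight rescaling", {
  w <- make_world(n_areas = 2, fieldwork = cmc(2018, 12), seed = 11,
                  clusters_per_stratum = 12, clusters_sampled = 6,
                  women_per_cluster = 12)
  d1 <- estimate_direct(w$records, "u5")
  rec2 <- w$records
  rec2$weight <- rec2$weight * 7.3
  d2 <- estimate_direct(rec2, "u5")
  expect_equal(d1$q, d2$q, tolerance = 1e-10)
  expect_equal(d1$var_logit_q, d2$var_logit_q, tolerance = 1e-10)
})

test_that("delta-method combination matches hand algebra on flat bands", {
  sch <- age_scheme("5to14")
  beta <- rep(logit(0.001), 10)
  fit <- structure(list(beta = beta, p = expit(beta),
                        cov = diag(0.01, 10), estimable = rep(TRUE, 10)),
                   class = "band_fit")
  est <- combine_bands_to_q(fit, sch)
  expect_equal(est$q, 1 - 0.999^120, tolerance = 1e-12)
  # single-band scheme of width 1: logit(q) = beta, var = Var(beta)
  sch1 <- structure(list(age_group = "u5", start = 0L, end = 1L, width = 1L,
                         n_bands = 1L), class = "age_scheme")
  fit1 <- structure(list(beta = logit(0.01), p = 0.01,
                         cov = matrix(0.04), estimable = TRUE),
                    class = "band_fit")
  est1 <- combine_bands_to_q(fit1, sch1)
  expect_equal(est1$logit_q, logit(0.01), tolerance = 1e-12)
  expect_equal(est1$var_logit_q, 0.04, tolerance = 1e-12)
})

test_that("surveys with insufficient period overlap yield no estimate", {
  # anchor 2018; a second survey ending 12 months into a period informs that
  # period only through <= 12 months of overlap and must be excluded there
  w <- make_world(n_areas = 2, fieldwork = cmc(2018, 12), seed = 12,
                  clusters_per_stratum = 10, clusters_sampled = 5,
                  women_per_cluster = 10)
  grid <- w$grid
  end2 <- grid$start[6] + 11L   # exactly 12 months inside the last period
  rec2 <- simulate_survey(w$surfaces, w$design, grid, end2,
                          survey_id = "S2", seed = 13)
  d <- estimate_direct(rbind(w$records, rec2), "u5", grid = grid)
  expect_false(any(d$survey_id == "S2" & d$period == 6))
  expect_true(any(d$survey_id == "S1" & d$period == 6))
})

test_that("large simulated surveys recover the generating block probabilities", {
  # scaled-down version of the large-sample recovery property: the 3-SE
  # criterion adapts to the realised sampling error
  w <- make_world(n_areas = 4, fieldwork = cmc(2018, 12), seed = 14,
                  clusters_per_stratum = 40, clusters_sampled = 18,
                  women_per_cluster = 28, mu_u5 = logit(0.10))
  d <- estimate_direct(w$records, "u5")
  d <- d[d$status == "ok" & d$period >= 4, ]   # periods with full exposure
  expect_gte(nrow(d), 8)
  ia <- match(d$admin1, w$graph$nodes)
  truth <- expit(w$surfaces$u5$lambda[cbind(ia, d$period)])
  z <- abs(logit(truth) - d$logit_q) / sqrt(d$var_logit_q)
  expect_gte(mean(z < 3), 0.95)
})
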