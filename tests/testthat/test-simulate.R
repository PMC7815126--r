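# helper: a flat surface with a prescribed block probability per area
flat_surface <- function(graph, T_, block_q_by_area) {
  s <- sample_true_surface(graph, T_, default_hyper(
    sigma2_alpha = 0, sigma2_gamma = 0, sigma2_theta = 0, sigma2_phi = 0,
    sigma2_delta = 0), mu = 0)
  s$lambda <- matrix(ifelse(block_q_by_area > 0, logit(block_q_by_area), -Inf),
                     graph$n, T_)
  s
}

test_that("zero hazards produce no deaths", {
  g <- generate_adjacency(2)
  grid <- build_period_grid(cmc(2018, 12), "u5")
  surf <- list(u5 = flat_surface(g, grid$T, c(0, 0)),
               "5to14" = flat_surface(g, grid$T, c(0, 0)))
  des <- sampling_design(g, 6, 3, 10, seed = 1)
  rec <- simulate_survey(surf, des, grid, cmc(2018, 12), seed = 2)
  expect_gt(nrow(rec), 0)
  expect_false(any(rec$died))
  expect_silent(validate_child_records(rec))
})

test_that("PPS cluster selection frequencies are proportional to size", {
  sizes <- c(50, 80, 120, 200, 350, 100, 150, 250)
  m <- 3
  reps <- 10000
  counts <- numeric(length(sizes))
  set.seed(42)
  for (r in seq_len(reps)) {
    sel <- mortsmooth:::pps_systematic(sizes, m)
    counts[sel] <- counts[sel] + 1
  }
  expected <- reps * m * sizes / sum(sizes)
  stat <- sum((counts - expected)^2 / expected)
  # systematic PPS has sub-multinomial variance, so the upper tail of the
  # chi-square reference is conservative
  expect_lt(stat, qchisq(0.99, df = length(sizes) - 1))
  expect_equal(sum(counts), reps * m)
})

test_that("weighted child totals are design-unbiased (Horvitz-Thompson)", {
  g <- generate_adjacency(4, "grid")
  grid <- build_period_grid(cmc(2018, 12), "u5")
  surf <- list(u5 = flat_surface(g, grid$T, rep(0.05, 4)),
               "5to14" = flat_surface(g, grid$T, rep(0, 4)))
  des <- sampling_design(g, clusters_per_stratum = 12, clusters_sampled = 4,
                         women_per_cluster = 10, seed = 3)
  fertility <- 0.0175
  # expected births per woman: fertility x mean reproductive window (ages
  # 15-49 uniform -> mean window (1+408)/2 months)
  truth <- sum(des$frame$n_women) * fertility * mean(1:408)
  ratios <- vapply(seq_len(200), function(r) {
    rec <- simulate_survey(surf, des, grid, cmc(2018, 12),
                           fertility = fertility, seed = 1000 + r)
    sum(rec$weight) / truth
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("a 4x monthly-hazard contrast shows up in weighted death rates", {
  g <- generate_adjacency(2)
  grid <- build_period_grid(cmc(2018, 12), "u5")
  q_hi <- 1 - (1 - 0.004)^60
  q_lo <- 1 - (1 - 0.001)^60
  surf <- list(u5 = flat_surface(g, grid$T, c(q_hi, q_lo)),
               "5to14" = flat_surface(g, grid$T, c(0, 0)))
  des <- sampling_design(g, clusters_per_stratum = 40, clusters_sampled = 25,
                         women_per_cluster = 30, seed = 4)
  rec <- simulate_survey(surf, des, grid, cmc(2018, 12), seed = 5)
  pm <- expand_person_months(rec, grid, age_scheme("u5"))
  rate <- sapply(split(pm, pm$admin1), function(d)
    sum(d$weight * d$event) / sum(d$weight))
  expect_equal(unname(rate["A1"] / rate["A2"]), 4, tolerance = 0.15)
})

test_that("child record CSV round-trips through the documented schema", {
  w <- make_world(n_areas = 2, fieldwork = cmc(2018, 12), seed = 6,
                  clusters_per_stratum = 6, clusters_sampled = 3,
                  women_per_cluster = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_child_records(w$records, path)
  rec2 <- read_child_records(path)
  expect_equal(nrow(rec2), nrow(w$records))
  expect_equal(rec2$weight, w$records$weight, tolerance = 1e-12)
  expect_equal(rec2$died, w$records$died)
})

test_that("fieldwork outside the surface support is rejected", {
  g <- generate_adjacency(2)
  grid <- build_period_grid(cmc(2018, 12), "u5")
  surf <- list(u5 = flat_surface(g, grid$T, c(0.05, 0.05)),
               "5to14" = flat_surface(g, grid$T, c(0, 0)))
  des <- sampling_design(g, 6, 3, 5)
  expect_error(simulate_survey(surf, des, grid, grid$start[1] - 1L),
               "support")
})
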