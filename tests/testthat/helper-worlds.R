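# Shared fixtures: small synthetic worlds built in code.

default_hyper <- function(...) {
  utils::modifyList(list(sigma2_alpha = 0.002, sigma2_gamma = 0.05,
                         sigma2_theta = 0.002, sigma2_phi = 0.03,
                         sigma2_delta = 0.01),
                    list(...))
}

# one simulated multi-survey world; sizes kept small for test runtime
make_world <- function(n_areas = 4, fieldwork = cmc(c(2018, 2013, 2008), 12),
                       clusters_per_stratum = 20, clusters_sampled = 8,
                       women_per_cluster = 25, mu_u5 = logit(0.10),
                       mu_5to14 = logit(0.03), seed = 1,
                       hyper = default_hyper(), shared_icar_sd = 0) {
  graph <- generate_adjacency(n_areas, "grid", seed = seed)
  grid <- build_period_grid(max(fieldwork), "u5")
  surfaces <- sample_surface_pair(graph, grid$T, hyper, hyper,
                                  mu_u5 = mu_u5, mu_5to14 = mu_5to14,
                                  shared_icar_sd = shared_icar_sd, seed = seed)
  design <- sampling_design(graph, clusters_per_stratum, clusters_sampled,
                            women_per_cluster, seed = seed)
  records <- do.call(rbind, lapply(seq_along(fieldwork), function(k)
    simulate_survey(surfaces, design, grid, fieldwork[k],
                    survey_id = paste0("S", k), seed = seed + 97L * k)))
  list(graph = graph, grid = grid, surfaces = surfaces, design = design,
       records = records)
}

# direct Gaussian observations of a known surface (skips survey machinery)
make_gaussian_obs <- function(surface, v, age_group = "u5") {
  n <- nrow(surface$lambda); T_ <- surface$T
  cells <- expand.grid(i = seq_len(n), t = seq_len(T_))
  data.frame(admin1 = surface$graph$nodes[cells$i], period = cells$t,
             period_label = paste0("T", cells$t), age_group = age_group,
             logit_q = rnorm(nrow(cells), surface$lambda[cbind(cells$i, cells$t)],
                             sqrt(v)),
             var_logit_q = v, q = NA_real_, n_surveys = 1L,
             hiv_adjusted = FALSE, status = "ok")
}

fixed_spec <- function(hyper, chains = 1L, warmup = 100L, draws = 200L,
                       seed = 1L) {
  smoothing_spec(chains = chains, warmup = warmup, draws = draws,
                 seed = seed, fix_hyper = hyper)
}
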