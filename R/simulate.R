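#' Stratified two-stage sampling design
#'
#' Emulates the DHS frame: strata are Admin-1 x urban/rural cells, each
#' holding a list of clusters (enumeration areas) with known numbers of
#' resident women aged 15-49. Stage one selects clusters within each stratum
#' with probability proportional to size (systematic PPS); stage two selects
#' a fixed number of women per sampled cluster by simple random sampling.
#' Design weights are the inverse product of the two inclusion
#' probabilities; non-response is not simulated.
#'
#' @param graph an [adjacency_graph()] naming the Admin-1 areas.
#' @param clusters_per_stratum number of clusters in each stratum's frame.
#' @param clusters_sampled clusters drawn per stratum.
#' @param women_per_cluster women drawn per sampled cluster.
#' @param mean_cluster_women expected women per cluster in the frame
#'   (cluster sizes are drawn uniformly between 0.5x and 1.5x this mean).
#' @param seed integer seed for the frame construction.
#' @return Object of class `sampling_design`: data.frame `frame` with one
#'   row per cluster (`stratum`, `admin1`, `urban`, `cluster`, `n_women`)
#'   plus the sampling counts.
#' @export
sampling_design <- function(graph, clusters_per_stratum = 30L,
                            clusters_sampled = 10L, women_per_cluster = 20L,
                            mean_cluster_women = 120L, seed = 1L) {
  stopifnot(clusters_sampled <= clusters_per_stratum)
  set.seed(seed)
  strata <- expand.grid(admin1 = graph$nodes, urban = c("urban", "rural"),
                        stringsAsFactors = FALSE)
  frame <- do.call(rbind, lapply(seq_len(nrow(strata)), function(s) {
    data.frame(
      stratum = paste(strata$admin1[s], strata$urban[s], sep = ":"),
      admin1 = strata$admin1[s], urban = strata$urban[s],
      cluster = paste(strata$admin1[s], strata$urban[s],
                      seq_len(clusters_per_stratum), sep = ":"),
      n_women = pmax(2L * women_per_cluster, as.integer(round(runif(
        clusters_per_stratum, 0.5 * mean_cluster_women,
        1.5 * mean_cluster_women))))
    )
  }))
  rownames(frame) <- NULL
  structure(list(frame = frame, clusters_sampled = as.integer(clusters_sampled),
                 women_per_cluster = as.integer(women_per_cluster),
                 graph = graph),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("<sampling_design: %d strata, %d clusters, %d x %d women sampled per stratum>\n",
              length(unique(x$frame$stratum)), nrow(x$frame),
              x$clusters_sampled, x$women_per_cluster))
  invisible(x)
}

## systematic PPS selection of m clusters; returns row indices into `sizes`.
## Inclusion probability of cluster c is m * size_c / sum(sizes) (sizes are
## checked to keep m * size < total so no certainty selections arise).
pps_systematic <- function(sizes, m) {
  tot <- sum(sizes)
  if (any(m * sizes >= tot)) stop("cluster size too large for PPS without certainties")
  cum <- cumsum(sizes)
  step <- tot / m
  u <- runif(1, 0, step)
  pts <- u + step * (seq_len(m) - 1)
  findInterval(pts, c(0, cum), left.open = TRUE)
}

#' Draw the sampled clusters and women of one survey
#'
#' @param design a [sampling_design()].
#' @return data.frame with one row per sampled woman: design labels and the
#'   design weight (inverse inclusion probability).
#' @keywords internal
draw_sample <- function(design) {
  fr <- design$frame
  m <- design$clusters_sampled
  out <- lapply(split(seq_len(nrow(fr)), fr$stratum), function(idx) {
    sizes <- fr$n_women[idx]
    sel <- idx[pps_systematic(sizes, m)]
    pi1 <- m * fr$n_women[sel] / sum(sizes)
    pi2 <- design$women_per_cluster / fr$n_women[sel]
    data.frame(
      stratum = rep(fr$stratum[sel], each = design$women_per_cluster),
      admin1 = rep(fr$admin1[sel], each = design$women_per_cluster),
      cluster = rep(fr$cluster[sel], each = design$women_per_cluster),
      weight = rep(1 / (pi1 * pi2), each = design$women_per_cluster)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$woman_id <- paste0(out$cluster, ":W", stats::ave(
    seq_len(nrow(out)), out$cluster, FUN = seq_along))
  out
}

#' Simulate one survey's full birth histories
#'
#' Each sampled woman is aged 15-49 at interview (uniform) and her births
#' form a Poisson process at rate `fertility` births per woman-month over
#' the months since she turned 15, so older women report births decades
#' back -- the feature of full birth histories that lets a survey inform
#' periods up to 24 years before fieldwork. Each child is
#' then followed month by month: in the month reaching age a (completed
#' months) and calendar month m, the child dies with the monthly probability
#' implied by the true surface -- the block probability expit(lambda_it) of
#' the child's area i and the period t containing m, split into per-band
#' monthly probabilities by [hazards_from_block_q()]. Calendar months before
#' the first period reuse the first period's hazards. Follow-up stops at
#' death, at age 180 months, or in the month before interview (the interview
#' month is incomplete exposure).
#'
#' @param surfaces list with `u5` and `5to14` elements of class
#'   `true_surface` sharing one graph and period count.
#' @param design a [sampling_design()] on the same graph.
#' @param grid a [build_period_grid()] result giving the calendar support of
#'   the surfaces (`grid$T` must equal the surfaces' `T`).
#' @param fieldwork_end interview month (CMC) for all women.
#' @param fertility births per woman-month of reproductive exposure
#'   (default 0.0175: about 3.6 births for the average woman, near
#'   sub-Saharan completed parity).
#' @param multipliers_u5,multipliers_5to14 per-band hazard multipliers.
#' @param survey_id label stored on every record.
#' @param seed integer seed.
#' @return data.frame of child records: `survey_id`, `stratum`, `cluster`,
#'   `woman_id`, `weight`, `interview_cmc`, `birth_cmc`, `died`,
#'   `age_at_death_months` (NA unless died), `admin1`.
#' @export
simulate_survey <- function(surfaces, design, grid, fieldwork_end,
                            fertility = 0.0175,
                            multipliers_u5 = c(6, 2, 1, 0.8, 0.6, 0.5),
                            multipliers_5to14 = rep(1, 10),
                            survey_id = "S1", seed = 1L) {
  stopifnot(inherits(design, "sampling_design"), inherits(grid, "period_grid"))
  if (surfaces$u5$T != grid$T || surfaces[["5to14"]]$T != grid$T)
    stop("surface period count does not match the grid")
  if (fieldwork_end < grid$start[1] || fieldwork_end >= grid$end[grid$T])
    stop("fieldwork month lies outside the surface's calendar support")
  set.seed(seed)
  women <- draw_sample(design)
  sch_u5 <- age_scheme("u5"); sch_514 <- age_scheme("5to14")
  ## per (area, period): monthly q by age band, rows = 16 bands (6 + 10)
  areas <- design$graph$nodes
  bandq <- array(0, dim = c(16L, length(areas), grid$T))
  for (i in seq_along(areas)) for (t in seq_len(grid$T)) {
    q_u5 <- expit(surfaces$u5$lambda[i, t])
    q_514 <- expit(surfaces[["5to14"]]$lambda[i, t])
    bandq[1:6, i, t] <- if (q_u5 > 0)
      hazards_from_block_q(q_u5, sch_u5, multipliers_u5)$monthly_q else 0
    bandq[7:16, i, t] <- if (q_514 > 0)
      hazards_from_block_q(q_514, sch_514, multipliers_5to14)$monthly_q else 0
  }
  band_of_age <- c(age_band_index(0:59, sch_u5), 6L + age_band_index(60:179, sch_514))
  interview <- as.integer(fieldwork_end)
  ## clamp calendar months to the grid support (earlier months reuse period 1)
  pidx <- function(m) pmin(pmax(findInterval(m, grid$start), 1L), grid$T)
  n_w <- nrow(women)
  ## reproductive exposure: months since turning 15, for an age drawn
  ## uniformly over 15-49 completed years at interview
  window <- sample.int(408L, n_w, replace = TRUE)
  n_births <- rpois(n_w, fertility * window)
  rows <- vector("list", n_w)
  for (w in seq_len(n_w)) {
    nb <- n_births[w]
    if (nb == 0) next
    birth <- interview - sort(sample.int(window[w], nb, replace = TRUE))
    area_i <- match(women$admin1[w], areas)
    died <- logical(nb); aad <- rep(NA_integer_, nb)
    for (b in seq_len(nb)) {
      dur <- min(180L, interview - birth[b])        # months fully lived
      if (dur <= 0) next
      ages <- 0:(dur - 1L)
      q <- bandq[cbind(band_of_age[ages + 1L], area_i, pidx(birth[b] + ages))]
      surv <- cumprod(1 - q)
      u <- runif(1)
      if (u > surv[dur]) {
        died[b] <- TRUE
        aad[b] <- ages[match(TRUE, u > surv)]
      }
    }
    rows[[w]] <- data.frame(
      survey_id = survey_id, stratum = women$stratum[w],
      cluster = women$cluster[w], woman_id = women$woman_id[w],
      weight = women$weight[w], interview_cmc = interview,
      birth_cmc = birth, died = died, age_at_death_months = aad,
      admin1 = women$admin1[w])
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec))
    rec <- data.frame(survey_id = character(0), stratum = character(0),
                      cluster = character(0), woman_id = character(0),
                      weight = numeric(0), interview_cmc = integer(0),
                      birth_cmc = integer(0), died = logical(0),
                      age_at_death_months = integer(0), admin1 = character(0))
  rownames(rec) <- NULL
  rec
}

#' Validate child records against the schema invariants
#'
#' @param records a child-record data.frame as produced by
#'   [simulate_survey()] or read from CSV.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_child_records <- function(records) {
  need <- c("survey_id", "stratum", "cluster", "woman_id", "weight",
            "interview_cmc", "birth_cmc", "died", "age_at_death_months",
            "admin1")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(records$weight <= 0)) stop("weights must be strictly positive")
  if (any(records$birth_cmc > records$interview_cmc))
    stop("birth after interview")
  d <- records$died
  if (any(d & is.na(records$age_at_death_months)))
    stop("died records need age_at_death_months")
  if (any(d & records$age_at_death_months < 0))
    stop("negative age at death")
  if (any(d & records$birth_cmc + records$age_at_death_months >
          records$interview_cmc))
    stop("death after interview")
  invisible(TRUE)
}

#' Read / write child-record CSV files
#' @param records child-record data.frame.
#' @param path file path.
#' @export
write_child_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_child_records
#' @export
read_child_records <- function(path) {
  rec <- utils::read.csv(path, colClasses = c(
    survey_id = "character", stratum = "character", cluster = "character",
    woman_id = "character", weight = "numeric", interview_cmc = "integer",
    birth_cmc = "integer", died = "logical",
    age_at_death_months = "integer", admin1 = "character"))
  validate_child_records(rec)
  rec
}
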