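#' Expand child records into person-months
#'
#' Discrete-time survival analysis works on child-month data: one row per
#' child per month of age lived, with a 0/1 death indicator. A child
#' contributes the months of age 0, 1, ... up to (exclusive) the completed
#' age at interview (the interview month itself is incomplete exposure and
#' is dropped), or up to and including the month of death, which counts as
#' one full exposed month with `event = 1`. Months falling outside the
#' period grid's calendar support, or outside the age scheme's support, are
#' dropped.
#'
#' @param records child-record data.frame (see [simulate_survey()]).
#' @param grid a [build_period_grid()] result.
#' @param scheme an [age_scheme()]; must match the grid's age group.
#' @return `data.table` with columns `survey_id`, `stratum`, `cluster`,
#'   `woman_id`, `weight`, `admin1`, `birth_cmc`, `age_months`, `band`,
#'   `period`, `event`.
#' @export
expand_person_months <- function(records, grid, scheme) {
  validate_child_records(records)
  stopifnot(inherits(grid, "period_grid"), inherits(scheme, "age_scheme"))
  if (grid$age_group != scheme$age_group)
    stop("grid and scheme disagree on the age group")
  dt <- data.table::as.data.table(records)
  ## months lived: death month included with event, interview month excluded
  dt[, n_months := ifelse(died, age_at_death_months + 1L,
                          interview_cmc - birth_cmc)]
  ## restrict expansion to the scheme's age support
  a_lo <- scheme$start[1]; a_hi <- scheme$end[scheme$n_bands]
  dt <- dt[n_months > a_lo]
  if (nrow(dt) == 0)
    return(data.table::data.table(
      survey_id = character(0), stratum = character(0), cluster = character(0),
      woman_id = character(0), weight = numeric(0), admin1 = character(0),
      age_months = integer(0), band = integer(0), period = integer(0),
      event = integer(0)))
  dt[, `:=`(a_from = a_lo, a_to = pmin(n_months, a_hi))]
  idx <- rep(seq_len(nrow(dt)), dt$a_to - dt$a_from)
  pm <- dt[idx, .(survey_id, stratum, cluster, woman_id, weight, admin1,
                  birth_cmc, died, n_months)]
  pm[, age_months := a_lo + sequence(dt$a_to - dt$a_from) - 1L]
  pm[, event := as.integer(died & age_months == n_months - 1L)]
  pm[, band := age_band_index(age_months, scheme)]
  pm[, period := period_index(birth_cmc + age_months, grid)]
  pm <- pm[!is.na(period) & !is.na(band)]
  pm[, c("died", "n_months") := NULL]
  pm[]
}
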