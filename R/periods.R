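#' Century-month-code helpers
#'
#' All calendar arithmetic uses the DHS century month code: months since
#' January 1900, so that January 1900 is 1 and December 2018 is 1428. Ages
#' in completed months are plain CMC differences.
#'
#' @param year,month calendar year and month.
#' @export
cmc <- function(year, month = 1L) as.integer((year - 1900L) * 12L + month)

#' @rdname cmc
#' @param x CMC value(s).
#' @export
cmc_year <- function(x) 1900L + (as.integer(x) - 1L) %/% 12L

#' Build the 4-year period grid shared by all surveys
#'
#' Periods are 4-year (48-month) calendar intervals anchored so that the most
#' recent survey's fieldwork end closes the last period; earlier breaks
#' follow backwards in 48-month steps. The grid reaches back far enough to
#' cover every survey's retrospective window: 24 years for under-5 (at most
#' 6 periods per survey) and 12 years for ages 5-14 (at most 3 periods per
#' survey, limiting first-born excess-mortality bias in old recall).
#'
#' @param fieldwork_end integer CMC vector, one fieldwork end month per survey.
#' @param age_group `"u5"` or `"5to14"`.
#' @return Object of class `period_grid`: list with `start`, `end` (CMC,
#'   end-exclusive, oldest period first), `labels` (year ranges), `T`,
#'   `age_group`, `anchor` (CMC closing the last period), `years_back`,
#'   `max_periods`.
#' @examples
#' build_period_grid(cmc(2018, 12), "5to14")$labels
#' # "2007-2010" "2011-2014" "2015-2018"
#' @export
build_period_grid <- function(fieldwork_end, age_group = c("u5", "5to14")) {
  age_group <- match.arg(age_group)
  if (length(fieldwork_end) < 1) stop("need at least one survey fieldwork end")
  fieldwork_end <- as.integer(fieldwork_end)
  years_back <- if (age_group == "u5") 24L else 12L
  max_periods <- if (age_group == "u5") 6L else 3L
  anchor <- max(fieldwork_end) + 1L          # end-exclusive bound of last period
  earliest <- min(fieldwork_end) + 1L - 12L * years_back
  T_ <- as.integer(ceiling((anchor - earliest) / 48))
  end <- anchor - 48L * (T_ - seq_len(T_))   # oldest first
  start <- end - 48L
  structure(list(start = start, end = end,
                 labels = paste0(cmc_year(start), "-", cmc_year(end - 1L)),
                 T = T_, age_group = age_group, anchor = anchor,
                 years_back = years_back, max_periods = max_periods),
            class = "period_grid")
}

#' @export
print.period_grid <- function(x, ...) {
  cat(sprintf("<period_grid %s: %d x 48-month periods, %s .. %s>\n",
              x$age_group, x$T, x$labels[1], x$labels[x$T]))
  invisible(x)
}

#' Period index of calendar months
#' @param cmc_month integer CMC vector.
#' @param grid a [build_period_grid()] result.
#' @return Integer period indices (1 = oldest); `NA` outside the grid.
#' @export
period_index <- function(cmc_month, grid) {
  idx <- findInterval(cmc_month, grid$start)
  idx[cmc_month < grid$start[1] | cmc_month >= grid$end[grid$T]] <- NA_integer_
  idx
}

#' Periods a survey is allowed to inform
#'
#' A survey's retrospective window covers the `years_back` years before its
#' fieldwork end, and is further capped at `max_periods` grid periods. A
#' survey that overlaps a period by no more than `min_exposure_months`
#' (default 12: "only one year of exposure") does not inform that period.
#'
#' @param fieldwork_end single CMC value.
#' @param grid a [build_period_grid()] result.
#' @param min_exposure_months exclusion threshold on calendar overlap.
#' @return Integer vector of period indices the survey informs.
#' @export
survey_periods <- function(fieldwork_end, grid, min_exposure_months = 12L) {
  w_end <- as.integer(fieldwork_end) + 1L
  w_start <- w_end - 12L * grid$years_back
  overlap <- pmax(0L, pmin(grid$end, w_end) - pmax(grid$start, w_start))
  ok <- which(overlap > min_exposure_months)
  if (length(ok) > grid$max_periods)
    ok <- utils::tail(ok, grid$max_periods)
  ok
}
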