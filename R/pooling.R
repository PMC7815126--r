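#' Pool per-survey direct estimates by inverse-variance weighting
#'
#' Surveys observing the same admin1 x period cell are combined on the logit
#' scale as a fixed-effect meta-analysis: pooled value
#' sum(x_s / V_s) / sum(1 / V_s), pooled variance 1 / sum(1 / V_s). Cells
#' where every contributing survey is missing stay missing.
#'
#' @param direct data.frame from [estimate_direct()] (one age group).
#' @return data.frame with one row per admin1 x period: `admin1`, `period`,
#'   `period_label`, `age_group`, `q`, `logit_q`, `var_logit_q`,
#'   `n_surveys`, `hiv_adjusted` (FALSE), `status`.
#' @export
pool_direct <- function(direct) {
  stopifnot(all(c("admin1", "period", "logit_q", "var_logit_q", "status")
                %in% names(direct)))
  out <- lapply(split(direct, list(direct$admin1, direct$period), drop = TRUE),
                function(d) {
    ok <- d[d$status == "ok" & is.finite(d$var_logit_q) & d$var_logit_q > 0, ]
    base <- data.frame(admin1 = d$admin1[1], period = d$period[1],
                       period_label = d$period_label[1],
                       age_group = d$age_group[1])
    if (nrow(ok) == 0)
      return(cbind(base, q = NA_real_, logit_q = NA_real_,
                   var_logit_q = NA_real_, n_surveys = 0L,
                   hiv_adjusted = FALSE, status = "missing"))
    w <- 1 / ok$var_logit_q
    x <- sum(w * ok$logit_q) / sum(w)
    cbind(base, q = expit(x), logit_q = x, var_logit_q = 1 / sum(w),
          n_surveys = nrow(ok), hiv_adjusted = FALSE, status = "ok")
  })
  out <- do.call(rbind, out)
  out <- out[order(out$admin1, out$period), ]
  rownames(out) <- NULL
  out
}

#' Pool a single cell's estimates (closed form)
#'
#' @param logit_q,var_logit_q numeric vectors of per-survey values.
#' @return list with `logit_q`, `var_logit_q`.
#' @export
pool_surveys <- function(logit_q, var_logit_q) {
  stopifnot(length(logit_q) == length(var_logit_q), length(logit_q) >= 1,
            all(var_logit_q > 0))
  w <- 1 / var_logit_q
  list(logit_q = sum(w * logit_q) / sum(w), var_logit_q = 1 / sum(w))
}

#' Apply HIV adjustment factors to pooled under-5 estimates
#'
#' Mothers who died of HIV cannot report their (high-risk) children, biasing
#' 5q0 downward in high-prevalence settings; externally supplied
#' multiplicative correction factors are applied to the pooled under-5
#' probabilities. The factor acts on the probability scale; the logit-scale
#' variance is carried over unchanged. Estimates for ages 5-14 are returned
#' untouched (no corrections exist for that age group). Lookup order: an
#' exact `admin1` match wins over a country-level match; areas/countries
#' absent from the table pass through unadjusted.
#'
#' @param pooled data.frame from [pool_direct()].
#' @param hiv_table data.frame with columns `area_or_country`,
#'   `period_label`, `factor` (positive multipliers), or `NULL` for no-op.
#' @param country country label used for country-level matches.
#' @return `pooled` with adjusted `q`/`logit_q` and `hiv_adjusted` set where
#'   a factor applied.
#' @export
apply_hiv_adjustment <- function(pooled, hiv_table = NULL, country = NULL) {
  if (is.null(hiv_table) || nrow(pooled) == 0) return(pooled)
  stopifnot(all(c("area_or_country", "period_label", "factor")
                %in% names(hiv_table)))
  if (any(hiv_table$factor <= 0)) stop("HIV factors must be positive")
  if (!all(pooled$age_group %in% "u5")) {
    if (all(pooled$age_group %in% "5to14")) return(pooled)
    stop("apply to one age group at a time")
  }
  listed <- unique(hiv_table$area_or_country)
  for (r in which(pooled$status == "ok")) {
    key_a <- hiv_table$area_or_country == pooled$admin1[r] &
      hiv_table$period_label == pooled$period_label[r]
    key_c <- !is.null(country) && any(
      hiv_table$area_or_country == country &
        hiv_table$period_label == pooled$period_label[r])
    if (any(key_a)) {
      f <- hiv_table$factor[which(key_a)[1]]
    } else if (isTRUE(key_c)) {
      f <- hiv_table$factor[which(hiv_table$area_or_country == country &
        hiv_table$period_label == pooled$period_label[r])[1]]
    } else if (pooled$admin1[r] %in% listed ||
               (!is.null(country) && country %in% listed)) {
      stop("no HIV factor for listed area/country in period ",
           pooled$period_label[r])
    } else next
    qadj <- pooled$q[r] * f
    if (qadj >= 1) stop("HIV-adjusted probability reaches 1")
    pooled$q[r] <- qadj
    pooled$logit_q[r] <- logit(qadj)
    pooled$hiv_adjusted[r] <- TRUE
  }
  pooled
}
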