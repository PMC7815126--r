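#' Weighted per-band logistic fit with design-based covariance
#'
#' With age-band indicators as the only covariates the weighted logistic
#' likelihood is saturated, so the fitted monthly probability in band a is
#' the weighted death proportion among that band's person-months and
#' beta_a is its logit. The covariance of the beta vector is the standard
#' Taylor-linearization (sandwich) estimator for a stratified cluster
#' design: score residuals are totalled within primary sampling units
#' (clusters), centred at their stratum means, with the n_h/(n_h - 1)
#' finite-sample factor; strata containing a single sampled cluster are
#' centred at the grand mean instead (the usual lonely-PSU adjustment).
#'
#' @param pm person-month `data.table` (one estimation cell: already
#'   filtered to one admin1 x period x survey).
#' @param n_bands number of bands in the age scheme.
#' @return Object of class `band_fit`: list with `beta` (length `n_bands`,
#'   `NA` where non-estimable), `cov` (design-based covariance over the
#'   estimable bands, `NA` rows/cols elsewhere), `p` (monthly probability
#'   per band), `n_events`, `n_personmonths`, `estimable` (logical).
#' @export
fit_band_logits <- function(pm, n_bands) {
  stopifnot(nrow(pm) > 0)
  sw  <- tapply_num(pm$weight, pm$band, n_bands)
  swy <- tapply_num(pm$weight * pm$event, pm$band, n_bands)
  nev <- tapply_num(as.numeric(pm$event), pm$band, n_bands)
  npm <- tapply_num(rep(1, nrow(pm)), pm$band, n_bands)
  p <- ifelse(sw > 0, swy / sw, NA_real_)
  estimable <- !is.na(p) & p > 0 & p < 1
  beta <- ifelse(estimable, logit(p), NA_real_)
  cov <- matrix(NA_real_, n_bands, n_bands)
  if (any(estimable)) {
    eb <- which(estimable)
    ## score residuals u_a = w * (y - p_a), totalled per cluster
    res <- pm$weight * (pm$event - p[pm$band])
    cl <- interaction(pm$stratum, pm$cluster, drop = TRUE)
    Z <- matrix(0, nlevels(cl), n_bands)
    key <- (as.integer(cl) - 1L) * n_bands + pm$band
    agg <- rowsum(res, key)
    ids <- as.integer(rownames(agg))
    Z[cbind((ids - 1L) %/% n_bands + 1L, (ids - 1L) %% n_bands + 1L)] <- agg
    strat <- as.character(pm$stratum)[match(levels(cl), as.character(cl))]
    B <- matrix(0, n_bands, n_bands)
    grand <- colMeans(Z)
    for (h in unique(strat)) {
      rows <- which(strat == h)
      nh <- length(rows)
      if (nh == 1L) {
        d <- Z[rows, ] - grand
        B <- B + tcrossprod(d)
      } else {
        ctr <- sweep(Z[rows, , drop = FALSE], 2, colMeans(Z[rows, , drop = FALSE]))
        B <- B + nh / (nh - 1) * crossprod(ctr)
      }
    }
    Ainv <- 1 / (sw * p * (1 - p))            # inverse Fisher info, diagonal
    V <- (Ainv %o% Ainv * B)
    cov[eb, eb] <- V[eb, eb]
    cov[eb, eb] <- (cov[eb, eb] + t(cov[eb, eb])) / 2
  }
  structure(list(beta = beta, cov = cov, p = p,
                 n_events = nev, n_personmonths = npm, estimable = estimable),
            class = "band_fit")
}

## fast named-bucket sums over band index 1..k
tapply_num <- function(x, band, k) {
  out <- numeric(k)
  s <- rowsum(x, band)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit: %d/%d bands estimable, %d events in %d person-months>\n",
              sum(x$estimable), length(x$beta), sum(x$n_events),
              sum(x$n_personmonths)))
  invisible(x)
}

#' Combine band-level fits into a block probability with delta-method variance
#'
#' Applies the life-table product q = 1 - prod_a (1 - p_a)^{n_a} with
#' p_a = expit(beta_a) and the band widths n_a as exponents, then propagates
#' the design-based covariance of beta to logit(q) by the delta method:
#' d logit(q) / d beta_a = n_a p_a / q, so V = g' Sigma g.
#'
#' @param fit a [fit_band_logits()] result.
#' @param scheme the matching [age_scheme()].
#' @return list with `q`, `logit_q`, `var_logit_q`, `status` (`"ok"` or
#'   `"missing"` when any band is non-estimable).
#' @export
combine_bands_to_q <- function(fit, scheme) {
  if (!all(fit$estimable))
    return(list(q = NA_real_, logit_q = NA_real_, var_logit_q = NA_real_,
                status = "missing"))
  p <- fit$p
  q <- 1 - exp(sum(scheme$width * log1p(-p)))
  g <- scheme$width * p / q
  v <- drop(t(g) %*% fit$cov %*% g)
  list(q = q, logit_q = logit(q), var_logit_q = v, status = "ok")
}

#' Direct survey-specific estimates for every area-period cell
#'
#' Orchestrates the first stage: builds (or reuses) the shared period grid,
#' expands person-months, and for each admin1 x period x survey cell whose
#' calendar overlap passes the one-year exposure rule fits the band logits
#' and combines them into a probability of dying with design-based
#' variance. Cells with data but a non-estimable band (no deaths or no
#' survivors in a required band) are reported with `status = "missing"`.
#'
#' @param records child-record data.frame (possibly several surveys).
#' @param age_group `"u5"` or `"5to14"`.
#' @param grid optional [build_period_grid()]; by default built from the
#'   fieldwork end (max interview month) of each survey in `records`.
#' @param min_exposure_months survey-period exclusion threshold (default 12).
#' @return data.frame with one row per produced cell: `admin1`, `period`,
#'   `period_label`, `survey_id`, `age_group`, `q`, `logit_q`,
#'   `var_logit_q`, `status`.
#' @export
estimate_direct <- function(records, age_group = c("u5", "5to14"),
                            grid = NULL, min_exposure_months = 12L) {
  age_group <- match.arg(age_group)
  validate_child_records(records)
  scheme <- age_scheme(age_group)
  ends <- tapply(records$interview_cmc, records$survey_id, max)
  if (is.null(grid)) grid <- build_period_grid(as.integer(ends), age_group)
  pm <- expand_person_months(records, grid, scheme)
  out <- list()
  for (s in names(ends)) {
    allowed <- survey_periods(ends[[s]], grid, min_exposure_months)
    pms <- pm[pm$survey_id == s & pm$period %in% allowed]
    if (nrow(pms) == 0) next
    for (cell in split(pms, by = c("admin1", "period"), drop = TRUE)) {
      fit <- fit_band_logits(cell, scheme$n_bands)
      est <- combine_bands_to_q(fit, scheme)
      out[[length(out) + 1L]] <- data.frame(
        admin1 = cell$admin1[1], period = cell$period[1],
        period_label = grid$labels[cell$period[1]], survey_id = s,
        age_group = age_group, q = est$q, logit_q = est$logit_q,
        var_logit_q = est$var_logit_q, status = est$status)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(admin1 = character(0), period = integer(0),
                      period_label = character(0), survey_id = character(0),
                      age_group = character(0), q = numeric(0),
                      logit_q = numeric(0), var_logit_q = numeric(0),
                      status = character(0))
  res <- res[order(res$admin1, res$period, res$survey_id), ]
  rownames(res) <- NULL
  attr(res, "grid") <- grid
  res
}
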