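#' Posterior coefficient of variation
#'
#' 100 times the posterior standard deviation divided by the posterior mean
#' of the probability of dying -- the Bayesian analogue of the survey
#' coefficient of variation used to screen unstable estimates. It is
#' invariant to rescaling the draws (per 1, per 1000, ...).
#'
#' @param q_draws numeric vector of posterior draws for one cell.
#' @return CV in percent.
#' @export
posterior_cv <- function(q_draws) {
  stopifnot(length(q_draws) >= 2)
  m <- mean(q_draws)
  if (m == 0) stop("posterior mean is zero; CV undefined")
  100 * stats::sd(q_draws) / m
}

#' Screen estimates by posterior CV and apply the period-retention rule
#'
#' Cells with CV greater than or equal to `threshold` percent (default 20,
#' the Hansen/Kish instability cutoff) are classified as not sufficiently
#' precise. A period is retained for the correlation analysis when at least
#' `retention_share` (default 0.75) of its areas are precise: with 3 areas
#' a single imprecise cell drops the period, with 5 areas one imprecise
#' cell is tolerated but two are not.
#'
#' @param fit a [fit_smoothing_model()] result (for the 5-14 age group in
#'   the primary workflow).
#' @param threshold CV cutoff in percent.
#' @param retention_share minimum fraction of precise areas per period.
#' @return Object of class `precision_report`: list with `cells`
#'   (data.frame: `admin1`, `period`, `period_label`, `cv_percent`,
#'   `precise`), `periods` (data.frame: `period`, `period_label`,
#'   `share_precise`, `retained`), `threshold`, `retention_share`.
#' @export
classify_and_retain <- function(fit, threshold = 20, retention_share = 0.75) {
  stopifnot(inherits(fit, "mort_fit"))
  cells <- list()
  for (i in seq_along(fit$areas)) for (t in seq_len(fit$T)) {
    cv <- posterior_cv(fit$q[, i, t])
    cells[[length(cells) + 1L]] <- data.frame(
      admin1 = fit$areas[i], period = t,
      period_label = fit$period_labels[t],
      cv_percent = cv, precise = cv < threshold)
  }
  cells <- do.call(rbind, cells)
  periods <- do.call(rbind, lapply(split(cells, cells$period), function(d)
    data.frame(period = d$period[1], period_label = d$period_label[1],
               share_precise = mean(d$precise),
               retained = mean(d$precise) >= retention_share)))
  rownames(cells) <- rownames(periods) <- NULL
  structure(list(cells = cells, periods = periods, threshold = threshold,
                 retention_share = retention_share),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report: %d/%d cells precise (CV < %g%%), %d/%d periods retained>\n",
              sum(x$cells$precise), nrow(x$cells), x$threshold,
              sum(x$periods$retained), nrow(x$periods)))
  invisible(x)
}
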