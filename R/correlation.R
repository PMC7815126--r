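#' Pearson correlation between the two age groups with credible intervals
#'
#' For every joint posterior draw s, computes the Pearson correlation of
#' the two age groups' probabilities across the selected (area, period)
#' cells; the draw-wise correlations {r_s} give a point estimate (their
#' median) and a 95% credible interval (2.5 / 97.5 percentiles) that
#' propagate the full posterior uncertainty of the sub-national estimates.
#' The `"pooled"` scope concatenates all retained cells; the
#' `"per-period"` scope computes one correlation per retained period
#' across areas, skipping (with a message) periods with fewer than 3 areas.
#'
#' @param fit_u5,fit_5to14 [fit_smoothing_model()] results for the two age
#'   groups on the same areas, periods and number of draws.
#' @param retained_periods integer vector of period indices to use
#'   (typically `periods$period[periods$retained]` from
#'   [classify_and_retain()]).
#' @param scope `"pooled"`, `"per-period"`, or `"both"`.
#' @return data.frame with columns `scope`, `period`, `period_label`
#'   (`"ALL"` for pooled), `r_point`, `ci_low`, `ci_high`, `n_points`,
#'   `crosses_zero`.
#' @export
pearson_with_ci <- function(fit_u5, fit_5to14, retained_periods,
                            scope = c("both", "pooled", "per-period")) {
  scope <- match.arg(scope)
  stopifnot(inherits(fit_u5, "mort_fit"), inherits(fit_5to14, "mort_fit"),
            identical(fit_u5$areas, fit_5to14$areas),
            dim(fit_u5$q)[1] == dim(fit_5to14$q)[1])
  retained_periods <- sort(unique(as.integer(retained_periods)))
  n <- length(fit_u5$areas)
  out <- list()
  summarize <- function(rs, scope_lab, period, label, npts) {
    qs <- stats::quantile(rs, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(scope = scope_lab, period = period, period_label = label,
               r_point = qs[2], ci_low = qs[1], ci_high = qs[3],
               n_points = npts, crosses_zero = qs[1] <= 0 & qs[3] >= 0)
  }
  drawwise_r <- function(idx_cells) {
    S <- dim(fit_u5$q)[1]
    x <- matrix(fit_u5$q, S)[, idx_cells, drop = FALSE]
    y <- matrix(fit_5to14$q, S)[, idx_cells, drop = FALSE]
    vapply(seq_len(S), function(s) stats::cor(x[s, ], y[s, ]), numeric(1))
  }
  cell_index <- function(periods) {
    idx <- as.matrix(expand.grid(i = seq_len(n), t = periods))
    (idx[, "t"] - 1L) * n + idx[, "i"]   # column index into S x (n*T) matrix
  }
  if (scope %in% c("both", "pooled")) {
    cells <- cell_index(retained_periods)
    if (length(cells) < 3) {
      message("pooled scope skipped: fewer than 3 cells")
    } else {
      out[[length(out) + 1L]] <- summarize(
        drawwise_r(cells), "pooled", NA_integer_, "ALL", length(cells))
    }
  }
  if (scope %in% c("both", "per-period")) {
    for (t in retained_periods) {
      if (n < 3) { message("period ", t, " skipped: fewer than 3 areas"); next }
      out[[length(out) + 1L]] <- summarize(
        drawwise_r(cell_index(t)), "per-period", t,
        fit_u5$period_labels[t], n)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(scope = character(0), period = integer(0),
                      period_label = character(0), r_point = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      n_points = integer(0), crosses_zero = logical(0))
  rownames(res) <- NULL
  res
}
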