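#' Share of total variance attributable to each model component
#'
#' Splits the variability of the fitted logit surface into the five random
#' components: RW2 time trend (gamma), ICAR space (phi), RW2 x ICAR
#' interaction (delta), iid time (alpha) and iid space (theta). Each
#' component's variance is the empirical variance of its posterior-mean
#' effect values over its own index set (time, space, or space x time);
#' shares are normalized to sum to 100. Empirical variances of the effect
#' vectors are used rather than the precision hyperparameters because
#' intrinsic (ICAR/RW2) precisions are not marginal variances. A component
#' with fewer than 2 index values has variance 0 by convention; adding a
#' constant to mu leaves all shares unchanged.
#'
#' @param fit a [fit_smoothing_model()] result.
#' @return Object of class `variance_shares`: named numeric vector of
#'   percentages (`RW2`, `ICAR`, `RW2xICAR`, `Time`, `Space`) with the
#'   age group as attribute.
#' @export
component_variance_shares <- function(fit) {
  stopifnot(inherits(fit, "mort_fit"))
  v_of <- function(x) if (length(x) < 2) 0 else stats::var(as.numeric(x))
  vars <- c(
    RW2      = v_of(colMeans(fit$gamma)),
    ICAR     = v_of(colMeans(fit$phi)),
    RW2xICAR = v_of(apply(fit$delta, c(2, 3), mean)),
    Time     = v_of(colMeans(fit$alpha)),
    Space    = v_of(colMeans(fit$theta)))
  if (sum(vars) == 0) stop("all components degenerate; no variance to split")
  structure(100 * vars / sum(vars), age_group = fit$age_group,
            class = "variance_shares")
}

#' @export
print.variance_shares <- function(x, ...) {
  cat("Share (%) of total variance from model components\n")
  print(round(unclass(x), 2))
  invisible(x)
}
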