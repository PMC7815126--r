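#' Sampler settings and hyperpriors for the smoothing model
#'
#' Precisions (inverse variances) of the five random components get
#' Gamma(a, b) hyperpriors. The defaults a = 0.5, b = 0.00149 are a common
#' weakly-informative choice in the smoothed-direct-estimates literature
#' (roughly: prior median marginal sd around 0.05 with a long right tail);
#' both are configurable. Inference is by a conjugate Gibbs sampler -- the
#' model is Gaussian given the variances, so every full conditional is a
#' (constrained) Gaussian or a Gamma. `fix_hyper` pins the component
#' variances instead of sampling them, which makes the posterior exactly
#' Gaussian; this is used by the calibration and closed-form oracle tests.
#'
#' @param a,b Gamma hyperprior shape and rate for every precision.
#' @param chains number of independent chains.
#' @param warmup burn-in iterations per chain.
#' @param draws kept iterations per chain.
#' @param seed integer seed.
#' @param fix_hyper optional named list of fixed variances
#'   (`sigma2_alpha`, `sigma2_gamma`, `sigma2_theta`, `sigma2_phi`,
#'   `sigma2_delta`).
#' @param scale_structure if `TRUE`, rescale the ICAR/RW2/interaction
#'   structure matrices to unit average marginal variance (generalized
#'   variance scaling) so one hyperprior is comparable across components;
#'   default `FALSE` (plain unscaled intrinsic priors).
#' @return An object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(a = 0.5, b = 0.00149, chains = 4L, warmup = 1000L,
                           draws = 1000L, seed = 1L, fix_hyper = NULL,
                           scale_structure = FALSE) {
  stopifnot(a > 0, b > 0, draws >= 1, warmup >= 0, chains >= 1)
  structure(list(a = a, b = b, chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), fix_hyper = fix_hyper,
                 scale_structure = isTRUE(scale_structure)),
            class = "smoothing_spec")
}

## draw from N(Q^{-1} b, Q^{-1}) subject to A x = 0 (conditioning by kriging);
## a tiny ridge is added only if the Cholesky factorization fails.
sample_constrained_gmrf <- function(Q, b, A = NULL) {
  L <- tryCatch(chol(Q), error = function(e) {
    chol(Q + diag(1e-8 * max(diag(Q)), nrow(Q)))
  })
  m <- backsolve(L, backsolve(L, b, transpose = TRUE))
  x <- m + backsolve(L, rnorm(length(b)))
  if (!is.null(A)) {
    V <- backsolve(L, backsolve(L, t(A), transpose = TRUE))
    W <- A %*% V
    W <- (W + t(W)) / 2
    corr <- tryCatch(solve(W, A %*% x), error = function(e) {
      ## W can be numerically singular when the structured precision
      ## dominates; fall back to the eigen pseudo-inverse
      eg <- eigen(W, symmetric = TRUE)
      keep <- eg$values > 1e-12 * max(eg$values)
      eg$vectors[, keep, drop = FALSE] %*%
        ((t(eg$vectors[, keep, drop = FALSE]) %*% (A %*% x)) / eg$values[keep])
    })
    x <- x - V %*% corr
  }
  drop(x)
}

#' Fit the Bayesian space-time smoothing model
#'
#' Treats the pooled logit-scale direct estimates as Gaussian observations
#' with known variances of a latent surface
#' \deqn{\lambda_{it} = \mu + \alpha_t + \gamma_t + \theta_i + \phi_i + \delta_{it}}
#' with a flat prior on mu, iid normal alpha (time) and theta (space), an
#' RW2 prior on gamma, an ICAR prior on phi, a type IV (RW2 x ICAR)
#' interaction delta, and Gamma hyperpriors on all five precisions.
#' Identifiability: gamma sums to zero (its linear trend is retained), phi
#' sums to zero within each connected component, delta satisfies the full
#' interaction constraint set; isolated areas (degree zero) contribute no
#' ICAR penalty and keep phi = 0. Missing cells contribute no likelihood
#' term but receive lambda draws from the structure. Split-Rhat over the
#' lambda cells is reported; values above 1.05 trigger a warning and set
#' the `converged` flag to `FALSE`.
#'
#' @param pooled data.frame from [pool_direct()] (one age group): needs
#'   `admin1`, `period`, `logit_q`, `var_logit_q`, `status`.
#' @param graph an [adjacency_graph()] whose nodes cover the areas.
#' @param spec a [smoothing_spec()].
#' @param T_ number of periods (default: the largest period index present).
#' @return Object of class `mort_fit` with elements `lambda` (S x n x T
#'   array), `q` (expit of lambda), component draws (`mu`, `alpha`, `gamma`,
#'   `theta`, `phi`, `delta`), `hyper` (S x 5 matrix of variances), `rhat`,
#'   `converged`, `areas`, `T`, `age_group`, `graph`, `period_labels`.
#' @export
fit_smoothing_model <- function(pooled, graph, spec = smoothing_spec(),
                                T_ = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"), inherits(spec, "smoothing_spec"))
  ok <- pooled$status == "ok" & is.finite(pooled$logit_q) &
    is.finite(pooled$var_logit_q) & pooled$var_logit_q > 0
  if (!any(ok)) stop("no non-missing cells to fit")
  if (is.null(T_)) T_ <- max(pooled$period)
  T_ <- as.integer(T_)
  if (T_ < 3) stop("need at least 3 periods for the RW2 prior")
  n <- graph$n
  ia <- match(pooled$admin1, graph$nodes)
  if (anyNA(ia)) stop("areas in `pooled` missing from the graph")
  y <- matrix(NA_real_, n, T_); wmat <- matrix(0, n, T_)
  y[cbind(ia[ok], pooled$period[ok])] <- pooled$logit_q[ok]
  wmat[cbind(ia[ok], pooled$period[ok])] <- 1 / pooled$var_logit_q[ok]
  y0 <- ifelse(wmat > 0, y, 0)

  comp <- graph$component
  isolated <- tabulate(c(graph$edges), n) == 0L
  Qs <- build_icar_precision(graph)
  Qt <- build_rw2_precision(T_)
  if (spec$scale_structure) {
    Qt <- Qt * mean_pinv_diag(Qt)
    Qs <- Qs * mean_pinv_diag(Qs)
  }
  inter <- build_interaction_precision(Qt, Qs, component = comp)
  A_gamma <- matrix(1, 1, T_)
  A_phi <- t(sapply(seq_len(max(comp)), function(cc) as.numeric(comp == cc)))
  ## isolated areas carry no ICAR information; keep their phi pinned at 0
  if (any(isolated))
    A_phi <- rbind(A_phi, diag(n)[isolated, , drop = FALSE])
  A_phi <- A_phi[qr(t(A_phi))$pivot[seq_len(qr(t(A_phi))$rank)], , drop = FALSE]

  rank_g <- T_ - 2L
  rank_p <- n - max(comp) - sum(isolated)
  rank_d <- inter$n * inter$T - nrow(inter$constraints)
  a <- spec$a; b <- spec$b
  fixed <- !is.null(spec$fix_hyper)
  if (fixed) {
    fh <- spec$fix_hyper
    s2 <- c(alpha = fh$sigma2_alpha, gamma = fh$sigma2_gamma,
            theta = fh$sigma2_theta, phi = fh$sigma2_phi,
            delta = fh$sigma2_delta)
  }

  S <- spec$chains * spec$draws
  lam_d <- array(NA_real_, c(S, n, T_))
  del_d <- array(NA_real_, c(S, n, T_))
  alp_d <- matrix(NA_real_, S, T_); gam_d <- matrix(NA_real_, S, T_)
  the_d <- matrix(NA_real_, S, n); phi_d <- matrix(NA_real_, S, n)
  mu_d <- numeric(S)
  hyp_d <- matrix(NA_real_, S, 5,
                  dimnames = list(NULL, c("sigma2_alpha", "sigma2_gamma",
                                          "sigma2_theta", "sigma2_phi",
                                          "sigma2_delta")))
  chain_id <- rep(seq_len(spec$chains), each = spec$draws)
  wt <- colSums(wmat); wi <- rowSums(wmat)
  wvec <- as.numeric(wmat)

  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + 1000L * (ch - 1L))
    mu <- sum(wmat * y0) / sum(wmat)
    alpha <- numeric(T_); gamma <- numeric(T_)
    theta <- numeric(n); phi <- numeric(n)
    delta <- matrix(0, n, T_)
    if (!fixed)
      s2 <- c(alpha = 0.01, gamma = 0.01, theta = 0.01, phi = 0.01,
              delta = 0.01)
    keep0 <- (ch - 1L) * spec$draws
    for (it in seq_len(spec$warmup + spec$draws)) {
      ## mu | rest (flat prior)
      r <- y0 - (outer(theta + phi, alpha + gamma, "+") + delta)
      mu <- rnorm(1, sum(wmat * r) / sum(wmat), sqrt(1 / sum(wmat)))
      ## alpha | rest (iid)
      r <- y0 - mu - outer(theta + phi, gamma, "+") - delta
      bt <- colSums(wmat * r)
      prec <- wt + 1 / s2["alpha"]
      alpha <- rnorm(T_, bt / prec, sqrt(1 / prec))
      ## gamma | rest (RW2, sum-to-zero)
      r <- y0 - mu - outer(theta + phi, alpha, "+") - delta
      bt <- colSums(wmat * r)
      gamma <- sample_constrained_gmrf(Qt / s2["gamma"] + diag(wt, T_), bt,
                                       A_gamma)
      ## theta | rest (iid)
      r <- y0 - mu - outer(phi, alpha + gamma, "+") - delta
      bi <- rowSums(wmat * r)
      prec <- wi + 1 / s2["theta"]
      theta <- rnorm(n, bi / prec, sqrt(1 / prec))
      ## phi | rest (ICAR, per-component sum-to-zero)
      r <- y0 - mu - outer(theta, alpha + gamma, "+") - delta
      bi <- rowSums(wmat * r)
      phi <- sample_constrained_gmrf(Qs / s2["phi"] + diag(wi, n), bi, A_phi)
      ## delta | rest (type IV)
      r <- y0 - mu - outer(theta + phi, alpha + gamma, "+")
      bv <- wvec * as.numeric(r)
      delta <- matrix(sample_constrained_gmrf(
        inter$Q / s2["delta"] + diag(wvec, n * T_), bv, inter$constraints),
        n, T_)
      ## variances | components (conjugate Gamma on precisions)
      if (!fixed) {
        s2["alpha"] <- 1 / rgamma(1, a + T_ / 2, b + sum(alpha^2) / 2)
        s2["theta"] <- 1 / rgamma(1, a + n / 2, b + sum(theta^2) / 2)
        s2["gamma"] <- 1 / rgamma(1, a + rank_g / 2,
                                  b + drop(t(gamma) %*% Qt %*% gamma) / 2)
        s2["phi"] <- 1 / rgamma(1, a + rank_p / 2,
                                b + drop(t(phi) %*% Qs %*% phi) / 2)
        dv <- as.numeric(delta)
        s2["delta"] <- 1 / rgamma(1, a + rank_d / 2,
                                  b + drop(t(dv) %*% inter$Q %*% dv) / 2)
      }
      if (it > spec$warmup) {
        k <- keep0 + it - spec$warmup
        lam_d[k, , ] <- mu + outer(theta + phi, alpha + gamma, "+") + delta
        del_d[k, , ] <- delta
        alp_d[k, ] <- alpha; gam_d[k, ] <- gamma
        the_d[k, ] <- theta; phi_d[k, ] <- phi
        mu_d[k] <- mu; hyp_d[k, ] <- s2
      }
    }
  }
  rhat <- apply(lam_d, c(2, 3), split_rhat, chain_id = chain_id)
  converged <- all(is.na(rhat) | rhat < 1.05)
  if (!converged)
    warning(sprintf("max split-Rhat = %.3f (> 1.05); inspect convergence",
                    max(rhat, na.rm = TRUE)))
  structure(list(lambda = lam_d, q = expit(lam_d), mu = mu_d, alpha = alp_d,
                 gamma = gam_d, theta = the_d, phi = phi_d, delta = del_d,
                 hyper = hyp_d, rhat = rhat, converged = converged,
                 areas = graph$nodes, T = T_, graph = graph,
                 age_group = if ("age_group" %in% names(pooled))
                   pooled$age_group[1] else NA_character_,
                 period_labels = if ("period_label" %in% names(pooled))
                   vapply(seq_len(T_), function(t) {
                     l <- pooled$period_label[pooled$period == t]
                     if (length(l)) l[1] else paste0("T", t)
                   }, character(1)) else paste0("T", seq_len(T_)),
                 chain_id = chain_id),
            class = "mort_fit")
}

## split-half Rhat across chains for one scalar's draws
split_rhat <- function(x, chain_id) {
  halves <- split(x, paste(chain_id, ave(seq_along(x), chain_id,
                                         FUN = function(i) i > mean(i))))
  m <- length(halves); nn <- min(lengths(halves))
  if (nn < 2) return(NA_real_)
  mat <- sapply(halves, function(h) h[seq_len(nn)])
  B <- nn * stats::var(colMeans(mat))
  W <- mean(apply(mat, 2, stats::var))
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' @export
print.mort_fit <- function(x, ...) {
  cat(sprintf("<mort_fit: %d draws, %d areas x %d periods, max Rhat %.3f>\n",
              dim(x$lambda)[1], length(x$areas), x$T,
              suppressWarnings(max(x$rhat, na.rm = TRUE))))
  invisible(x)
}

#' Posterior summaries of the smoothed probabilities
#'
#' @param fit a [fit_smoothing_model()] result.
#' @param quantiles probabilities for posterior quantiles of q.
#' @return data.frame: `admin1`, `period`, `period_label`, `mean`, `median`
#'   and one `q<p>` column per requested quantile.
#' @export
posterior_summaries <- function(fit, quantiles = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fit, "mort_fit"), dim(fit$q)[1] >= 2)
  out <- list()
  for (i in seq_along(fit$areas)) for (t in seq_len(fit$T)) {
    dr <- fit$q[, i, t]
    qs <- stats::quantile(dr, quantiles, names = FALSE)
    row <- data.frame(admin1 = fit$areas[i], period = t,
                      period_label = fit$period_labels[t],
                      mean = mean(dr), median = stats::median(dr))
    for (k in seq_along(quantiles))
      row[[paste0("q", format(quantiles[k], trim = TRUE))]] <- qs[k]
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
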