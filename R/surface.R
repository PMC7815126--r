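#' Sample a true mortality surface from the space-time model's priors
#'
#' Generates the latent logit surface lambda_it = mu + alpha_t + gamma_t +
#' theta_i + phi_i + delta_it used both as the generative truth for the
#' synthetic-data module and as the smoothing model's prior. alpha and theta
#' are iid normal; gamma is an RW2 draw constrained orthogonal to the
#' constant and linear sequences; phi is an ICAR draw with per-component
#' sum-to-zero; delta is an RW2 (x) ICAR (type IV) draw satisfying the full
#' constraint set. Intrinsic components are sampled spectrally: coordinates
#' on the positive-eigenvalue eigenvectors of the structure matrix, variance
#' sigma^2 / eigenvalue, which imposes orthogonality to the null space (and
#' hence the sum-to-zero constraints) exactly.
#'
#' @param graph an [adjacency_graph()].
#' @param T_ number of periods (>= 3).
#' @param hyper named list/vector of component variances
#'   `sigma2_alpha`, `sigma2_gamma`, `sigma2_theta`, `sigma2_phi`,
#'   `sigma2_delta` (each >= 0; 0 gives an all-zero component).
#' @param mu overall level on the logit scale.
#' @param seed integer seed.
#' @param scale_structure if `TRUE`, the intrinsic structure matrices are
#'   rescaled so that the average marginal variance of each constrained
#'   prior equals its sigma^2, making variance parameters directly
#'   comparable across components (unscaled intrinsic priors have marginal
#'   variances that depend strongly on T and the graph). Default `FALSE`.
#' @return Object of class `true_surface`: list with `mu`, `alpha`, `gamma`
#'   (length T), `theta`, `phi` (length n), `delta` (n x T), `lambda`
#'   (n x T, rows = areas), `graph`, `T`.
#' @export
sample_true_surface <- function(graph, T_, hyper, mu = -3, seed = 1L,
                                scale_structure = FALSE) {
  stopifnot(inherits(graph, "adjacency_graph"), T_ >= 3)
  h <- as.list(hyper)
  need <- c("sigma2_alpha", "sigma2_gamma", "sigma2_theta", "sigma2_phi",
            "sigma2_delta")
  if (!all(need %in% names(h))) stop("`hyper` must name: ", paste(need, collapse = ", "))
  if (any(unlist(h[need]) < 0)) stop("variances must be >= 0")
  if (max(graph$component) > 1L)
    warning("adjacency graph is disconnected; ICAR constraints applied per component")
  set.seed(seed)
  n <- graph$n
  T_ <- as.integer(T_)
  alpha <- if (h$sigma2_alpha > 0) rnorm(T_, 0, sqrt(h$sigma2_alpha)) else numeric(T_)
  theta <- if (h$sigma2_theta > 0) rnorm(n, 0, sqrt(h$sigma2_theta)) else numeric(n)
  Qg <- build_rw2_precision(T_)
  Qs <- build_icar_precision(graph)
  if (scale_structure) {
    Qg <- Qg * mean_pinv_diag(Qg)
    Qs <- Qs * mean_pinv_diag(Qs)
  }
  gamma <- sample_intrinsic(Qg, h$sigma2_gamma)
  phi   <- sample_intrinsic(Qs, h$sigma2_phi)
  delta <- matrix(sample_intrinsic_kron(Qg, Qs, h$sigma2_delta), n, T_)
  lambda <- mu + outer(theta + phi, alpha + gamma, "+") + delta
  structure(list(mu = mu, alpha = alpha, gamma = gamma, theta = theta,
                 phi = phi, delta = delta, lambda = lambda,
                 graph = graph, T = T_),
            class = "true_surface")
}

## average marginal variance of the constrained intrinsic prior at sigma^2=1:
## mean of the diagonal of the Moore-Penrose inverse of Q
mean_pinv_diag <- function(Q, tol = 1e-9) {
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev > tol * max(ev)
  sum(1 / ev[pos]) / nrow(Q)
}

## spectral draw from an intrinsic GMRF: x = sum_k e_k z_k * sqrt(s2/l_k)
sample_intrinsic <- function(Q, s2, tol = 1e-9) {
  m <- nrow(Q)
  if (s2 == 0) return(numeric(m))
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values)
  z <- rnorm(sum(pos))
  drop(eg$vectors[, pos, drop = FALSE] %*% (z * sqrt(s2 / eg$values[pos])))
}

## Kronecker intrinsic draw using the factor eigendecompositions:
## eigenvalues of Qt (x) Qs are products, eigenvectors u_k (x) v_l.
sample_intrinsic_kron <- function(Q_time, Q_space, s2, tol = 1e-9) {
  T_ <- nrow(Q_time); n <- nrow(Q_space)
  if (s2 == 0) return(numeric(n * T_))
  et <- eigen(Q_time, symmetric = TRUE)
  es <- eigen(Q_space, symmetric = TRUE)
  pt <- et$values > tol * max(et$values)
  ps <- es$values > tol * max(es$values)
  ## coefficient matrix C[l,k] ~ N(0, s2/(lt_k * ls_l)); delta = Vs C Vt'
  C <- matrix(0, n, T_)
  sdm <- sqrt(s2 / outer(es$values[ps], et$values[pt]))
  C[seq_len(sum(ps)), seq_len(sum(pt))] <- rnorm(sum(ps) * sum(pt)) * sdm
  D <- es$vectors[, ps, drop = FALSE] %*%
    (C[seq_len(sum(ps)), seq_len(sum(pt)), drop = FALSE] %*%
       t(et$vectors[, pt, drop = FALSE]))
  as.numeric(D)
}

#' @export
print.true_surface <- function(x, ...) {
  cat(sprintf("<true_surface: %d areas x %d periods, mu = %.3f>\n",
              nrow(x$lambda), x$T, x$mu))
  invisible(x)
}

#' Sample a linked pair of surfaces for the two age groups
#'
#' The two age-group surfaces are generated independently by default (the
#' analysis models them independently). For testing the cross-age-group
#' correlation machinery, `shared_icar_sd > 0` adds one common ICAR field
#' (scaled to the given marginal-ish sd) to both surfaces, creating genuine
#' within-period spatial correlation between the age groups.
#'
#' @param graph,T_ as in [sample_true_surface()].
#' @param hyper_u5,hyper_5to14 per-age-group variance lists.
#' @param mu_u5,mu_5to14 logit levels (defaults correspond to 5q0 ~ 0.08 and
#'   10q5 ~ 0.02, typical sub-Saharan magnitudes).
#' @param shared_icar_sd sd of a common spatial field added to both surfaces.
#' @param seed integer seed.
#' @return list with elements `u5` and `5to14`, each a `true_surface`.
#' @export
sample_surface_pair <- function(graph, T_, hyper_u5, hyper_5to14,
                                mu_u5 = logit(0.08), mu_5to14 = logit(0.02),
                                shared_icar_sd = 0, seed = 1L) {
  s1 <- sample_true_surface(graph, T_, hyper_u5, mu = mu_u5, seed = seed)
  s2 <- sample_true_surface(graph, T_, hyper_5to14, mu = mu_5to14,
                            seed = seed + 1000L)
  if (shared_icar_sd > 0) {
    set.seed(seed + 2000L)
    common <- sample_intrinsic(build_icar_precision(graph), shared_icar_sd^2)
    s1$phi <- s1$phi + common
    s2$phi <- s2$phi + common
    s1$lambda <- s1$lambda + common
    s2$lambda <- s2$lambda + common
  }
  out <- list(s1, s2)
  names(out) <- c("u5", "5to14")
  out
}
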