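# Minimal hand-built `mort_fit` objects for testing downstream modules
# without running the sampler.
make_fit <- function(lambda, alpha = NULL, gamma = NULL, theta = NULL,
                     phi = NULL, delta = NULL, mu = NULL,
                     age_group = "5to14") {
  S <- dim(lambda)[1]; n <- dim(lambda)[2]; T_ <- dim(lambda)[3]
  zS <- function(k) matrix(0, S, k)
  structure(list(
    lambda = lambda, q = expit(lambda),
    mu = mu %||% rep(0, S),
    alpha = alpha %||% zS(T_), gamma = gamma %||% zS(T_),
    theta = theta %||% zS(n), phi = phi %||% zS(n),
    delta = delta %||% array(0, c(S, n, T_)),
    hyper = matrix(NA_real_, S, 5), rhat = matrix(NA_real_, n, T_),
    converged = TRUE, areas = paste0("A", seq_len(n)), T = T_,
    graph = NULL, age_group = age_group,
    period_labels = paste0("T", seq_len(T_)), chain_id = rep(1L, S)),
    class = "mort_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draws with an exact target mean and sd in one cell
draws_with_cv <- function(S, mean, cv_percent) {
  x <- scale(rnorm(S))            # exact mean 0, sd 1
  mean * (1 + x * cv_percent / 100)
}
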