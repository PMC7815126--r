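#' Structure matrices for the intrinsic Gaussian Markov random field priors
#'
#' The smoothing model combines an ICAR prior over areas, a second-order
#' random walk over periods, and their Kronecker-product interaction
#' (Knorr-Held type IV). These builders return the unscaled structure
#' matrices Q; a component with variance sigma^2 has improper density
#' proportional to exp(-x' Q x / (2 sigma^2)).
#'
#' @name structure-matrices
NULL

#' ICAR structure matrix
#'
#' Q = D - A, the graph Laplacian: degree on the diagonal, minus one for each
#' neighbour pair. Row sums are zero; the rank is n minus the number of
#' connected components, with the null space spanned by the per-component
#' indicator vectors (hence the per-component sum-to-zero constraints).
#'
#' @param g an [adjacency_graph()] with at least 2 nodes.
#' @return n x n symmetric matrix.
#' @export
build_icar_precision <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"), g$n >= 2)
  A <- adjacency_matrix(g)
  diag(rowSums(A)) - A
}

#' RW2 structure matrix
#'
#' Q = D2' D2 where D2 is the (T-2) x T second-difference operator. The rank
#' is T - 2; the null space is spanned by the constant and the linear
#' sequence, so an RW2 prior leaves level and trend unpenalised.
#'
#' @param T_ number of periods (>= 3).
#' @return T x T symmetric matrix.
#' @export
build_rw2_precision <- function(T_) {
  if (!is.numeric(T_) || length(T_) != 1 || T_ < 3)
    stop("`T_` must be a single integer >= 3")
  T_ <- as.integer(T_)
  D2 <- matrix(0, T_ - 2L, T_)
  for (k in seq_len(T_ - 2L)) D2[k, k + 0:2] <- c(1, -2, 1)
  crossprod(D2)
}

#' Type IV space-time interaction structure
#'
#' The Knorr-Held type IV interaction assumes that the structured temporal
#' and spatial effects interact: its structure matrix is the Kronecker
#' product Q_time (x) Q_space, acting on vec of the n x T effect matrix
#' (areas varying fastest). The rank is (T-2) * (n-c) for c connected
#' components; the emitted constraint matrix spans the null space -- each
#' area's time-series must be orthogonal to both the constant and the linear
#' sequence (the RW2 null space), and each period's spatial field must sum
#' to zero within every connected component.
#'
#' @param Q_time RW2 structure matrix (T x T) from [build_rw2_precision()].
#' @param Q_space ICAR structure matrix (n x n) from [build_icar_precision()].
#' @param component optional integer component membership (length n); default
#'   assumes a connected graph.
#' @return list with `Q` (nT x nT), `constraints` (matrix A with independent
#'   rows such that A vec(delta) = 0), `n`, `T`.
#' @export
build_interaction_precision <- function(Q_time, Q_space, component = NULL) {
  T_ <- nrow(Q_time); n <- nrow(Q_space)
  if (is.null(component)) component <- rep(1L, n)
  Q <- kronecker(Q_time, Q_space)
  ## constraints: for each area, sum_t delta_it = 0 and sum_t t*delta_it = 0;
  ## for each (period, component), sum_i delta_it = 0. Redundant rows dropped.
  A <- matrix(0, 2L * n + T_ * max(component), n * T_)
  r <- 0L
  tt <- seq_len(T_)
  for (i in seq_len(n)) {
    r <- r + 1L; A[r, i + (tt - 1L) * n] <- 1
    r <- r + 1L; A[r, i + (tt - 1L) * n] <- tt
  }
  for (cc in seq_len(max(component))) {
    idx_i <- which(component == cc)
    for (t in tt) { r <- r + 1L; A[r, idx_i + (t - 1L) * n] <- 1 }
  }
  qrA <- qr(t(A))
  A <- A[qrA$pivot[seq_len(qrA$rank)], , drop = FALSE]
  list(Q = Q, constraints = A, n = n, T = T_)
}
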