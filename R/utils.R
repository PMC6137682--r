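# Numerical utilities shared across modules.

# Clip bound for probit arguments: |a| <= 8 keeps Phi within [1e-16, 1-1e-16]
# so log-likelihoods stay finite; the induced probability error is < 1e-15.
PROBIT_CLIP <- 8

clip_probit <- function(a) pmin(pmax(a, -PROBIT_CLIP), PROBIT_CLIP)

#' Gauss-Hermite quadrature for a standard normal weight
#'
#' Computes an \code{n}-point rule such that
#' \eqn{\int g(x)\,\phi(x)\,dx \approx \sum_q w_q g(x_q)} where \eqn{\phi}
#' is the standard normal density.  Nodes and weights are obtained by the
#' Golub-Welsch algorithm (eigendecomposition of the Jacobi matrix of the
#' Hermite polynomials) and rescaled from the physicists' to the
#' probabilists' convention.
#'
#' @param n number of nodes (positive integer).
#' @return list with \code{nodes} and \code{weights}, both length \code{n};
#'   weights sum to 1.
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord] * sqrt(2)          # physicists' -> N(0,1) scale
  weights <- (e$vectors[1, ord])^2          # already sum to 1
  list(nodes = nodes, weights = weights)
}

#' Derive deterministic sub-seeds from a root seed
#'
#' A single root seed deterministically spawns per-module substreams so that
#' permutation and posterior-predictive loops are reproducible independently
#' of execution order.  Uses a Lehmer-style integer recurrence carried out in
#' exact double arithmetic; all returned seeds lie in \code{[1, 2^31 - 2]}.
#'
#' @param root integer root seed.
#' @param n number of sub-seeds.
#' @return integer vector of length \code{n}.
#' @export
spawn_seeds <- function(root, n) {
  stopifnot(length(root) == 1, is.finite(root), n >= 1)
  m <- 2147483647   # 2^31 - 1, prime
  s <- (abs(as.double(root)) %% (m - 1)) + 1
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- (s * 48271) %% m
    # decorrelate neighbouring roots with a second multiplicative pass
    out[k] <- (s * 69621) %% m
  }
  as.integer(pmax(out, 1))
}

# One multivariate normal draw per row: mean matrix (n x d) + chol(Sigma).
rmvn <- function(n, mean, Sigma) {
  d <- ncol(Sigma)
  L <- chol(Sigma)
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% L, 2, rep(0, d), "+") + mean
}

# Inverse-Wishart draw via rWishart on the inverted scale matrix.
riwish <- function(df, S) {
  W <- rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

# fast row maxima (max.col runs in C)
rowMaxs_fast <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

# log of Phi with clipping, elementwise
log_phi_clip <- function(a) pnorm(clip_probit(a), log.p = TRUE)

# log Psi(a, x) = x log Phi(a) + (1-x) log(1 - Phi(a)), clipped
log_psi <- function(a, x) {
  a <- clip_probit(a)
  x * pnorm(a, log.p = TRUE) + (1 - x) * pnorm(a, lower.tail = FALSE, log.p = TRUE)
}

#' Bernoulli kernel of the probit likelihood
#'
#' \eqn{\Psi(a, x) = \Phi(a)^x (1-\Phi(a))^{1-x}}.  Satisfies
#' \eqn{\Psi(a,1)+\Psi(a,0)=1} for all finite \code{a}.
#'
#' @param a probit argument (any numeric array).
#' @param x response in \{0,1\} (same shape or scalar).
#' @return numeric of the common shape.
#' @export
psi_prob <- function(a, x) exp(log_psi(a, x))
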