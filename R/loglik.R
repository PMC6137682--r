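# Marginal -2 log-likelihood at posterior means and the modified BIC.

#' Marginal -2 log-likelihood of a joint model
#'
#' \deqn{-2\sum_p \ln \iint \prod_i f(x_{pi}, t_{pi} \mid \theta, \tau)\,
#' N_2((\theta,\tau); 0, \Sigma_P)\, d\theta\, d\tau,}
#' evaluated by two-dimensional Gauss-Hermite quadrature (default 31 nodes
#' per dimension, rotated through the Cholesky factor of \eqn{\Sigma_P}).
#' Intended to be called at the posterior means of the parameters, giving
#' the "modified" likelihood used by \code{\link{modified_bic}}.
#'
#' @param data an \code{\link{rtc_dataset}}.
#' @param model model kind.
#' @param params list with \code{alpha}, \code{beta} (K x B), \code{xi},
#'   \code{sigma}, \code{Sigma_P} (e.g. \code{\link{posterior_mean_params}}).
#' @param thresholds,baseline multicat settings.
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @return scalar, minus twice the marginal log-likelihood.
#' @export
minus2_loglik <- function(data, model, params,
                          thresholds = c(-1.5, -0.5, 0.5, 1.5),
                          baseline = NULL, n_nodes = 31) {
  stopifnot(inherits(data, "rtc_dataset"))
  model <- match.arg(model, MODEL_KINDS)
  M <- length(thresholds) + 1L
  if (model == "multicat" && is.null(baseline)) baseline <- (M + 1L) %/% 2L
  X <- data$X; lnT <- log(data$T)
  N <- data$N; K <- data$K
  gh <- gauss_hermite(n_nodes)
  U <- chol(params$Sigma_P)
  # all node pairs: rows of sqrt-rotated grid
  g1 <- rep(gh$nodes, times = n_nodes)
  g2 <- rep(gh$nodes, each = n_nodes)
  pts <- cbind(g1, g2) %*% U            # (theta, tau) node pairs
  lw <- log(rep(gh$weights, times = n_nodes)) +
    log(rep(gh$weights, each = n_nodes))
  acc <- matrix(-Inf, N, 1)
  lsum <- rep(-Inf, N)
  jac <- -rowSums(lnT)                  # t -> ln t Jacobian, constant
  for (q in seq_len(nrow(pts))) {
    th <- pts[q, 1]; ta <- pts[q, 2]
    z <- (lnT - outer(rep(-ta, N), params$xi, "+")) /
      rep(params$sigma, each = N)
    eta <- eta_matrix(z, rep(th, N), params$alpha, params$beta, model,
                      thresholds, baseline)
    ll <- rowSums(log_psi(eta, X)) +
      rowSums(dnorm(lnT, mean = outer(rep(-ta, N), params$xi, "+"),
                    sd = rep(params$sigma, each = N), log = TRUE))
    v <- lw[q] + ll
    mx <- pmax(lsum, v)
    lsum <- mx + log(exp(lsum - mx) + exp(v - mx))
  }
  if (any(!is.finite(lsum))) stop("quadrature produced non-finite values", call. = FALSE)
  -2 * sum(lsum + jac)
}

#' Number of conditional-dependence model parameters
#'
#' Counts the per-item parameter vectors that enter the item-side normal
#' distribution (alpha coefficients, beta coefficients, time intensity),
#' i.e. \code{(2B+1) * K}: 3K for conditional independence, 5K linear,
#' 7K quadratic, (2M+1)K for the multiple-category model.  Increments over
#' the conditional independence model are therefore 2K, 4K and 2(M-1)K.
#' Residual SDs and hyper-parameters are excluded, matching the convention
#' in which only the dependence structure is penalized incrementally.
#'
#' @param model model kind; @param K item count; @param M category count.
#' @return integer parameter count.
#' @export
count_params <- function(model, K, M = 5L) {
  model <- match.arg(model, MODEL_KINDS)
  (2L * model_basis_dim(model, M) + 1L) * as.integer(K)
}

#' Modified Bayesian information criterion
#'
#' \code{m2ll + n_params * log(n_persons)} where \code{m2ll} is the
#' marginal -2 log-likelihood evaluated at the posterior means of the
#' parameters (rather than at maximum-likelihood estimates).  The penalty
#' uses the number of persons; pass \code{n_persons = N * K} if an
#' observation-level penalty is preferred.
#'
#' @param m2ll minus twice the log-likelihood.
#' @param n_params parameter count (> 0).
#' @param n_persons sample size for the penalty (> 1).
#' @return scalar criterion value.
#' @export
modified_bic <- function(m2ll, n_params, n_persons) {
  stopifnot(n_params > 0, n_persons > 1)
  m2ll + n_params * log(n_persons)
}
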