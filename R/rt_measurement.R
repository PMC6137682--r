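# Marginal log-normal response-time measurement model:
#   ln t_pi = xi_i - tau_p + eps_pi,  tau ~ N(0, v),  eps_pi ~ N(0, sigma_i^2)
# i.e. a one-factor model with all loadings equal (here fixed to -1 on tau),
# whose implied covariance of ln T is compound symmetric:
#   Cov(ln t_i, ln t_j) = v + sigma_i^2 1[i = j].

#' Fit the marginal log-normal response-time model
#'
#' Marginal maximum likelihood under the equal-loadings one-factor
#' structure.  The per-item means are saturated, so \eqn{\hat\xi_i} are the
#' column means of \eqn{\ln T} exactly; the variance components
#' (\eqn{Var(\tau)}, \eqn{\sigma_i^2}) are estimated by an EM iteration that
#' treats the speed factor as missing data (monotone in the marginal
#' likelihood).  Predicted speeds \eqn{\hat\tau_p} are regression-method
#' factor scores (posterior means of \eqn{\tau} given the person's log-time
#' row), which average exactly to zero.
#'
#' @param T N x K matrix of positive response times, N >= 10, K >= 3.
#' @param tol convergence tolerance on the change in variance components.
#' @param max_iter maximum EM iterations.
#' @return object of class \code{rtc_rtfit}: \code{xi_hat}, \code{sigma_hat},
#'   \code{var_tau_hat}, \code{tau_hat}, \code{logLik}, \code{n_iter}.
#' @export
fit_lognormal_rt <- function(T, tol = 1e-8, max_iter = 500) {
  T <- as.matrix(T)
  N <- nrow(T); K <- ncol(T)
  if (K < 3) stop("at least 3 items are required to identify the factor structure",
                  call. = FALSE)
  if (N < 10) stop("at least 10 persons are required", call. = FALSE)
  if (any(T <= 0)) stop("response times must be strictly positive", call. = FALSE)
  Y <- log(T)
  sdc <- apply(Y, 2, sd)
  if (any(sdc == 0)) {
    stop(sprintf("degenerate item %d: zero variance of log response time",
                 which(sdc == 0)[1]), call. = FALSE)
  }
  xi <- colMeans(Y)
  C <- sweep(Y, 2, xi)          # c_pi = -tau_p + eps_pi
  s2 <- pmax(apply(C, 2, var) * 0.5, 1e-6)
  # moment start for v: mean off-diagonal covariance (equals v in the model)
  S <- crossprod(C) / N
  v <- max(mean(S[upper.tri(S)]), 1e-6)
  for (it in seq_len(max_iter)) {
    prec <- 1 / v + sum(1 / s2)
    V <- 1 / prec
    m <- as.vector(C %*% (-1 / s2)) * V        # E[tau_p | row]
    v_new <- mean(m^2) + V
    R <- C + m                                  # E[eps_pi | row] = c + tau
    s2_new <- colMeans(R^2) + V
    delta <- max(abs(c(v_new - v, s2_new - s2)))
    v <- v_new; s2 <- s2_new
    if (delta < tol) break
  }
  prec <- 1 / v + sum(1 / s2)
  tau_hat <- as.vector(C %*% (-1 / s2)) / prec
  structure(list(xi_hat = xi, sigma_hat = sqrt(s2), var_tau_hat = v,
                 tau_hat = tau_hat, n_iter = it,
                 logLik = lognormal_rt_loglik(T, xi, sqrt(s2), v)),
            class = "rtc_rtfit")
}

#' Marginal log-likelihood of the response-time model
#'
#' Multivariate-normal log-likelihood of \eqn{\ln T} under the compound
#' symmetric covariance \eqn{v J + diag(\sigma^2)}, evaluated with the
#' matrix determinant lemma (no K x K inversion).
#'
#' @param T time matrix; @param xi,sigma item parameters;
#' @param var_tau speed variance.
#' @return scalar log-likelihood.
#' @export
lognormal_rt_loglik <- function(T, xi, sigma, var_tau) {
  Y <- log(T)
  N <- nrow(Y); K <- ncol(Y)
  C <- sweep(Y, 2, xi)
  s2 <- sigma^2
  a <- sum(1 / s2)
  # Sigma^{-1} = D^{-1} - v/(1 + v a) d d' with d = 1/s2 (Sherman-Morrison)
  q1 <- rowSums(sweep(C^2, 2, s2, "/"))
  u <- as.vector(C %*% (1 / s2))
  shrink <- if (var_tau > 0) var_tau / (1 + var_tau * a) else 0
  quad <- q1 - shrink * u^2
  logdet <- sum(log(s2)) + log1p(var_tau * a)
  # Jacobian of t -> ln t: subtract sum(log T)
  -0.5 * N * (K * log(2 * pi) + logdet) - 0.5 * sum(quad) - sum(Y)
}

#' Estimated standardized residual log response times
#'
#' \eqn{\hat z_{pi} = (\ln t_{pi} - \hat\xi_i + \hat\tau_p)/\hat\sigma_i}.
#' No empirical re-standardization is applied: comparability across focal
#' points relies on the model-based scale.
#'
#' @param T N x K time matrix.
#' @param fit an \code{rtc_rtfit} (or any list with \code{xi_hat},
#'   \code{sigma_hat}, \code{tau_hat}).
#' @return N x K matrix of residuals.
#' @export
standardized_residuals <- function(T, fit) {
  T <- as.matrix(T)
  stopifnot(nrow(T) == length(fit$tau_hat), ncol(T) == length(fit$xi_hat))
  (log(T) - outer(-fit$tau_hat, fit$xi_hat, "+")) / rep(fit$sigma_hat, each = nrow(T))
}
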