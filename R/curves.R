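# Nonparametric moderation: kernel-weighted marginal ML estimation of the
# ICC slope and intercept at focal points of the residual log response time.

#' Gaussian kernel weights around a focal point
#'
#' \eqn{w_{pji} = \exp(-(\hat z_{pi} - F_j)^2 / (2 (h N^{-1/5})^2))}.
#' The effective bandwidth \eqn{h N^{-1/5}} shrinks with the sample size at
#' the usual one-dimensional smoothing rate.
#'
#' @param z_col length-N residuals for one item.
#' @param F_j focal point.
#' @param h bandwidth factor (> 0), default 1.1.
#' @param N sample size used in the bandwidth (defaults to
#'   \code{length(z_col)}).
#' @return length-N weights in (0, 1].
#' @export
kernel_weights <- function(z_col, F_j, h = 1.1, N = length(z_col)) {
  stopifnot(h > 0, N >= 2)
  bw <- h * N^(-1 / 5)
  exp(-(z_col - F_j)^2 / (2 * bw^2))
}

#' Construct a focal grid
#'
#' @param points ascending focal points (default -2 to 2 by 0.5).
#' @param h bandwidth factor.
#' @return list of class \code{rtc_grid}.
#' @export
focal_grid <- function(points = seq(-2, 2, by = 0.5), h = 1.1) {
  stopifnot(length(points) >= 2, all(diff(points) > 0), h > 0)
  structure(list(points = as.numeric(points), h = h), class = "rtc_grid")
}

#' Weighted marginal log-likelihood for one item at a focal point
#'
#' Reference (pure R) evaluation of
#' \deqn{\sum_p \ln \int \Psi(\alpha\theta+\beta, x_{pi})^{w_p}
#'   \prod_{k \ne i} \Psi(\alpha^*_{pk}\theta + \beta^*_{pk}, x_{pk})\,
#'   N(\theta; 0, 1)\, d\theta}
#' by Gauss-Hermite quadrature.  The C++ optimizer used by
#' \code{\link{estimate_curves}} maximizes this same objective.
#'
#' @param alpha_ji,beta_ji candidate slope and intercept.
#' @param X N x K accuracy matrix.
#' @param i target item index.
#' @param rsp list with N x K matrices \code{alpha_star}, \code{beta_star}.
#' @param w length-N non-negative weights.
#' @param quad quadrature rule from \code{\link{gauss_hermite}}.
#' @return scalar log-likelihood.
#' @export
weighted_item_loglik <- function(alpha_ji, beta_ji, X, i, rsp, w,
                                 quad = gauss_hermite(61)) {
  X <- as.matrix(X)
  N <- nrow(X); K <- ncol(X); Q <- length(quad$nodes)
  stopifnot(length(w) == N, all(w >= 0))
  rest <- matrix(0, N, Q)
  for (k in seq_len(K)) {
    if (k == i) next
    eta_k <- outer(rsp$alpha_star[, k], quad$nodes) + rsp$beta_star[, k]
    rest <- rest + log_psi(eta_k, X[, k])
  }
  own <- outer(rep(1, N), quad$nodes)
  own <- log_psi(alpha_ji * own + beta_ji, X[, i]) * w
  v <- rest + own + rep(log(quad$weights), each = N)
  mx <- apply(v, 1, max)
  out <- sum(mx + log(rowSums(exp(v - mx))))
  if (!is.finite(out)) stop("non-finite weighted log-likelihood", call. = FALSE)
  out
}

#' Quick marginal-ML fit of the two-parameter normal-ogive model
#'
#' EM over a Gauss-Hermite grid for the standard 2PNO
#' \eqn{\Pr(x=1) = \Phi(\alpha_i\theta + \beta_i)}, \eqn{\theta \sim N(0,1)}.
#' Used to initialize the nonparametric sweep (and available as a fast
#' conditional independence accuracy-side fit).
#'
#' @param X N x K binary matrix.
#' @param n_quad quadrature nodes.
#' @param max_iter,tol EM controls.
#' @return list with \code{alpha}, \code{beta}, \code{logLik},
#'   \code{n_iter}.
#' @export
fit_2pno <- function(X, n_quad = 61, max_iter = 200, tol = 1e-4) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  N <- nrow(X); K <- ncol(X)
  gh <- gauss_hermite(n_quad)
  th <- gh$nodes; lgw <- log(gh$weights)
  alpha <- rep(1, K)
  beta <- qnorm(pmin(pmax(colMeans(X), 0.02), 0.98))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step: person-node posterior weights
    lp <- cpp_2pno_estep(X, alpha, beta, th, lgw)
    mx <- rowMaxs_fast(lp)
    P <- exp(lp - mx)
    rs <- rowSums(P)
    ll <- sum(mx + log(rs))
    P <- P / rs
    r1 <- crossprod(P, X)          # n_quad x K expected correct
    nq <- colSums(P)               # expected counts per node
    # M-step: per-item 2-parameter probit on the grid (Newton)
    for (k in seq_len(K)) {
      a <- alpha[k]; b <- beta[k]
      for (nw in 1:25) {
        eta <- clip_probit(a * th + b)
        Ph <- pnorm(eta); ph <- dnorm(eta)
        Ph <- pmin(pmax(Ph, 1e-12), 1 - 1e-12)
        u <- ph * (r1[, k] / Ph - (nq - r1[, k]) / (1 - Ph))
        wgt <- ph^2 * (r1[, k] / Ph^2 + (nq - r1[, k]) / (1 - Ph)^2)
        g <- c(sum(u * th), sum(u))
        H <- matrix(c(sum(wgt * th^2), sum(wgt * th), sum(wgt * th),
                      sum(wgt)), 2, 2)
        stp <- tryCatch(solve(H, g), error = function(e) g * 0.1)
        if (any(!is.finite(stp))) break
        stp <- pmin(pmax(stp, -0.5), 0.5)
        a <- min(max(a + stp[1], 0.01), 5)
        b <- min(max(b + stp[2], -6), 6)
        if (max(abs(stp)) < 1e-8) break
      }
      alpha[k] <- a; beta[k] <- b
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(alpha = alpha, beta = beta, logLik = ll, n_iter = it)
}

#' Estimate nonparametric ICC parameter curves
#'
#' Iterative kernel-weighted marginal ML: sweeping over items in index order
#' and focal points left to right, each (item, focal point) slope/intercept
#' pair maximizes the weighted log-likelihood
#' (\code{\link{weighted_item_loglik}}); after each item the N x K
#' response-specific parameters are refreshed by piecewise-linear
#' interpolation of that item's curve at each person's residual.  Stops when
#' the largest absolute change in any curve estimate falls below \code{tol}
#' or after \code{max_sweeps} sweeps.
#'
#' @param X N x K binary accuracy matrix.
#' @param Z_hat N x K estimated residual matrix (from
#'   \code{\link{standardized_residuals}}).
#' @param grid an \code{\link{focal_grid}}.
#' @param init list with length-K \code{alpha}, \code{beta} starting values
#'   (conditional independence 2PNO estimates); computed via
#'   \code{\link{fit_2pno}} when NULL.
#' @param tol convergence tolerance on curve estimates (default 1e-3).
#' @param max_sweeps maximum sweeps (default 20).
#' @param n_quad Gauss-Hermite nodes for the weighted likelihood
#'   (default 61; the fractional powers make the integrand less smooth than
#'   standard IRT).
#' @param min_sum_w focal points with total kernel weight below this are
#'   flagged \code{low_info} (default 25).
#' @return object of class \code{rtc_curves}: \code{alpha_curve},
#'   \code{beta_curve} (K x J), \code{alpha_star}, \code{beta_star} (N x K),
#'   \code{sum_weights}, \code{low_info}, \code{converged}, \code{n_sweeps},
#'   \code{grid}, \code{init}.
#' @export
estimate_curves <- function(X, Z_hat, grid = focal_grid(), init = NULL,
                            tol = 1e-3, max_sweeps = 20, n_quad = 61,
                            min_sum_w = 25) {
  X <- as.matrix(X); Z_hat <- as.matrix(Z_hat)
  stopifnot(identical(dim(X), dim(Z_hat)), inherits(grid, "rtc_grid"))
  if (is.null(init)) init <- fit_2pno(X, n_quad = n_quad)
  stopifnot(all(is.finite(init$alpha)), all(is.finite(init$beta)),
            length(init$alpha) == ncol(X))
  gh <- gauss_hermite(n_quad)
  storage.mode(X) <- "integer"
  res <- cpp_estimate_curves(
    X, Z_hat, grid$points, grid$h,
    init$alpha, init$beta, gh$nodes, gh$weights, tol, as.integer(max_sweeps),
    0.01, 5, -6, 6, min_sum_w)
  structure(c(res, list(grid = grid, init = init)), class = "rtc_curves")
}

#' Interpolate curve values at an arbitrary residual
#'
#' Piecewise-linear interpolation between bracketing focal points; outside
#' the focal range the value at the nearest focal point is used.
#' Continuous in \eqn{\hat z} and exact at the knots.
#'
#' @param z_hat residual value(s).
#' @param alpha_row,beta_row length-J curve values for one item.
#' @param grid an \code{\link{focal_grid}}.
#' @return list with \code{alpha}, \code{beta} at \code{z_hat}.
#' @export
interpolate_params <- function(z_hat, alpha_row, beta_row, grid = focal_grid()) {
  stopifnot(all(is.finite(alpha_row)), all(is.finite(beta_row)))
  list(alpha = approx(grid$points, alpha_row, xout = z_hat, rule = 2)$y,
       beta = approx(grid$points, beta_row, xout = z_hat, rule = 2)$y)
}

#' Tidy curve estimates
#'
#' @param x an \code{rtc_curves}; @param ... unused.
#' @return data.frame (item, focal_point, alpha, beta, sum_weights,
#'   low_info).
#' @export
as.data.frame.rtc_curves <- function(x, ...) {
  K <- nrow(x$alpha_curve); J <- length(x$grid$points)
  data.frame(item = rep(seq_len(K), times = J),
             focal_point = rep(x$grid$points, each = K),
             alpha = as.vector(x$alpha_curve),
             beta = as.vector(x$beta_curve),
             sum_weights = as.vector(x$sum_weights),
             low_info = as.vector(x$low_info))
}
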