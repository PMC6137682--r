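# Permutation test of conditional independence and posterior predictive
# check of linearity, both built on the nonparametric curve estimates.

#' Variance of a curve across focal points
#'
#' Sample variance (denominator J - 1) of the J focal-point estimates of an
#' ICC parameter; the permutation-test discrepancy statistic.  Invariant to
#' adding a constant to the curve.
#'
#' @param curve_row length-J numeric.
#' @return scalar variance.
#' @export
variance_statistic <- function(curve_row) {
  stopifnot(length(curve_row) >= 2)
  var(curve_row)
}

#' Maximum absolute cumulative sum of linear-regression residuals
#'
#' Discrepancy from linearity: OLS of the curve values on the focal points,
#' then \eqn{\max_j |\sum_{l \le j} e_l|} of the residuals.  Zero for an
#' exactly linear curve and invariant to adding any linear trend.
#'
#' @param curve_row length-J curve values (J >= 3).
#' @param points the J focal points.
#' @return scalar statistic.
#' @export
linearity_statistic <- function(curve_row, points) {
  stopifnot(length(curve_row) >= 3, length(points) == length(curve_row))
  e <- resid(lm(curve_row ~ points))
  max(abs(cumsum(e)))
}

#' Permutation test of conditional independence
#'
#' For each permutation each item's residual column is shuffled
#' independently across persons (accuracies untouched), the nonparametric
#' curves are re-estimated with the same settings, and the variance of each
#' curve across focal points is recorded.  The p-value uses the add-one
#' finite-sample correction
#' \eqn{p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{perm} + 1)}.
#'
#' @param X N x K accuracy matrix.
#' @param Z_hat N x K residual matrix.
#' @param grid an \code{\link{focal_grid}}.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer root seed (spawns one substream per permutation).
#' @param init optional starting values passed to
#'   \code{\link{estimate_curves}}; computed once from \code{X} when NULL
#'   (permutations leave \code{X} unchanged, so the conditional
#'   independence initialization is shared).
#' @param ... further arguments for \code{\link{estimate_curves}}.
#' @return object of class \code{rtc_permtest}: data.frame \code{results}
#'   (item, parameter, statistic, p_value, n_null), matrices of null
#'   variances, and the observed curves.
#' @export
permutation_test <- function(X, Z_hat, grid = focal_grid(), n_perm = 500,
                             seed = 1, init = NULL, ...) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(X); Z_hat <- as.matrix(Z_hat)
  N <- nrow(X); K <- ncol(X)
  if (is.null(init)) init <- fit_2pno(X)
  obs <- estimate_curves(X, Z_hat, grid, init = init, ...)
  stat_a <- apply(obs$alpha_curve, 1, variance_statistic)
  stat_b <- apply(obs$beta_curve, 1, variance_statistic)
  null_a <- matrix(NA_real_, n_perm, K)
  null_b <- matrix(NA_real_, n_perm, K)
  seeds <- spawn_seeds(seed, n_perm)
  for (r in seq_len(n_perm)) {
    set.seed(seeds[r])
    Zp <- apply(Z_hat, 2, sample)
    cur <- estimate_curves(X, Zp, grid, init = init, ...)
    null_a[r, ] <- apply(cur$alpha_curve, 1, variance_statistic)
    null_b[r, ] <- apply(cur$beta_curve, 1, variance_statistic)
  }
  p_a <- (1 + colSums(null_a >= rep(stat_a, each = n_perm))) / (n_perm + 1)
  p_b <- (1 + colSums(null_b >= rep(stat_b, each = n_perm))) / (n_perm + 1)
  res <- data.frame(
    item = rep(seq_len(K), 2),
    parameter = rep(c("alpha", "beta"), each = K),
    statistic = c(stat_a, stat_b),
    p_value = c(p_a, p_b),
    n_null = n_perm)
  structure(list(results = res, null_alpha = null_a, null_beta = null_b,
                 observed = obs, seed = seed),
            class = "rtc_permtest")
}

#' Posterior predictive check of linearity of conditional dependence
#'
#' Requires chains from the \emph{linear} conditional dependence model.  For
#' every retained posterior draw at the PPC thinning, a full replicate
#' dataset (times and accuracies, same persons) is generated under the
#' linear model; the complete two-step nonparametric pipeline (response-time
#' model fit, residuals, conditional independence initialization, curve
#' estimation) is re-run on each replicate, mirroring the estimation noise
#' of the observed analysis.  The discrepancy is
#' \code{\link{linearity_statistic}} per item and parameter, and the
#' posterior predictive p-value is the proportion of replicates with a
#' statistic at least as large as observed; items with \code{ppp < 0.05}
#' are flagged.
#'
#' @param chains an \code{rtc_chains} from \code{\link{run_gibbs}} with
#'   \code{model = "linear"} (person draws retained).
#' @param data the observed \code{\link{rtc_dataset}}.
#' @param grid an \code{\link{focal_grid}}.
#' @param n_rep number of replicates (must not exceed the stored person
#'   draws).
#' @param seed integer root seed.
#' @param ... further arguments for \code{\link{estimate_curves}}.
#' @return object of class \code{rtc_ppc}: data.frame \code{results} (item,
#'   parameter, statistic, ppp, flagged), replicate statistics, observed and
#'   replicated curves.
#' @export
ppc_linearity <- function(chains, data, grid = focal_grid(), n_rep = 500,
                          seed = 1, ...) {
  stopifnot(inherits(chains, "rtc_chains"), inherits(data, "rtc_dataset"))
  if (chains$model != "linear") {
    stop("posterior predictive linearity check requires chains from the linear model, got '",
         chains$model, "'", call. = FALSE)
  }
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  nd <- nrow(chains$person_draws$theta)
  if (is.null(nd) || nd < n_rep) {
    stop(sprintf("chains hold %d person draws but n_rep = %d; run more iterations",
                 ifelse(is.null(nd), 0L, nd), n_rep), call. = FALSE)
  }
  K <- chains$K; N <- chains$N; J <- length(grid$points)

  run_pipeline <- function(dat) {
    rtf <- fit_lognormal_rt(dat$T)
    Zh <- standardized_residuals(dat$T, rtf)
    estimate_curves(dat$X, Zh, grid, init = fit_2pno(dat$X), ...)
  }
  obs <- run_pipeline(data)
  obs_a <- apply(obs$alpha_curve, 1, linearity_statistic, points = grid$points)
  obs_b <- apply(obs$beta_curve, 1, linearity_statistic, points = grid$points)

  # map the r-th person draw to the matching retained item-parameter row
  pdt <- attr(chains$person_draws, "thin")
  if (is.null(pdt)) pdt <- 10L
  rep_a <- matrix(NA_real_, n_rep, K)
  rep_b <- matrix(NA_real_, n_rep, K)
  rep_curves_b <- array(NA_real_, c(n_rep, K, J))
  seeds <- spawn_seeds(seed, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    row <- min(r * pdt, nrow(chains$draws))
    pm <- chains$draws[row, ]
    A <- cbind(pm[sprintf("alpha0[%d]", seq_len(K))],
               pm[sprintf("alpha1[%d]", seq_len(K))])
    C <- cbind(pm[sprintf("beta0[%d]", seq_len(K))],
               pm[sprintf("beta1[%d]", seq_len(K))])
    xi <- pm[sprintf("xi[%d]", seq_len(K))]
    sig <- pm[sprintf("sigma[%d]", seq_len(K))]
    persons <- list(theta = chains$person_draws$theta[r, ],
                    tau = chains$person_draws$tau[r, ])
    Trep <- simulate_times(persons, xi, sig)
    Zrep <- true_residuals(Trep, persons, xi, sig)
    Xrep <- simulate_accuracy("linear", persons,
                              list(alpha = A, beta = C), Zrep)
    cur <- run_pipeline(rtc_dataset(Xrep, Trep))
    rep_a[r, ] <- apply(cur$alpha_curve, 1, linearity_statistic, points = grid$points)
    rep_b[r, ] <- apply(cur$beta_curve, 1, linearity_statistic, points = grid$points)
    rep_curves_b[r, , ] <- cur$beta_curve
  }
  ppp_a <- colMeans(rep_a >= rep(obs_a, each = n_rep))
  ppp_b <- colMeans(rep_b >= rep(obs_b, each = n_rep))
  res <- data.frame(
    item = rep(seq_len(K), 2),
    parameter = rep(c("alpha", "beta"), each = K),
    statistic = c(obs_a, obs_b),
    ppp = c(ppp_a, ppp_b),
    flagged = c(ppp_a, ppp_b) < 0.05,
    n_rep = n_rep)
  structure(list(results = res, rep_alpha = rep_a, rep_beta = rep_b,
                 rep_beta_curves = rep_curves_b, observed = obs,
                 seed = seed),
            class = "rtc_ppc")
}
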