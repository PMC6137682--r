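# Metropolis-within-Gibbs estimation of the four joint models.
#
# Parameterization per item: gamma_i = (alpha coefficients, beta
# coefficients) of length 2B (see R/models.R for the basis), plus the time
# intensity xi_i and residual log-time SD sigma_i.  The item vector
# (gamma_i, xi_i) has a joint N(mu_I, Sigma_I) prior; ln sigma_i has a
# diffuse normal prior.  Persons are N2(0, Sigma_P) with Var(theta) = 1.
#
# Update scheme (one iteration):
#   1. (theta_p, tau_p): joint random-walk Metropolis per person against the
#      observed-data likelihood (x* integrated out); z is recomputed from
#      the current draws, so the accuracy term sees the dependence of z on
#      tau.
#   2. (xi_i, ln sigma_i): joint random-walk Metropolis per item, again
#      against the observed-data likelihood (z depends on both).
#   3. Latent x*_pi ~ truncated normal (probit augmentation).
#   4. gamma_i: exact conjugate normal draw given x*, theta, z, with the
#      prior conditional of the joint item normal given current xi_i.
#   5. Sigma_P: inverse-Wishart expansion draw, then rescale theta (and
#      compensate the alpha coefficients) to restore Var(theta) = 1.
#   6. (mu_I, Sigma_I): conjugate normal / inverse-Wishart.
# Steps 1-2 target the x*-marginal posterior; x* is redrawn before its only
# consumer (step 4), making the composition a valid partially collapsed
# Gibbs sampler.  Proposal scales adapt during burn-in toward ~35%
# acceptance and are frozen afterwards.

# observed-data log-likelihood pieces via the C++ kernel (Jacobian of
# t -> ln t dropped; it is constant in all parameters)
MODEL_CODES <- c(ci = 0L, linear = 1L, quadratic = 2L, multicat = 3L)

joint_ll <- function(lnT, Xint, theta, tau, xi, sigma, A, C, model,
                     thresholds, baseline, want_eta = FALSE) {
  cpp_joint_loglik(lnT, Xint, theta, tau, xi, sigma, A, C,
                   MODEL_CODES[[model]], thresholds, as.integer(baseline),
                   want_eta)
}

compute_z <- function(lnT, tau, xi, sigma) {
  (lnT - outer(-tau, xi, "+")) / rep(sigma, each = nrow(lnT))
}

# truncated standard-normal around eta: sign fixed by x
draw_xstar <- function(eta, X) {
  plo <- pnorm(-eta)                     # P(x* < 0)
  u <- runif(length(eta))
  # x = 1: sample U in [plo, 1); x = 0: in (0, plo)
  p <- ifelse(X == 1, plo + u * (1 - plo), u * plo)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  matrix(eta + qnorm(p), nrow(eta), ncol(eta))
}

#' Fit a joint model by Metropolis-within-Gibbs sampling
#'
#' Runs the data-augmentation Gibbs sampler for the chosen model kind and
#' returns post-burn-in, thinned draws of all item parameters and
#' hyper-parameters, posterior means of the person parameters, and
#' acceptance diagnostics.  Two runs with identical data, configuration and
#' seed produce bit-identical chains.
#'
#' @param data an \code{\link{rtc_dataset}}.
#' @param config an \code{rtc_config} (see \code{\link{default_config}});
#'   fields used: \code{model}, \code{n_iter}, \code{burn_in}, \code{thin},
#'   \code{seed}, \code{multicat_thresholds}, \code{multicat_baseline}.
#' @param seed optional override of \code{config$seed}.
#' @param person_draw_thin store full person draws every this many retained
#'   iterations (needed by \code{\link{ppc_linearity}}); default 10.
#' @return object of class \code{rtc_chains}; see Details.
#' @details The returned object contains \code{draws} (matrix, one row per
#'   retained iteration; columns named \code{alpha<b>[i]}, \code{beta<b>[i]},
#'   \code{xi[i]}, \code{sigma[i]}, \code{var_tau}, \code{cov_theta_tau},
#'   \code{mu_I[..]}), \code{theta_mean}/\code{tau_mean},
#'   \code{person_draws} (list of \code{theta}/\code{tau} matrices at the
#'   PPC thinning), \code{accept} rates, and bookkeeping fields.
#' @export
run_gibbs <- function(data, config = default_config(), seed = NULL,
                      person_draw_thin = 10L) {
  stopifnot(inherits(data, "rtc_dataset"))
  config <- validate_config(unclass(config))
  model <- config$model
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)

  X <- data$X; lnT <- log(data$T)
  N <- data$N; K <- data$K
  thr <- config$multicat_thresholds
  bas <- config$multicat_baseline
  M <- length(thr) + 1L
  B <- model_basis_dim(model, M)
  d_item <- 2L * B + 1L   # (gamma, xi)

  # ---- initialization (deterministic given data) ----
  rtf <- fit_lognormal_rt(data$T)
  xi <- rtf$xi_hat; sigma <- rtf$sigma_hat
  tau <- rtf$tau_hat
  sc <- rowMeans(X); sc <- (sc - mean(sc)) / max(sd(sc), 1e-8)
  theta <- sc
  A <- cbind(rep(1, K), matrix(0, K, B - 1L))
  C <- cbind(qnorm(pmin(pmax(colMeans(X), 0.02), 0.98)), matrix(0, K, B - 1L))
  Sigma_P <- matrix(c(1, 0, 0, max(rtf$var_tau_hat, 1e-4)), 2, 2)
  mu_I <- c(A[1, ] * 0, C[1, ] * 0, mean(xi)); mu_I[1] <- 1
  Sigma_I <- diag(d_item)
  lsig_prior_mean <- 0; lsig_prior_sd <- 5
  mu0_sd <- 100                        # diffuse prior SD for mu_I
  iw_df0 <- d_item + 2                 # Sigma_I ~ IW(I, dim + 2)

  scale_person <- rep(0.5, N)          # RW scales, adapted in burn-in
  scale_item <- rep(0.05, K)
  acc_person_post <- 0; acc_item_post <- 0; n_post <- 0L
  ap_batch <- numeric(N); ai_batch <- numeric(K); batch_n <- 0L

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  par_names <- c(
    as.vector(t(outer(seq_len(K), seq_len(B) - 1L,
                      function(i, b) sprintf("alpha%d[%d]", b, i)))),
    as.vector(t(outer(seq_len(K), seq_len(B) - 1L,
                      function(i, b) sprintf("beta%d[%d]", b, i)))),
    sprintf("xi[%d]", seq_len(K)), sprintf("sigma[%d]", seq_len(K)),
    "var_tau", "cov_theta_tau", sprintf("mu_I[%d]", seq_len(d_item)))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  theta_sum <- numeric(N); tau_sum <- numeric(N); n_mean <- 0L
  person_draws <- list(theta = NULL, tau = NULL)
  pd_theta <- list(); pd_tau <- list()

  Xint <- X; storage.mode(Xint) <- "integer"
  keep_i <- 0L
  for (iter in seq_len(config$n_iter)) {
    # ---- 1. persons ----
    jl <- joint_ll(lnT, Xint, theta, tau, xi, sigma, A, C, model, thr, bas)
    ll_cur <- rowSums(jl$acc) + rowSums(jl$rt)
    SPi <- solve(Sigma_P)
    pr_cur <- -0.5 * (theta^2 * SPi[1, 1] + 2 * theta * tau * SPi[1, 2] +
                      tau^2 * SPi[2, 2])
    th_p <- theta + rnorm(N) * scale_person
    ta_p <- tau + rnorm(N) * scale_person * sqrt(Sigma_P[2, 2])
    jlp <- joint_ll(lnT, Xint, th_p, ta_p, xi, sigma, A, C, model, thr, bas)
    ll_p <- rowSums(jlp$acc) + rowSums(jlp$rt)
    pr_p <- -0.5 * (th_p^2 * SPi[1, 1] + 2 * th_p * ta_p * SPi[1, 2] +
                    ta_p^2 * SPi[2, 2])
    acc <- log(runif(N)) < (ll_p + pr_p - ll_cur - pr_cur)
    theta[acc] <- th_p[acc]; tau[acc] <- ta_p[acc]
    ap_batch <- ap_batch + acc
    if (iter > config$burn_in) acc_person_post <- acc_person_post + mean(acc)

    # ---- 2. items (xi, ln sigma) ----
    # prior conditional of xi given gamma (joint normal partition)
    Sgg <- Sigma_I[seq_len(2 * B), seq_len(2 * B), drop = FALSE]
    Sgx <- Sigma_I[seq_len(2 * B), d_item]
    wv <- solve(Sgg, Sgx)
    xi_cond_var <- max(Sigma_I[d_item, d_item] - sum(Sgx * wv), 1e-10)
    gam <- cbind(A, C)
    xi_cond_mean <- mu_I[d_item] +
      as.vector((gam - matrix(mu_I[seq_len(2 * B)], K, 2 * B, byrow = TRUE)) %*% wv)
    jl <- joint_ll(lnT, Xint, theta, tau, xi, sigma, A, C, model, thr, bas)
    ll_cur_i <- colSums(jl$acc) + colSums(jl$rt) +
      dnorm(xi, xi_cond_mean, sqrt(xi_cond_var), log = TRUE) +
      dnorm(log(sigma), lsig_prior_mean, lsig_prior_sd, log = TRUE)
    xi_p <- xi + rnorm(K) * scale_item
    sig_p <- sigma * exp(rnorm(K) * scale_item)
    jlp <- joint_ll(lnT, Xint, theta, tau, xi_p, sig_p, A, C, model, thr, bas)
    ll_p_i <- colSums(jlp$acc) + colSums(jlp$rt) +
      dnorm(xi_p, xi_cond_mean, sqrt(xi_cond_var), log = TRUE) +
      dnorm(log(sig_p), lsig_prior_mean, lsig_prior_sd, log = TRUE)
    acc <- log(runif(K)) < (ll_p_i - ll_cur_i)
    xi[acc] <- xi_p[acc]; sigma[acc] <- sig_p[acc]
    ai_batch <- ai_batch + acc
    batch_n <- batch_n + 1L
    if (iter > config$burn_in) {
      acc_item_post <- acc_item_post + mean(acc)
      n_post <- n_post + 1L
    }

    # ---- 2b. directional Gibbs moves along the likelihood-flat directions --
    # The likelihood is invariant under (tau + c, xi + c) and under
    # (theta + e, beta - e * alpha); random-walk updates mix these common
    # modes O(1/N) per iteration, so sample the shifts from their exact
    # conditionals (Gaussian: the priors are the only non-flat terms).
    Sxx <- Sigma_I[d_item, d_item]
    cond_S <- Sgg - tcrossprod(Sgx) / Sxx
    P0 <- solve(cond_S + diag(1e-10, 2 * B))
    # (tau, xi) location
    prec_c <- N * SPi[2, 2] + K / xi_cond_var
    b_c <- sum(SPi[2, 2] * tau + SPi[1, 2] * theta) +
      sum(xi - xi_cond_mean) / xi_cond_var
    shift <- rnorm(1, -b_c / prec_c, sqrt(1 / prec_c))
    tau <- tau + shift; xi <- xi + shift
    # (theta, intercepts) location
    M0 <- matrix(mu_I[seq_len(2 * B)], K, 2 * B, byrow = TRUE) +
      outer((xi - mu_I[d_item]) / Sxx, Sgx)
    G0 <- cbind(A, C)
    P0C <- P0[B + seq_len(B), , drop = FALSE]      # C-block rows of the precision
    prec_e <- N * SPi[1, 1] + sum(A * (A %*% P0[B + seq_len(B), B + seq_len(B)]))
    b_e <- -sum(SPi[1, 1] * theta + SPi[1, 2] * tau) +
      sum(A * ((G0 - M0) %*% t(P0C)))
    e_shift <- rnorm(1, b_e / prec_e, sqrt(1 / prec_e))
    theta <- theta + e_shift
    C <- C - e_shift * A

    # ---- 3. latent x* ----
    z <- compute_z(lnT, tau, xi, sigma)
    eta <- joint_ll(lnT, Xint, theta, tau, xi, sigma, A, C, model, thr, bas,
                    want_eta = TRUE)$eta
    xstar <- draw_xstar(eta, X)

    # ---- 4. gamma_i conjugate (cond_S/P0 as computed in 2b) ----
    bl <- basis_list(z, model, thr, bas)
    for (i in seq_len(K)) {
      D <- matrix(NA_real_, N, 2 * B)
      for (b in seq_len(B)) {
        zb <- bl[[b]][, i]
        D[, b] <- zb * theta
        D[, B + b] <- zb
      }
      m0 <- mu_I[seq_len(2 * B)] + Sgx / Sxx * (xi[i] - mu_I[d_item])
      Vp <- solve(P0 + crossprod(D))
      mp <- Vp %*% (P0 %*% m0 + crossprod(D, xstar[, i]))
      g <- as.vector(mp + t(chol(Vp)) %*% rnorm(2 * B))
      A[i, ] <- g[seq_len(B)]
      C[i, ] <- g[B + seq_len(B)]
    }

    # ---- 5. Sigma_P with unit-variance constraint ----
    P2 <- cbind(theta, tau)
    W <- riwish(4 + N, diag(2) + crossprod(P2))
    cc <- sqrt(W[1, 1])
    theta <- theta / cc
    A <- A * cc
    Dg <- diag(c(1 / cc, 1))
    Sigma_P <- Dg %*% W %*% Dg
    Sigma_P[1, 1] <- 1   # exact by construction; enforce against rounding

    # ---- 6. item hyper-parameters ----
    V_items <- cbind(A, C, xi)
    prec_mu <- diag(1 / mu0_sd^2, d_item) + K * solve(Sigma_I)
    Vmu <- solve(prec_mu)
    mmu <- Vmu %*% (solve(Sigma_I) %*% colSums(V_items))
    mu_I <- as.vector(mmu + t(chol(Vmu)) %*% rnorm(d_item))
    Rm <- V_items - matrix(mu_I, K, d_item, byrow = TRUE)
    Sigma_I <- riwish(iw_df0 + K, diag(d_item) + crossprod(Rm))

    # ---- adaptation during burn-in ----
    if (iter <= config$burn_in && batch_n == 25L) {
      scale_person <- scale_person * exp(ap_batch / batch_n - 0.35)
      scale_item <- scale_item * exp(ai_batch / batch_n - 0.35)
      scale_person <- pmin(pmax(scale_person, 1e-3), 5)
      scale_item <- pmin(pmax(scale_item, 1e-3), 2)
      ap_batch[] <- 0; ai_batch[] <- 0; batch_n <- 0L
    }

    if (any(!is.finite(c(A, C, xi, sigma, theta, tau, Sigma_P)))) {
      stop(sprintf("divergent chain: non-finite draw at iteration %d", iter),
           call. = FALSE)
    }

    # ---- bookkeeping ----
    if (iter > config$burn_in) {
      if ((iter - config$burn_in) %% config$thin == 0L) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- c(as.vector(t(A)), as.vector(t(C)), xi, sigma,
                             Sigma_P[2, 2], Sigma_P[1, 2], mu_I)
        theta_sum <- theta_sum + theta; tau_sum <- tau_sum + tau
        n_mean <- n_mean + 1L
        if (keep_i %% person_draw_thin == 0L) {
          pd_theta[[length(pd_theta) + 1L]] <- theta
          pd_tau[[length(pd_tau) + 1L]] <- tau
        }
      }
    }
  }

  accept <- list(person = acc_person_post / max(n_post, 1L),
                 item = acc_item_post / max(n_post, 1L))

  structure(list(
    model = model, draws = draws[seq_len(keep_i), , drop = FALSE],
    K = K, N = N, B = B, M = M, thresholds = thr, baseline = bas,
    theta_mean = theta_sum / n_mean, tau_mean = tau_sum / n_mean,
    person_draws = structure(list(theta = do.call(rbind, pd_theta),
                                  tau = do.call(rbind, pd_tau)),
                             thin = as.integer(person_draw_thin)),
    accept = accept, seed = seed,
    n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
    final_state = list(z = compute_z(lnT, tau, xi, sigma), theta = theta,
                       tau = tau, xi = xi, sigma = sigma, A = A, C = C)),
    class = "rtc_chains")
}

#' @export
print.rtc_chains <- function(x, ...) {
  cat(sprintf("<rtc_chains> model=%s, %d retained draws (%d iter, %d burn-in), N=%d K=%d\n",
              x$model, nrow(x$draws), x$n_iter, x$burn_in, x$N, x$K))
  cat(sprintf("  acceptance: persons %.2f, items %.2f\n",
              x$accept$person, x$accept$item))
  invisible(x)
}

#' Posterior summaries of a fitted chain
#'
#' @param chains an \code{rtc_chains}.
#' @param prob central credible-interval mass (default 0.95).
#' @return data.frame with parameter, mean, sd, lower, upper.
#' @export
posterior_summary <- function(chains, prob = 0.95) {
  d <- chains$draws
  a <- (1 - prob) / 2
  data.frame(parameter = colnames(d),
             mean = colMeans(d),
             sd = apply(d, 2, sd),
             lower = apply(d, 2, quantile, probs = a),
             upper = apply(d, 2, quantile, probs = 1 - a),
             row.names = NULL)
}

#' Extract posterior-mean item parameters from chains
#'
#' @param chains an \code{rtc_chains}.
#' @return list with \code{alpha}, \code{beta} (K x B), \code{xi},
#'   \code{sigma}, \code{Sigma_P}.
#' @export
posterior_mean_params <- function(chains) {
  pm <- colMeans(chains$draws)
  K <- chains$K; B <- chains$B
  A <- matrix(NA_real_, K, B); C <- matrix(NA_real_, K, B)
  for (b in seq_len(B)) {
    A[, b] <- pm[sprintf("alpha%d[%d]", b - 1L, seq_len(K))]
    C[, b] <- pm[sprintf("beta%d[%d]", b - 1L, seq_len(K))]
  }
  Sigma_P <- matrix(c(1, pm["cov_theta_tau"], pm["cov_theta_tau"],
                      pm["var_tau"]), 2, 2)
  list(alpha = A, beta = C,
       xi = unname(pm[sprintf("xi[%d]", seq_len(K))]),
       sigma = unname(pm[sprintf("sigma[%d]", seq_len(K))]),
       Sigma_P = Sigma_P)
}
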