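# Simulator for the four generative models: persons, items, response times
# and accuracies.  Serves both as fixture source and as ground truth for
# parameter-recovery studies.

#' Default person covariance matrix
#'
#' Unit ability variance (identification constraint), speed variance 0.25
#' and ability-speed correlation 0.3 — typical magnitudes for timed ability
#' tests, where speed spreads much less than log-time noise and correlates
#' moderately with ability.
#'
#' @param var_tau speed variance.
#' @param cor_theta_tau ability-speed correlation.
#' @return 2 x 2 covariance matrix with rows/cols (theta, tau).
#' @export
default_sigma_p <- function(var_tau = 0.25, cor_theta_tau = 0.3) {
  stopifnot(var_tau >= 0, abs(cor_theta_tau) < 1)
  cv <- cor_theta_tau * sqrt(var_tau)
  matrix(c(1, cv, cv, var_tau), 2, 2,
         dimnames = list(c("theta", "tau"), c("theta", "tau")))
}

#' Sample persons from the latent bivariate normal
#'
#' Draws \code{n} independent (ability, speed) pairs from
#' \eqn{N_2(0, \Sigma_P)}; \eqn{\Sigma_P} must be positive definite with the
#' identification constraint \eqn{\Sigma_P[\theta,\theta] = 1}.
#'
#' @param n number of persons.
#' @param Sigma_P 2 x 2 latent covariance.
#' @param seed optional integer seed.
#' @return list with \code{theta}, \code{tau} (length n) and \code{Sigma_P}.
#' @export
sample_persons <- function(n, Sigma_P = default_sigma_p(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Sigma_P <- as.matrix(Sigma_P)
  stopifnot(identical(dim(Sigma_P), c(2L, 2L)))
  if (abs(Sigma_P[1, 1] - 1) > 1e-12) {
    stop("Sigma_P[theta, theta] must equal 1 (identification constraint)", call. = FALSE)
  }
  ev <- eigen(Sigma_P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma_P must be positive definite", call. = FALSE)
  draws <- rmvn(n, 0, Sigma_P)
  list(theta = draws[, 1], tau = draws[, 2], Sigma_P = Sigma_P)
}

#' Default item hyper-parameters for a generating model
#'
#' Mean vector and covariance of the per-item parameter vector
#' (alpha coefficients, beta coefficients, xi) used when items are drawn
#' hierarchically.  Baseline slopes centre on 1, baseline intercepts on 0
#' with generous spread; quadratic effects centre on (-0.02, -0.09) with
#' variance 0.03, the magnitudes reported for a large operational arithmetic
#' test; time intensities centre on log(45s) with SD 0.4.
#'
#' @param model model kind.
#' @param M number of categories (multicat).
#' @return list with \code{mu} (length 2B+1), \code{Sigma}
#'   ((2B+1) x (2B+1), diagonal), \code{mean_log_sigma}, \code{sd_log_sigma}
#'   for the residual log-time SD drawn log-normally.
#' @export
default_item_hyper <- function(model, M = 5L) {
  model <- match.arg(model, MODEL_KINDS)
  B <- model_basis_dim(model, M)
  mu_a <- c(1, rep(0, B - 1L))
  mu_b <- rep(0, B)
  sd_a <- c(0.25, rep(0.2, B - 1L))
  sd_b <- c(0.7, rep(0.3, B - 1L))
  if (model == "quadratic") {
    mu_a[3] <- -0.02; mu_b[3] <- -0.09
    sd_a[3] <- sqrt(0.03); sd_b[3] <- sqrt(0.03)
  }
  mu <- c(mu_a, mu_b, log(45))
  Sigma <- diag(c(sd_a, sd_b, 0.4)^2)
  nm <- c(paste0("alpha", seq_len(B) - 1L), paste0("beta", seq_len(B) - 1L), "xi")
  names(mu) <- nm; dimnames(Sigma) <- list(nm, nm)
  list(mu = mu, Sigma = Sigma, mean_log_sigma = log(0.4), sd_log_sigma = 0.15)
}

#' Sample item parameters from the hyper-distribution
#'
#' Draws K item vectors from \eqn{N(\mu_I, \Sigma_I)}; the residual
#' log-time SD is drawn on the log scale and exponentiated, guaranteeing
#' positivity without truncation artifacts.
#'
#' @param K number of items.
#' @param model model kind.
#' @param hyper as returned by \code{\link{default_item_hyper}}.
#' @param M number of categories (multicat).
#' @param seed optional integer seed.
#' @return list with matrices \code{alpha}, \code{beta} (K x B) and vectors
#'   \code{xi}, \code{sigma}.
#' @export
sample_items <- function(K, model, hyper = default_item_hyper(model, M), M = 5L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model, MODEL_KINDS)
  B <- model_basis_dim(model, M)
  stopifnot(length(hyper$mu) == 2L * B + 1L)
  ev <- eigen(hyper$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("item hyper-covariance must be PSD", call. = FALSE)
  V <- rmvn(K, matrix(hyper$mu, K, 2L * B + 1L, byrow = TRUE),
            hyper$Sigma + diag(1e-12, nrow(hyper$Sigma)))
  sigma <- exp(rnorm(K, hyper$mean_log_sigma, hyper$sd_log_sigma))
  list(alpha = V[, seq_len(B), drop = FALSE],
       beta = V[, B + seq_len(B), drop = FALSE],
       xi = V[, 2L * B + 1L], sigma = sigma)
}

#' Simulate log-normal response times
#'
#' \eqn{\ln t_{pi} \sim N(\xi_i - \tau_p, \sigma_i^2)} independently.
#'
#' @param persons list with \code{tau} (length N).
#' @param xi length-K time intensities.
#' @param sigma length-K residual SDs (> 0).
#' @param seed optional integer seed.
#' @return N x K matrix of times in seconds.
#' @export
simulate_times <- function(persons, xi, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(xi) == length(sigma), all(sigma > 0))
  N <- length(persons$tau); K <- length(xi)
  mu <- outer(-persons$tau, xi, "+")
  exp(mu + matrix(rnorm(N * K), N, K) * rep(sigma, each = N))
}

#' True standardized residual log response times
#'
#' \eqn{z_{pi} = (\ln t_{pi} - \xi_i + \tau_p)/\sigma_i} computed from the
#' generating person and item parameters; each column is standard normal in
#' population under the generating model.
#'
#' @param T N x K time matrix.
#' @inheritParams simulate_times
#' @return N x K residual matrix.
#' @export
true_residuals <- function(T, persons, xi, sigma) {
  N <- nrow(T)
  (log(T) - outer(-persons$tau, xi, "+")) / rep(sigma, each = N)
}

#' Simulate accuracies given residual log response times
#'
#' Bernoulli draws with success probability \eqn{\Phi(\eta_{pi})} where the
#' probit argument follows the chosen model kind (see
#' \code{\link{icc_probability}}).
#'
#' @param model model kind.
#' @param persons list with \code{theta}.
#' @param items list with \code{alpha}, \code{beta} (K x B matrices).
#' @param Z N x K residual matrix computed from the same times/persons/items.
#' @param thresholds,baseline multicat settings.
#' @param seed optional integer seed.
#' @return N x K binary matrix.
#' @export
simulate_accuracy <- function(model, persons, items, Z,
                              thresholds = c(-1.5, -0.5, 0.5, 1.5),
                              baseline = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model, MODEL_KINDS)
  M <- length(thresholds) + 1L
  if (model == "multicat" && is.null(baseline)) baseline <- (M + 1L) %/% 2L
  eta <- eta_matrix(Z, persons$theta, items$alpha, items$beta, model,
                    thresholds, baseline)
  P <- pnorm(clip_probit(eta))
  (matrix(runif(length(P)), nrow(P), ncol(P)) < P) * 1
}

#' Simulate a complete dataset under a generative model
#'
#' Full pipeline: persons from \eqn{N_2(0, \Sigma_P)}, items either drawn
#' from the hyper-distribution or supplied explicitly, times from the
#' log-normal model, residuals, then accuracies under the chosen conditional
#' dependence structure.  A single seed deterministically spawns substreams
#' for the four sampling stages.
#'
#' @param model model kind.
#' @param N,K numbers of persons and items.
#' @param seed integer root seed.
#' @param Sigma_P person covariance.
#' @param items optional explicit item parameters (as from
#'   \code{\link{sample_items}}); drawn hierarchically when NULL.
#' @param hyper item hyper-parameters used when drawing items.
#' @param thresholds,baseline multicat settings.
#' @return list with \code{data} (an \code{\link{rtc_dataset}}) and
#'   \code{truth} (persons, items, Z, model settings).
#' @export
simulate_dataset <- function(model, N = 3000, K = 20, seed = 1,
                             Sigma_P = default_sigma_p(),
                             items = NULL,
                             hyper = default_item_hyper(model, M),
                             thresholds = c(-1.5, -0.5, 0.5, 1.5),
                             baseline = NULL) {
  model <- match.arg(model, MODEL_KINDS)
  M <- length(thresholds) + 1L
  if (is.null(baseline)) baseline <- (M + 1L) %/% 2L
  seeds <- spawn_seeds(seed, 4)
  persons <- sample_persons(N, Sigma_P, seed = seeds[1])
  if (is.null(items)) items <- sample_items(K, model, hyper, M = M, seed = seeds[2])
  T <- simulate_times(persons, items$xi, items$sigma, seed = seeds[3])
  Z <- true_residuals(T, persons, items$xi, items$sigma)
  X <- simulate_accuracy(model, persons, items, Z, thresholds, baseline,
                         seed = seeds[4])
  list(data = rtc_dataset(X, T),
       truth = list(model = model, persons = persons, items = items, Z = Z,
                    Sigma_P = persons$Sigma_P, thresholds = thresholds,
                    baseline = baseline, seed = seed))
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Writes the X/T matrices as CSVs plus a JSON file holding all generating
#' person/item parameters for recovery studies.
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xp <- file.path(dir, "x.csv"); tp <- file.path(dir, "t.csv")
  gp <- file.path(dir, "truth.json")
  write_dataset(sim$data, xp, tp)
  tr <- sim$truth
  jsonlite::write_json(
    list(model = tr$model, thresholds = tr$thresholds, baseline = tr$baseline,
         seed = tr$seed, Sigma_P = tr$Sigma_P,
         theta = tr$persons$theta, tau = tr$persons$tau,
         alpha = tr$items$alpha, beta = tr$items$beta,
         xi = tr$items$xi, sigma = tr$items$sigma),
    gp, auto_unbox = TRUE, digits = NA)
  invisible(c(x = xp, t = tp, truth = gp))
}
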