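# brute-force 2-D trapezoid integration of the joint marginal likelihood on
# [-8, 8]^2, the independent oracle for the Gauss-Hermite implementation
brute_m2ll <- function(data, model, params, step = 0.01) {
  gr <- seq(-8, 8, by = step)
  G <- expand.grid(theta = gr, tau = gr)
  wt <- rep(1, length(gr)); wt[c(1, length(gr))] <- 0.5   # trapezoid weights
  W <- outer(wt, wt) * step^2
  Si <- solve(params$Sigma_P)
  ld <- -log(2 * pi) - 0.5 * log(det(params$Sigma_P)) -
    0.5 * (Si[1, 1] * G$theta^2 + 2 * Si[1, 2] * G$theta * G$tau + Si[2, 2] * G$tau^2)
  tot <- 0
  for (p in seq_len(data$N)) {
    lp <- ld
    for (i in seq_len(data$K)) {
      item <- list(alpha = params$alpha[i, ], beta = params$beta[i, ],
                   xi = params$xi[i], sigma = params$sigma[i])
      lp <- lp + joint_density(model, item, data$X[p, i], data$T[p, i],
                               G$theta, G$tau, log = TRUE)
    }
    tot <- tot + log(sum(exp(lp) * as.vector(W)))
  }
  -2 * tot
}

test_that("quadrature marginal likelihood matches brute-force integration", {
  sim <- simulate_dataset("linear", N = 1, K = 1, seed = 31)
  pars <- list(alpha = sim$truth$items$alpha, beta = sim$truth$items$beta,
               xi = sim$truth$items$xi, sigma = sim$truth$items$sigma,
               Sigma_P = sim$truth$Sigma_P)
  m_gh <- minus2_loglik(sim$data, "linear", pars)
  m_bf <- brute_m2ll(sim$data, "linear", pars)
  expect_equal(m_gh, m_bf, tolerance = 1e-6)
})

test_that("nested parameterizations give identical likelihood values", {
  sim <- simulate_dataset("linear", N = 40, K = 3, seed = 32)
  it <- sim$truth$items
  parsl <- list(alpha = it$alpha, beta = it$beta, xi = it$xi, sigma = it$sigma,
                Sigma_P = sim$truth$Sigma_P)
  parsq <- parsl
  parsq$alpha <- cbind(it$alpha, 0)
  parsq$beta <- cbind(it$beta, 0)
  expect_equal(minus2_loglik(sim$data, "quadratic", parsq),
               minus2_loglik(sim$data, "linear", parsl), tolerance = 1e-10)
})

test_that("an uninformative item contributes exactly ln(1/2) per response", {
  sim <- simulate_dataset("ci", N = 30, K = 3, seed = 33)
  it <- sim$truth$items
  pars <- list(alpha = it$alpha, beta = it$beta, xi = it$xi, sigma = it$sigma,
               Sigma_P = sim$truth$Sigma_P)
  m0 <- minus2_loglik(sim$data, "ci", pars)
  # append an item with zero slope/intercept and a huge residual SD: its
  # accuracy factor is exactly 1/2 and its time factor decouples from tau
  sig_big <- 1000
  set.seed(34)
  Textra <- exp(rnorm(30, 3.5, sig_big * 0.001))  # keep times representable
  Xextra <- rbinom(30, 1, 0.5)
  d2 <- rtc_dataset(cbind(sim$data$X, Xextra), cbind(sim$data$T, Textra))
  pars2 <- pars
  pars2$alpha <- rbind(it$alpha, 0); pars2$beta <- rbind(it$beta, 0)
  pars2$xi <- c(it$xi, 3.5); pars2$sigma <- c(it$sigma, sig_big)
  m1 <- minus2_loglik(d2, "ci", pars2)
  rt_part <- sum(dnorm(log(Textra), 3.5, sig_big, log = TRUE) - log(Textra))
  expect_equal(m1 - m0, -2 * (30 * log(0.5) + rt_part), tolerance = 1e-4)
})

test_that("modified BIC follows the penalized definition", {
  expect_equal(modified_bic(100, 10, exp(1)), 110)
  # incremental parameter counts against the conditional independence model
  expect_equal(count_params("linear", 38) - count_params("ci", 38), 76)
  expect_equal(count_params("quadratic", 38) - count_params("ci", 38), 152)
  expect_equal(count_params("multicat", 38, M = 5) - count_params("ci", 38), 304)
  expect_error(modified_bic(100, 0, 10))
})

test_that("direct ML of the quadratic model nests the linear fit", {
  sim <- simulate_dataset("linear", N = 40, K = 1, seed = 35)
  Sigma_P <- sim$truth$Sigma_P
  obj <- function(par, model, B) {
    m <- matrix(par, 1)
    pars <- list(alpha = m[, 1:B, drop = FALSE],
                 beta = m[, B + 1:B, drop = FALSE],
                 xi = m[, 2 * B + 1], sigma = exp(m[, 2 * B + 2]),
                 Sigma_P = Sigma_P)
    minus2_loglik(sim$data, model, pars, n_nodes = 11)
  }
  it <- sim$truth$items
  ctl <- list(iter.max = 60, eval.max = 200)
  start_l <- c(it$alpha, it$beta, it$xi, log(it$sigma))
  fit_l <- nlminb(start_l, obj, model = "linear", B = 2, control = ctl,
                  lower = c(-5, -5, -6, -6, 0, -3), upper = c(5, 5, 6, 6, 8, 2))
  # start the quadratic fit at the linear optimum with zero quadratic terms
  p <- fit_l$par
  start_q <- c(p[1], p[2], 0, p[3], p[4], 0, p[5], p[6])
  fit_q <- nlminb(start_q, obj, model = "quadratic", B = 3, control = ctl,
                  lower = c(-5, -5, -3, -6, -6, -3, 0, -3),
                  upper = c(5, 5, 3, 6, 6, 3, 8, 2))
  expect_lte(fit_q$objective, fit_l$objective + 1e-6)
})
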