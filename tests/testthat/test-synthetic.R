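test_that("sample_persons matches the generating correlation", {
  n <- 1e5
  ps <- sample_persons(n, diag(2), seed = 1)
  expect_lt(abs(cor(ps$theta, ps$tau)), 0.01)
  expect_lt(abs(mean(ps$theta)), 0.02)

  Sig <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ps2 <- sample_persons(n, Sig, seed = 2)
  expect_lt(abs(cor(ps2$theta, ps2$tau) - 0.5), 0.01)

  expect_error(sample_persons(10, matrix(c(2, 0, 0, 1), 2, 2)), "must equal 1")
  expect_error(sample_persons(10, matrix(c(1, 2, 2, 1), 2, 2)), "positive definite")
})

test_that("simulate_times follows the log-normal measurement model", {
  persons <- list(tau = c(0, 0.5))
  # degenerate noise: t = exp(xi - tau) to 6 decimals
  T0 <- simulate_times(persons, xi = c(1, 2), sigma = rep(1e-8, 2), seed = 1)
  expect_equal(T0, exp(outer(-persons$tau, c(1, 2), "+")), tolerance = 1e-6)

  # moments of ln t for one cell: xi=1, tau=0, sigma=0.5
  many <- simulate_times(list(tau = rep(0, 1e5)), xi = 1, sigma = 0.5, seed = 3)
  expect_lt(abs(mean(log(many)) - 1), 0.01)
  expect_lt(abs(sd(log(many)) - 0.5), 0.01)

  # tau = xi implies median time 1
  med <- simulate_times(list(tau = rep(2, 2e4)), xi = 2, sigma = 0.4, seed = 4)
  expect_lt(abs(median(med) - 1), 0.02)

  expect_error(simulate_times(persons, xi = c(1, 2), sigma = c(0.5, -1)), "sigma")
})

test_that("true_residuals standardizes exactly and in distribution", {
  persons <- list(tau = c(0.2, -0.1))
  xi <- c(1, 1.5); sigma <- c(0.4, 0.6)
  Texact <- exp(outer(-persons$tau, xi, "+"))
  expect_equal(true_residuals(Texact, persons, xi, sigma),
               matrix(0, 2, 2))
  Tone <- exp(outer(-persons$tau, xi, "+") + rep(sigma, each = 2))
  expect_equal(true_residuals(Tone, persons, xi, sigma), matrix(1, 2, 2))

  ps <- sample_persons(1e5, default_sigma_p(), seed = 5)
  T <- simulate_times(ps, xi, sigma, seed = 6)
  Z <- true_residuals(T, ps, xi, sigma)
  expect_true(all(abs(colMeans(Z)) < 0.01))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 0.01))
})

test_that("simulate_accuracy respects the model kind", {
  ps <- sample_persons(2e4, default_sigma_p(), seed = 7)
  Z <- matrix(rnorm(2e4 * 2), 2e4, 2)

  # flat quadratic model: success probability exactly 1/2
  it0 <- list(alpha = matrix(0, 2, 3), beta = matrix(0, 2, 3))
  X0 <- simulate_accuracy("quadratic", ps, it0, Z, seed = 8)
  expect_lt(abs(mean(X0) - 0.5), 0.01)

  # nested reduction: quadratic with zero quadratic terms == linear, same seed
  itl <- list(alpha = rbind(c(1, 0.3), c(0.9, 0)),
              beta = rbind(c(0.2, -0.4), c(0, 0.5)))
  itq <- list(alpha = cbind(itl$alpha, 0), beta = cbind(itl$beta, 0))
  Xl <- simulate_accuracy("linear", ps, itl, Z, seed = 11)
  Xq <- simulate_accuracy("quadratic", ps, itq, Z, seed = 11)
  expect_identical(Xl, Xq)

  # multicat with zero contrasts reduces to CI, same seed
  itc <- list(alpha = matrix(1, 2, 1), beta = matrix(0.3, 2, 1))
  itm <- list(alpha = cbind(1, matrix(0, 2, 4)), beta = cbind(0.3, matrix(0, 2, 4)))
  Xc <- simulate_accuracy("ci", ps, itc, Z, seed = 12)
  Xm <- simulate_accuracy("multicat", ps, itm, Z, seed = 12)
  expect_identical(Xc, Xm)

  expect_error(simulate_accuracy("weibull", ps, itc, Z), "should be one of")
})

test_that("quadratic accuracy peaks near -beta1/(2 beta2)", {
  # alpha = 0 so the curve is a pure function of z; N = 50,000
  n <- 5e4
  ps <- list(theta = rep(0, n), tau = rep(0, n))
  Z <- matrix(rnorm(n), n, 1)
  b1 <- 0.4; b2 <- -0.4
  it <- list(alpha = cbind(0, 0, 0), beta = cbind(0.5, b1, b2))
  X <- simulate_accuracy("quadratic", ps, it, Z, seed = 13)
  bins <- cut(Z[, 1], breaks = seq(-2, 2, by = 0.25))
  rate <- tapply(X[, 1], bins, mean)
  mids <- seq(-2 + 0.125, 2 - 0.125, by = 0.25)
  peak <- mids[which.max(rate)]
  expect_lt(abs(peak - (-b1 / (2 * b2))), 0.25 + 1e-9)
})

test_that("log-time covariance has the factor structure", {
  ps <- sample_persons(1e5, default_sigma_p(var_tau = 0.25), seed = 14)
  xi <- c(3, 3.5, 4); sigma <- c(0.3, 0.4, 0.5)
  T <- simulate_times(ps, xi, sigma, seed = 15)
  S <- cov(log(T))
  expect_true(all(abs(diag(S) - (sigma^2 + 0.25)) < 0.01))
  off <- S[upper.tri(S)]
  expect_true(all(abs(off - 0.25) < 0.01))
})

test_that("simulate_dataset is reproducible and writes ground truth", {
  s1 <- simulate_dataset("linear", N = 50, K = 4, seed = 99)
  s2 <- simulate_dataset("linear", N = 50, K = 4, seed = 99)
  expect_identical(s1$data$X, s2$data$X)
  expect_identical(s1$data$T, s2$data$T)

  dir <- withr::local_tempdir()
  paths <- write_simulation(s1, dir)
  expect_true(all(file.exists(paths)))
  tr <- jsonlite::fromJSON(paths[["truth"]])
  expect_equal(tr$xi, s1$truth$items$xi)
  d2 <- read_dataset(paths[["x"]], paths[["t"]])
  expect_equal(d2$X, s1$data$X)
})
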