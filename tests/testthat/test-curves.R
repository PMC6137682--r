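test_that("kernel weights follow the bandwidth formula", {
  z <- c(-1, 0, 0.5, 1)
  expect_equal(kernel_weights(z, F_j = 0.5)[3], 1)       # zero distance
  w <- kernel_weights(c(-0.5, 0.5), F_j = 0)             # even kernel
  expect_equal(w[1], w[2])
  # reference constants: h = 1.1, N = 4632, |z - F| = 0.5
  w0 <- kernel_weights(0.5, F_j = 0, h = 1.1, N = 4632)
  expect_equal(w0, exp(-0.25 / (2 * (1.1 * 4632^(-1 / 5))^2)))
  expect_equal(w0, 0.049, tolerance = 0.01)
})

test_that("weighted likelihood reduces to the plain 2PNO marginal likelihood", {
  set.seed(51)
  N <- 40; K <- 3
  th <- rnorm(N)
  a <- c(1, 1.3, 0.7); b <- c(-0.5, 0.2, 0.6)
  X <- matrix(rbinom(N * K, 1, pnorm(outer(th, a) + rep(b, each = N))), N, K)
  rsp <- list(alpha_star = matrix(a, N, K, byrow = TRUE),
              beta_star = matrix(b, N, K, byrow = TRUE))
  ll <- weighted_item_loglik(a[1], b[1], X, 1, rsp, w = rep(1, N))
  # brute-force trapezoid integration over theta on [-8, 8]
  gr <- seq(-8, 8, by = 1e-3)
  wt <- rep(1e-3, length(gr)); wt[c(1, length(gr))] <- 5e-4
  ll_bf <- 0
  for (p in seq_len(N)) {
    f <- dnorm(gr)
    for (k in seq_len(K)) f <- f * psi_prob(a[k] * gr + b[k], X[p, k])
    ll_bf <- ll_bf + log(sum(f * wt))
  }
  expect_equal(ll, ll_bf, tolerance = 1e-6)

  # zero weights: the target item drops out entirely
  l0a <- weighted_item_loglik(0.5, -2, X, 1, rsp, w = rep(0, N))
  l0b <- weighted_item_loglik(3, 2, X, 1, rsp, w = rep(0, N))
  expect_equal(l0a, l0b, tolerance = 1e-10)

  # K = 1, unit weights, zero slope: integral collapses to Bernoulli
  X1 <- X[, 1, drop = FALSE]
  rsp1 <- list(alpha_star = rsp$alpha_star[, 1, drop = FALSE],
               beta_star = rsp$beta_star[, 1, drop = FALSE])
  l1 <- weighted_item_loglik(0, 0.3, X1, 1, rsp1, w = rep(1, N))
  expect_equal(l1, sum(X1 * log(pnorm(0.3)) + (1 - X1) * log(1 - pnorm(0.3))),
               tolerance = 1e-9)
})

test_that("interpolation is exact at knots and clamped outside", {
  gr <- focal_grid(points = c(-1, 0, 1, 2))
  ar <- c(0.5, 1, 1.5, 1.2); br <- c(-1, 0, 0.4, 0.1)
  at_knot <- interpolate_params(0, ar, br, gr)
  expect_equal(at_knot$alpha, 1); expect_equal(at_knot$beta, 0)
  mid <- interpolate_params(0.5, ar, br, gr)
  expect_equal(mid$alpha, mean(ar[2:3])); expect_equal(mid$beta, mean(br[2:3]))
  out <- interpolate_params(7, ar, br, gr)
  expect_equal(out$alpha, ar[4]); expect_equal(out$beta, br[4])
  lo <- interpolate_params(-9, ar, br, gr)
  expect_equal(lo$beta, br[1])
  # continuity across a knot
  eps <- 1e-9
  expect_equal(interpolate_params(1 - eps, ar, br, gr)$beta,
               interpolate_params(1 + eps, ar, br, gr)$beta, tolerance = 1e-6)
})

test_that("fit_2pno recovers item parameters on CI data", {
  sim <- simulate_dataset("ci", N = 2000, K = 10, seed = 52)
  f <- fit_2pno(sim$data$X)
  expect_gt(cor(f$beta, sim$truth$items$beta[, 1]), 0.95)
  expect_gt(cor(f$alpha, sim$truth$items$alpha[, 1]), 0.7)
  expect_lt(mean(abs(f$beta - sim$truth$items$beta[, 1])), 0.12)
})

test_that("curve estimates sit at a maximum of the weighted likelihood", {
  sim <- simulate_dataset("linear", N = 300, K = 4, seed = 53)
  rtf <- fit_lognormal_rt(sim$data$T)
  Zh <- standardized_residuals(sim$data$T, rtf)
  cur <- estimate_curves(sim$data$X, Zh)
  expect_true(all(is.finite(cur$alpha_curve)))
  expect_equal(dim(cur$alpha_curve), c(4L, 9L))
  rsp <- list(alpha_star = cur$alpha_star, beta_star = cur$beta_star)
  for (i in c(1, 3)) {
    j <- 5  # central focal point, well supported
    w <- kernel_weights(Zh[, i], focal_grid()$points[j])
    f0 <- weighted_item_loglik(cur$alpha_curve[i, j], cur$beta_curve[i, j],
                               sim$data$X, i, rsp, w)
    for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
      fd <- weighted_item_loglik(cur$alpha_curve[i, j] + d[1],
                                 cur$beta_curve[i, j] + d[2],
                                 sim$data$X, i, rsp, w)
      expect_lte(fd, f0 + 1e-4)
    }
  }
})

test_that("curves recover a linear intercept effect", {
  K <- 6
  items <- list(alpha = cbind(rep(1, K), 0),
                beta = cbind(seq(-0.5, 0.5, length.out = K), 0.4),
                xi = rep(3.5, K), sigma = rep(0.4, K))
  sim <- simulate_dataset("linear", N = 2000, K = K, seed = 54, items = items)
  rtf <- fit_lognormal_rt(sim$data$T)
  Zh <- standardized_residuals(sim$data$T, rtf)
  cur <- estimate_curves(sim$data$X, Zh)
  slopes <- apply(cur$beta_curve, 1, function(b) coef(lm(b ~ focal_grid()$points))[2])
  expect_lt(abs(mean(slopes) - 0.4), 0.15)
})

test_that("low-information focal points are flagged, not hidden", {
  sim <- simulate_dataset("ci", N = 60, K = 3, seed = 55)
  rtf <- fit_lognormal_rt(sim$data$T)
  Zh <- standardized_residuals(sim$data$T, rtf)
  cur <- estimate_curves(sim$data$X, Zh)
  # N = 60 leaves the +/-2 tails data-starved
  expect_true(any(cur$low_info))
  df <- as.data.frame(cur)
  expect_named(df, c("item", "focal_point", "alpha", "beta", "sum_weights", "low_info"))
  expect_equal(nrow(df), 3 * 9)
})

test_that("curve estimation is invariant to item relabeling", {
  sim <- simulate_dataset("linear", N = 500, K = 5, seed = 56)
  rtf <- fit_lognormal_rt(sim$data$T)
  Zh <- standardized_residuals(sim$data$T, rtf)
  ord <- c(4, 2, 5, 1, 3)
  c1 <- estimate_curves(sim$data$X, Zh)
  c2 <- estimate_curves(sim$data$X[, ord], Zh[, ord])
  # sweep order differs, so agreement is to the convergence tolerance scale
  expect_lt(max(abs(c2$beta_curve - c1$beta_curve[ord, ])), 0.05)
  expect_lt(max(abs(c2$alpha_curve - c1$alpha_curve[ord, ])), 0.05)
})
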