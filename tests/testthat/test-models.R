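test_that("probit argument of zero gives probability one half", {
  expect_equal(icc_probability("ci", list(alpha = 1, beta = 0), theta = 0), 0.5)
  expect_equal(icc_probability("linear", list(alpha = c(1, 0.5), beta = c(0, 0.3)),
                               theta = 0, z = 0), 0.5)
  expect_equal(icc_probability("quadratic",
                               list(alpha = c(1, 0.5, -0.2), beta = c(0, 0.3, -0.1)),
                               theta = 0, z = 0), 0.5)
  # baseline category with zero baseline intercept
  expect_equal(icc_probability("multicat",
                               list(alpha = c(1, rep(0.4, 4)), beta = c(0, rep(-0.3, 4))),
                               theta = 0, z = 0), 0.5)
})

test_that("nested model kinds agree on a parameter grid", {
  th <- seq(-3, 3, length.out = 20)
  zz <- seq(-2.5, 2.5, length.out = 20)
  g <- expand.grid(theta = th, z = zz)
  pl <- icc_probability("linear", list(alpha = c(1.2, 0.4), beta = c(-0.3, 0.6)),
                        g$theta, g$z)
  pq <- icc_probability("quadratic",
                        list(alpha = c(1.2, 0.4, 0), beta = c(-0.3, 0.6, 0)),
                        g$theta, g$z)
  expect_equal(pq, pl, tolerance = 1e-12)
  pc <- icc_probability("ci", list(alpha = 1.2, beta = -0.3), g$theta, 0 * g$z)
  pl0 <- icc_probability("linear", list(alpha = c(1.2, 0), beta = c(-0.3, 0)),
                         g$theta, g$z)
  expect_equal(pl0, pc, tolerance = 1e-12)
})

test_that("quadratic curve peaks where the vertex formula says", {
  b1 <- 0.5; b2 <- -0.35
  zgrid <- seq(-3, 3, by = 0.001)
  p <- icc_probability("quadratic", list(alpha = c(1, 0, 0), beta = c(0.2, b1, b2)),
                       theta = 0, z = zgrid)
  expect_lt(abs(zgrid[which.max(p)] - (-b1 / (2 * b2))), 0.0011)
})

test_that("multicat uses the category the residual falls in", {
  item <- list(alpha = c(1, 0.1, 0.2, 0.3, 0.4), beta = c(0, -0.5, -0.2, 0.2, 0.5))
  thr <- c(-1.5, -0.5, 0.5, 1.5)
  # z = -2 -> category 1 (first contrast), z = 0 -> baseline (cat 3)
  expect_equal(icc_probability("multicat", item, theta = 1, z = -2, thr),
               pnorm((1 + 0.1) * 1 + (0 - 0.5)))
  expect_equal(icc_probability("multicat", item, theta = 1, z = 0, thr),
               pnorm(1))
  expect_equal(icc_probability("multicat", item, theta = 1, z = 2, thr),
               pnorm((1 + 0.4) * 1 + (0 + 0.5)))
})

test_that("bivariate-normal conditioning matches the linear reparameterization", {
  # rho = 0: conditional probability is the CI probability
  expect_equal(bvn_conditional_prob(0.7, 0.1, 1, 0.2, 1, 0.5, 0, 2),
               icc_probability("ci", list(alpha = 1, beta = 0.2), 0.7))
  rho <- 0.3
  a <- 1; b <- 0; xi <- 1; sig <- 0.5
  p1 <- bvn_conditional_prob(0, 0, a, b, xi, sig, rho, exp(1))
  s <- sqrt(1 - rho^2)
  p2 <- icc_probability("linear",
                        list(alpha = c(a / s, 0), beta = c(b / s, rho / s)),
                        theta = 0, z = (1 - xi + 0) / sig)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(bvn_conditional_prob(0, 0, 1, 0, 1, 0.5, 1.2, 1), "rho")
})

test_that("conditional probability integrates the joint density (quadrature oracle)", {
  theta <- 0.4; tau <- -0.2; a <- 1.1; b <- -0.1; xi <- 1.2; sig <- 0.6; rho <- 0.35
  tstar <- 0.9                       # a value of ln t
  z <- (tstar - xi + tau) / sig
  # numeric integral over x* > 0 of the bivariate normal density at t* fixed
  xs <- seq(0, 12, by = 1e-3)
  mu <- c(a * theta + b, xi - tau)
  Sg <- matrix(c(1, rho * sig, rho * sig, sig^2), 2, 2)
  Si <- solve(Sg)
  dens <- function(x1, x2) {
    q <- Si[1, 1] * (x1 - mu[1])^2 + 2 * Si[1, 2] * (x1 - mu[1]) * (x2 - mu[2]) +
      Si[2, 2] * (x2 - mu[2])^2
    exp(-q / 2) / (2 * pi * sqrt(det(Sg)))
  }
  num <- sum(dens(xs, tstar)) * 1e-3 - 0.5e-3 * dens(0, tstar)  # trapezoid
  marg <- dnorm(tstar, xi - tau, sig)
  pcond <- bvn_conditional_prob(theta, tau, a, b, xi, sig, rho, exp(tstar))
  expect_equal(num / marg, pcond, tolerance = 1e-6)
})

test_that("joint density is a proper density in the accuracy margin", {
  item <- list(alpha = c(1, 0.3, -0.1), beta = c(0.2, 0.4, -0.2), xi = 1, sigma = 0.5)
  for (t in c(0.5, 2, 8)) {
    tot <- joint_density("quadratic", item, 1, t, 0.3, -0.1) +
      joint_density("quadratic", item, 0, t, 0.3, -0.1)
    expect_equal(tot, dnorm(log(t), 1 - (-0.1), 0.5) / t, tolerance = 1e-12)
  }
})
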