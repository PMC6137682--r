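# Model-kind machinery: basis expansions of the residual log response time
# z and the probit ICC for all four model kinds.
#
# Every model writes the probit argument as
#   eta = (alpha . b(z)) * theta + (beta . b(z)),
# where b(z) is a model-specific basis of length B:
#   ci:        b = (1)                                   B = 1
#   linear:    b = (1, z)                                B = 2
#   quadratic: b = (1, z, z^2)                           B = 3
#   multicat:  b = (1, 1[cat=k] for each k != m)         B = M
# For multicat, alpha[1]/beta[1] are the baseline-category parameters and the
# remaining entries are additive contrasts for the non-baseline categories in
# ascending category order.

MODEL_KINDS <- c("ci", "linear", "quadratic", "multicat")

model_basis_dim <- function(model, M = 5L) {
  switch(model, ci = 1L, linear = 2L, quadratic = 3L, multicat = as.integer(M),
         stop("unknown model kind: ", model, call. = FALSE))
}

# z values -> category indices 1..M given ascending thresholds (length M-1);
# shape of z is preserved
z_category <- function(z, thresholds) {
  out <- findInterval(z, thresholds) + 1L
  dim(out) <- dim(z)
  out
}

# List of basis matrices/vectors, each the shape of z.
basis_list <- function(z, model, thresholds = NULL, baseline = NULL) {
  one <- z * 0 + 1
  switch(model,
    ci = list(one),
    linear = list(one, z),
    quadratic = list(one, z, z * z),
    multicat = {
      M <- length(thresholds) + 1L
      cat <- z_category(z, thresholds)
      out <- vector("list", M)
      out[[1]] <- one
      j <- 1L
      for (k in seq_len(M)) {
        if (k == baseline) next
        j <- j + 1L
        ind <- (cat == k) * 1
        dim(ind) <- dim(z)
        out[[j]] <- ind
      }
      out
    },
    stop("unknown model kind: ", model, call. = FALSE))
}

# N x K slope and intercept surfaces from K x B coefficient matrices.
# A, C: K x B matrices of alpha / beta coefficients.
predictor_surfaces <- function(z, A, C, model, thresholds = NULL, baseline = NULL) {
  bl <- basis_list(z, model, thresholds, baseline)
  S <- sweep(bl[[1]], 2, A[, 1], "*")
  I <- sweep(bl[[1]], 2, C[, 1], "*")
  if (length(bl) > 1) {
    for (b in 2:length(bl)) {
      S <- S + sweep(bl[[b]], 2, A[, b], "*")
      I <- I + sweep(bl[[b]], 2, C[, b], "*")
    }
  }
  list(slope = S, intercept = I)
}

# N x K probit argument given theta (length N) and z (N x K).
eta_matrix <- function(z, theta, A, C, model, thresholds = NULL, baseline = NULL) {
  s <- predictor_surfaces(z, A, C, model, thresholds, baseline)
  s$slope * theta + s$intercept
}

#' ICC success probability under a conditional (in)dependence model
#'
#' Probability of a correct response given ability \code{theta} and residual
#' log response time \code{z}, i.e. \eqn{\Phi(\eta)} with the probit argument
#' \eqn{\eta} determined by the model kind:
#' \describe{
#'   \item{ci}{\eqn{\alpha_0\theta + \beta_0}}
#'   \item{linear}{\eqn{(\alpha_0+\alpha_1 z)\theta + \beta_0+\beta_1 z}}
#'   \item{quadratic}{\eqn{(\alpha_0+\alpha_1 z+\alpha_2 z^2)\theta +
#'     \beta_0+\beta_1 z+\beta_2 z^2}}
#'   \item{multicat}{baseline parameters plus the contrast of the category
#'     that \code{z} falls in.}
#' }
#' The probit argument is clipped to \eqn{\pm 8} before evaluation, so the
#' value is always inside (0, 1).
#'
#' @param model one of \code{"ci"}, \code{"linear"}, \code{"quadratic"},
#'   \code{"multicat"}.
#' @param item list with numeric vectors \code{alpha} and \code{beta} of the
#'   model's basis length (see Details above for coefficient order).
#' @param theta ability value(s).
#' @param z residual log response time value(s), recycled against theta.
#' @param thresholds ascending category thresholds (multicat only).
#' @param baseline baseline category index (multicat only).
#' @return success probabilities, shaped like \code{theta * z}.
#' @export
icc_probability <- function(model, item, theta, z = 0,
                            thresholds = c(-1.5, -0.5, 0.5, 1.5),
                            baseline = NULL) {
  model <- match.arg(model, MODEL_KINDS)
  M <- length(thresholds) + 1L
  if (model == "multicat" && is.null(baseline)) baseline <- (M + 1L) %/% 2L
  B <- model_basis_dim(model, M)
  stopifnot(length(item$alpha) == B, length(item$beta) == B)
  shp <- theta + z  # recycling template
  z <- z + 0 * shp; theta <- theta + 0 * shp
  bl <- basis_list(z, model, thresholds, baseline)
  slope <- 0; inter <- 0
  for (b in seq_along(bl)) {
    slope <- slope + item$alpha[b] * bl[[b]]
    inter <- inter + item$beta[b] * bl[[b]]
  }
  pnorm(clip_probit(slope * theta + inter))
}

#' Conditional success probability under the bivariate-normal joint model
#'
#' Analytic oracle for the equivalence between the bivariate-normal joint
#' model for (augmented accuracy, log time) with conditional correlation
#' \eqn{\rho} and the linear conditional dependence model: conditioning the
#' bivariate normal on the observed time gives
#' \deqn{P(x = 1 \mid t) = \Phi\left(\frac{\alpha\theta + \beta + \rho z}
#'   {\sqrt{1-\rho^2}}\right), \quad z = \frac{\ln t - \xi + \tau}{\sigma}.}
#'
#' @param theta ability; @param tau speed.
#' @param alpha,beta ICC slope and intercept.
#' @param xi time intensity; @param sigma residual log-time SD (> 0).
#' @param rho conditional correlation, |rho| < 1.
#' @param t observed response time (> 0).
#' @return conditional probability of a correct response.
#' @export
bvn_conditional_prob <- function(theta, tau, alpha, beta, xi, sigma, rho, t) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  z <- (log(t) - xi + tau) / sigma
  pnorm((alpha * theta + beta + rho * z) / sqrt(1 - rho^2))
}

#' Joint density of (accuracy, time) given the latent variables
#'
#' \eqn{f(x, t \mid \theta, \tau) = \Psi(\eta(z), x) \cdot
#' \mathrm{lnN}(t; \xi - \tau, \sigma^2)} with \eqn{z = (\ln t - \xi +
#' \tau)/\sigma} and \eqn{\eta} the model-kind probit argument.
#'
#' @inheritParams icc_probability
#' @param x accuracy in \{0,1\}; @param t time (> 0); @param tau speed.
#' @param log if TRUE return the log density.
#' @return (log) density values.
#' @export
joint_density <- function(model, item, x, t, theta, tau,
                          thresholds = c(-1.5, -0.5, 0.5, 1.5),
                          baseline = NULL, log = FALSE) {
  stopifnot(all(t > 0), item$sigma > 0)
  z <- (base::log(t) - item$xi + tau) / item$sigma
  p <- icc_probability(model, item, theta, z, thresholds, baseline)
  la <- x * base::log(p) + (1 - x) * base::log1p(-p)
  lt <- dnorm(base::log(t), mean = item$xi - tau, sd = item$sigma, log = TRUE) - base::log(t)
  out <- la + lt
  if (log) out else exp(out)
}
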