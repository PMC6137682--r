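---
title: "Modeling conditional dependence between response time and accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conditional dependence between response time and accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Computerized tests record, for person $p$ and item $i$, a binary accuracy
$x_{pi}$ and a response time $t_{pi}$.  The hierarchical framework for these
data combines a two-parameter normal-ogive (2PNO) accuracy model,

$$\Pr(X_{pi} = 1 \mid \theta_p) = \Phi(\alpha_i \theta_p + \beta_i),$$

with a log-normal time model,

$$\ln t_{pi} \sim N(\xi_i - \tau_p,\ \sigma_i^2),$$

where $\theta_p$ is ability, $\tau_p$ speed, $\xi_i$ the item's time
intensity and $1/\sigma_i^2$ its time discrimination.  The latent pair
$(\theta_p, \tau_p)$ is bivariate normal with zero means and unit ability
variance (identification), and the item parameter vectors are themselves
multivariate normal across items.  Under *conditional independence* (CI),
accuracy and time on the same item are linked only through
$\mathrm{cor}(\theta, \tau)$.

That assumption often fails, and the failure is informative: a response can
be unusually fast or slow *for that person on that item*, measured by the
standardized residual log response time

$$z_{pi} = \frac{\ln t_{pi} - (\xi_i - \tau_p)}{\sigma_i}.$$

This package models the ICC slope and intercept as functions of $z_{pi}$,
in four nested ways:

* **ci** — no dependence (baseline);
* **linear** — $(\alpha_{i0} + \alpha_{i1} z)\theta + \beta_{i0} + \beta_{i1} z$,
  equivalent to a bivariate-normal model for the augmented accuracy and log
  time with conditional correlation $\rho_i$
  ($\alpha' = \alpha/\sqrt{1-\rho^2}$, $\beta_1' = \rho/\sqrt{1-\rho^2}$,
  verified to $10^{-12}$ in the test suite);
* **quadratic** — adds $\alpha_{i2} z^2$ and $\beta_{i2} z^2$; with
  $\beta_{i2} < 0$ the intercept is maximized at $z = -\beta_{i1}/(2\beta_{i2})$,
  so the model can express "responses at the expected speed are most often
  correct";
* **multicat** — $z$ is cut into $M$ ordered categories at fixed thresholds
  (default $-1.5, -0.5, 0.5, 1.5$, i.e. $M = 5$, symmetric and one residual
  SD apart), each non-baseline category carrying additive slope/intercept
  contrasts relative to the middle (baseline) category.  Unlike median-split
  fast/slow approaches, categorizing the *residual* keeps the conditional
  dependence separate from the speed-ability correlation, and time itself
  stays continuous in the likelihood.

## Estimation

`run_gibbs()` estimates any of the four joint models by
Metropolis-within-Gibbs with probit data augmentation:

* latent continuous accuracies $x^*_{pi}$ have truncated-normal full
  conditionals, which makes the per-item coefficient vectors conjugate
  normal given $z$;
* $(\theta_p, \tau_p)$ is updated jointly by random-walk Metropolis against
  the observed-data likelihood — the dependence of $z$ on $\tau$ through the
  accuracy side breaks conjugacy, so $z$ is recomputed from the current
  draws at every step rather than treated as a fixed covariate;
* $(\xi_i, \ln\sigma_i)$ likewise by random-walk Metropolis;
* the unit ability variance is enforced by a parameter-expansion step: an
  unconstrained inverse-Wishart draw of the person covariance is rescaled,
  with the slope coefficients compensated, so the constraint holds exactly
  in every retained draw;
* two directional Gibbs moves resample the likelihood-flat locations — a
  common shift of all $(\tau_p, \xi_i)$ and a shift of all $\theta_p$ with
  intercepts compensated by $-e\,\alpha_i$ — from their exact Gaussian
  conditionals.  Random-walk steps alone mix these common modes at rate
  $O(1/N)$, which freezes the time intensities near their starting offset
  and makes their credible intervals dishonestly narrow; with the moves the
  interval for $\xi_i$ correctly carries the $\mathrm{SD} \approx
  \sqrt{1/(N \cdot [\Sigma_P^{-1}]_{\tau\tau})}$ location uncertainty;
* item hyper-parameters $(\mu_I, \Sigma_I)$ get conjugate
  normal/inverse-Wishart updates.

Proposal scales adapt toward roughly 35% acceptance during burn-in only
(so the post-burn-in chain is a fixed Markov kernel).  Priors are weakly
informative: $\mu_I \sim N(0, 100^2)$, $\Sigma_I \sim IW(I, \dim + 2)$,
$\ln\sigma_i \sim N(0, 5^2)$.  The reference analysis used 10,000
iterations with 5,000 burn-in; those are the package defaults
(`default_config()`), while tests run shorter chains.

Model comparison uses the modified BIC: $-2\ell + P \ln N$ with the
marginal likelihood $\ell$ evaluated by two-dimensional Gauss–Hermite
quadrature (31 nodes per dimension; agrees with brute-force grid
integration to $10^{-6}$ relative error in the tests) at the *posterior
means* of the parameters.  $P$ counts the per-item vectors
($3K$, $5K$, $7K$, $(2M{+}1)K$), so the increments over CI are $2K$, $4K$
and $2(M{-}1)K$.  Whether the penalty should use persons or observations is
not settled; persons is the default and the argument is explicit.

## Nonparametric moderation

`estimate_curves()` estimates $\alpha_{ji}, \beta_{ji}$ at focal points
$F_1 < \dots < F_J$ of the *estimated* residual $\hat z_{pi}$ (default
$-2$ to $2$ by $0.5$).  This is a two-step method: first
`fit_lognormal_rt()` fits the time model alone by marginal ML — the
equal-loadings factor structure makes $\hat\xi_i$ the column means of
$\ln T$ exactly, the variance components come from a monotone EM, and
$\hat\tau_p$ are regression-method factor scores — then
`standardized_residuals()` plugs the estimates into the defining formula.
$\hat z$ is *not* re-standardized empirically afterwards; comparability
across focal points relies on the model-based scale.

Each person's response to item $i$ is weighted by a Gaussian kernel
$w_{pji} = \exp(-(\hat z_{pi} - F_j)^2 / (2 (h N^{-1/5})^2))$ with
bandwidth factor $h = 1.1$, and $(\alpha_{ji}, \beta_{ji})$ maximizes the
weighted marginal likelihood in which the other items enter through
response-specific parameters $\alpha^*_{pk}, \beta^*_{pk}$ — themselves
refreshed after each item by piecewise-linear interpolation of that item's
curve at $\hat z_{pk}$ (nearest-endpoint beyond the focal range).  Sweeps
run over items in index order, focal points left to right.

Numerical choices (the procedure's stopping rule and optimizer are not
pinned down by its description, so these are this package's commitments):

* 61-point Gauss–Hermite quadrature for the weighted likelihood — the
  fractional powers $\Psi^w$ make the integrand less smooth than in
  standard IRT;
* per focal point, a damped projected Newton ascent in
  $(\alpha, \beta) \in [0.01, 5] \times [-6, 6]$ with analytic
  gradient/Hessian and a gradient fallback when the Hessian is indefinite,
  warm-started from the previous sweep (chosen over a derivative-free
  search for speed — the permutation and posterior-predictive loops re-run
  this estimator hundreds of times — with maximality verified against the
  pure-R likelihood by perturbation tests);
* the bulk per-sweep $\log\Phi$ evaluations use a $10^{-3}$-step lookup
  table with linear interpolation (error $\sim 3\times 10^{-7}$ in log
  space, negligible against the $10^{-3}$ sweep tolerance); the optimizer
  itself and all reference likelihood computations use exact tails;
* convergence when the largest absolute change in any curve estimate is
  below $10^{-3}$, with at most 20 sweeps;
* initialization at CI 2PNO estimates from a fast marginal-ML EM
  (`fit_2pno()`), not from MCMC, for speed;
* focal points with total kernel weight below 25 are flagged
  `low_info` rather than suppressed — tail focal points can be
  data-starved;
* probit arguments are clipped to $\pm 8$ throughout the likelihood code
  (probability error below $10^{-15}$).

## Tests of conditional dependence

`permutation_test()` shuffles each item's residual column independently
across persons (accuracies untouched), re-estimates the curves, and
compares the variance of each curve across focal points with its
permutation distribution; $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(n_{\text{perm}} + 1)$, the add-one correction guaranteeing validity.  The
description of the reference procedure ("residual log-transformed response
times randomly assigned to different persons") is ambiguous between
per-item and whole-row permutation; per-item is implemented because it
preserves each item's residual marginal exactly.

`ppc_linearity()` checks the *linearity* assumption: given a fitted linear
conditional dependence model, every 10th retained draw generates a full
replicate dataset (times and accuracies, using that draw's person
parameters), and the complete two-step pipeline — time-model fit,
residuals, 2PNO initialization, curve estimation — is re-run on each
replicate, so the reference distribution carries the same estimation noise
as the observed analysis.  The discrepancy per item and parameter is the
maximum absolute cumulative sum of OLS residuals of the curve regressed on
the focal points (zero for an exactly linear curve, invariant to adding
any linear trend); cells with posterior predictive $p < 0.05$ are flagged.

## The synthetic-data generator

There is no public reference dataset (the motivating application is a
proprietary high-stakes arithmetic test: 38 items, 4,632 persons), so
`simulate_dataset()` generates data with exactly the generative structure
above and serves as the ground truth for recovery tests.  Its fixed
defaults describe a realistic operational ability test:

* $N = 3000$, $K = 20$ — comparable information per item to the
  motivating application at desk-scale runtime;
* $\mathrm{Var}(\tau) = 0.25$, $\mathrm{cor}(\theta, \tau) = 0.3$ — speed
  spreads much less than log-time noise and correlates moderately with
  ability;
* item hyper-means: baseline slopes around 1 (SD 0.25), baseline
  intercepts around 0 (SD 0.7), time intensities around $\ln 45$ s
  (SD 0.4), residual log-time SDs around 0.4 (drawn on the log scale, so
  positivity needs no truncation);
* quadratic effects centre on $(-0.02, -0.09)$ with variance $0.03$ — the
  hyper-parameter estimates reported for the motivating application —
  and linear/categorical effects centre on 0 with SDs 0.2–0.3.

Items can also be supplied explicitly (recovery studies need fixed
truths).  What the generator does *not* emulate: missing responses,
within-person speed drift, item-specific time-discrimination loadings,
nonlinear dependence between speed and ability at the higher level, or
guessing floors.  A green recovery test therefore establishes correctness
of the estimation machinery under the stated model, not robustness to
misspecification.

## Scale choices in the acceptance tests

The acceptance suite (one test per criterion in
`tests/testthat/test-acceptance.R`) must finish on one CPU in about
25 minutes, whereas the criteria's own runtime estimates sum to well over
an hour.  Criterion-stated quantities are kept exactly — recovery at
$N = 3000$, $K = 20$ with 2,000 iterations and 1,000 burn-in; 200
permutations; 100 posterior-predictive replicates; all thresholds and
tolerances — and only dataset sizes the criteria leave open were fixed
once for budget: $N = 150$ per dataset (10 datasets, both parameters
pooled, 200 rejection trials) for permutation calibration — the validity of
a permutation test does not depend on $N$ — $N = 400$ for
posterior-predictive calibration and $N = 1000$ for its power condition.
These were chosen from runtime measurements before the criteria were
evaluated and are not revisited.

## Known limitations

* Missing responses are rejected, not modeled.
* The permutation test's per-item null assumes the estimated residuals are
  exchangeable across persons under CI; estimation error in
  $\hat\tau_p$ makes this approximate (and is why calibration is itself a
  tested property).
* The multiple-category model's outer categories hold a few percent of the
  responses each, so their contrasts are estimated with visibly more noise
  than inner ones.
* The exact priors of the reference Gibbs samplers are unavailable; the
  ones above are replacements, and posterior summaries for weakly
  identified hyper-parameters may differ from the reference
  implementation's.
* No bandwidth selection: $h = 1.1$ is fixed, as in the indicator-level
  moderation literature.

## A worked example

```{r, eval = FALSE}
library(rtcondep)

sim <- simulate_dataset("quadratic", N = 3000, K = 20, seed = 1)
fit <- run_gibbs(sim$data, default_config(model = "quadratic",
                                          n_iter = 2000, burn_in = 1000))
pm <- posterior_mean_params(fit)
m2ll <- minus2_loglik(sim$data, "quadratic", pm)
modified_bic(m2ll, count_params("quadratic", 20), 3000)

rtf <- fit_lognormal_rt(sim$data$T)
zh <- standardized_residuals(sim$data$T, rtf)
curves <- estimate_curves(sim$data$X, zh)
permutation_test(sim$data$X, zh, n_perm = 500, seed = 2)$results
```
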