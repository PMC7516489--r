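---
title: "Fully Bayesian multi-fidelity Gaussian process regression: model and methods"
author: "mufigp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fully Bayesian multi-fidelity Gaussian process regression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mufigp)
```

## The model

`mufigp` fuses simulator outputs of several fidelity levels
$t = 1, \dots, N_t$ (level 1 cheapest, level $N_t$ most accurate) through
the first-order autoregressive (co-kriging) recursion

$$z_1(x) = \delta_1(x), \qquad
  z_t(x) = \rho_{t-1}\, z_{t-1}(x) + \delta_t(x) \quad (t \ge 2),$$

where each *difference process* $\delta_t$ is an independent Gaussian
process with a parametric trend and a scaled correlation kernel,

$$\delta_t \sim \mathcal{GP}\!\left(h_t(x)\,\beta_t,\;
  \sigma_t^2\, k_t(x, x'; \alpha_t)\right).$$

The trend basis $h_t$ consists of $N_{\beta t}$ Legendre polynomials
("order $n$" means $n$ basis functions, degrees $0..n\!-\!1$) evaluated
after an affine map of each input dimension onto $[-1, 1]$; for
multi-dimensional inputs the tensor basis is truncated by total degree and
ordered by (total degree, lexicographic multi-index), so the column order
is deterministic. The kernel is the isotropic squared exponential
$k(x, x') = \exp(-\alpha \|x - x'\|^2)$ on the rescaled coordinates, with
$\alpha$ the inverse squared correlation length; there is deliberately no
factor $1/2$ in the exponent — the convention follows the verbal
definition of $\alpha$, and the package documents it so results are
comparable.

Training data live on a *nested design*: every pivot of level $t$ must
also be a pivot of level $t-1$ (matched within $10^{-9}$ on rescaled
coordinates), so the previous-level outputs $z_{t-1}(x_t)$ are always
available and are derived internally, never supplied by the user.

## What is marginalized, and how

Rather than optimizing hyperparameters, everything is integrated out.
With flat priors on $\beta_t$ and $\rho_{t-1}$ and Jeffreys' prior
$1/\sigma_t$ on the scale, the integrals over $(\beta, \rho, \sigma)$ are
Gaussian/inverse-gamma and close in terms of a handful of sufficient
statistics per level (at fixed $\alpha_t$):

$$A_t = (H_t' K_t^{-1} H_t)^{-1}, \quad B_t = H_t' K_t^{-1}, \quad
  C_t = K_t^{-1} - B_t' A_t B_t,$$
$$c_t = z_t' C_t z_t, \quad b_t = z_t' C_t z_{t-1}, \quad
  a_t = z_{t-1}' C_t z_{t-1}, \quad
  \gamma_t = \tfrac{N_{xt} - N_{\beta t}}{2}, \quad
  \Phi_t = c_t - b_t^2/a_t,$$

with the level-1 conventions $a_1 = 1$, $b_1 = 0$. The conditional
posterior means are $\bar\rho_{t-1} = b_t/a_t$,
$\bar\beta_t = A_t B_t (z_t - \bar\rho_{t-1} z_{t-1})$,
$E[\rho_{t-1}^2] = \bar\sigma_t^2/a_t + \bar\rho_{t-1}^2$ and

$$\bar\sigma_t^2 = \frac{\Phi_t}{2\gamma_t - 3 + \delta_{t1}}.$$

The denominator deserves a note. On coupled levels ($t \ge 2$) it is
$2\gamma_t - 3$; on level 1, which has no coupling factor and therefore
one analytic integration fewer, it is $2\gamma_t - 2$. Both cases were
locked in by requiring agreement with the package's brute-force quadrature
oracle (below) before any downstream code was written, and the
admissibility constraint that `validate_design()` enforces,

$$N_{\beta 1} < N_{x1} - 2, \qquad N_{\beta t} < N_{xt} - 3 \ (t \ge 2),$$

is exactly positivity of these denominators — violating it leaves the
second moments of $\sigma_t$ undefined, which is also why an 11-pivot
coupled level admits at most 7 trend functions.

Only the kernel hyperparameters $\alpha_t$ remain. Their posterior
factorizes over levels; each per-level factor is, up to the prior,

$$\log p(D_t \mid \alpha_t) = -\log 2 + \log\Gamma(e_t)
  - e_t \log(\pi \Phi_t) - \tfrac{1-\delta_{t1}}{2} \log a_t
  - \tfrac12 \log|K_t| + \tfrac12 \log|A_t|,
  \qquad e_t = \gamma_t - \tfrac{1 - \delta_{t1}}{2},$$

again certified against the oracle including its absolute constant, so the
integral of the density is a genuine marginal likelihood and summing the
per-level log evidences gives the total model evidence used for comparing
trend orders and kernels. `grid_posterior()` integrates each level on a
grid of equally sized cells (midpoint rule; 100 nodes per level by
default, which refinement tests show is converged to well below 1% in the
posterior means), normalizes by log-sum-exp, and warns when more than 5%
of the mass sits in an outermost cell. Because levels are independent the
computation parallelizes trivially; the parallel path is bitwise identical
to the serial one.

Jeffreys' prior on $\alpha$ is improper, so it is truncated to user-set
bounds. The bounds are a *required* input (`alpha_bounds`) — the package
refuses to invent a default because the appropriate range is problem
knowledge, and the boundary-mass warning tells the user when the choice
was too tight.

## Prediction

At fixed $\alpha_t$ the difference-process posterior is the textbook GP
conditioning identity with the plug-in conditional means
$\bar\beta_t, \bar\rho_{t-1}$; the plug-in definition
$\delta_t(x_t) = z_t(x_t) - \bar\rho_{t-1} z_{t-1}(x_t)$ was an open
choice and was adopted because it makes the predictive mean interpolate
the top-level data exactly at zero jitter, which we take as the defining
property of an interpolating surrogate. Predictions mix these conditional
moments over the discretized $\alpha$ posteriors and compose levels
through the recursion:

$$\bar z_{N_t}(x) = \sum_t \langle \bar\delta_t(x) \rangle_{\alpha_t}
  \prod_{l=t}^{N_t-1} \bar\rho_l .$$

For the covariance, the per-level posteriors are independent, so the
covariance of the sum is the sum of per-level covariances,

$$\mathrm{Cov}\big(z_{N_t}(x)\big) = \sum_t \Big[
  \big\langle \bar\sigma_t^2 \Sigma_t + \bar\delta_t \bar\delta_t' \big\rangle_{\alpha_t}
  \textstyle\prod_l E[\rho_l^2]
  - \langle \bar\delta_t \rangle \langle \bar\delta_t \rangle'
  \textstyle\prod_l \bar\rho_l^2 \Big],$$

with no cross-level covariance terms. Two numerical safeguards: the
reported matrix is symmetrized, and for standard deviations its
eigenvalues are clipped at zero (negative diagonal entries can appear at
the $10^{-12}$ level after the moment subtraction); the unclipped matrix
is kept in `covariance_raw` for diagnostics. Credible bands default to
$k = 1$ standard deviation and are configurable.

Two properties are worth knowing. First, trend-coefficient uncertainty
does not enter the predictive variance (only $\bar\beta_t$ appears), so
wide $\beta$ posteriors — normal in small-data regimes — do not blow up
the bands. Second, the factorized treatment neglects the negative
posterior correlation between $\rho$ and the top-level difference
process, so the bands are *conservative*: in the package's own recovery
studies the nominal-68% band covers the truth at roughly 90% of query
points. Tests therefore assert non-under-coverage rather than exact
nominal coverage.

## Numerical choices

* All inverses go through Cholesky factorizations; quadratic forms and
  log-determinants are computed from triangular solves, never from
  explicit inverses of ill-conditioned matrices.
* A failed factorization is retried once at 10 times the jitter, then
  raises a hard error; escalation is recorded.
* **Jitter.** The default nugget is $10^{-8}$ on the diagonal of the
  *unit-diagonal correlation matrix*, i.e. $10^{-8}\sigma_t^2$ in
  covariance units — several orders of magnitude below the process
  variance, as the conditioning advice for this model requires. The
  convention matters more than it looks: at realistic $\alpha$ the SE Gram
  matrix is numerically rank-deficient, so the nugget is effectively part
  of the model, and the synthetic-data generator therefore uses the *same*
  relative nugget. A data-variance-scaled absolute nugget (an alternative
  we rejected) silently makes the generative and fitted models different
  models and visibly biases scale recovery.
* Pivot matching uses absolute tolerance $10^{-9}$ on rescaled
  coordinates; duplicate pivots within a level are design errors.
* Queries more than 10% outside the mapped domain warn (extrapolation)
  but do not error.
* $\Phi_t \le 0$ (a degenerate fit) yields a $-\infty$ log density with a
  warning rather than an exception, so a single bad grid node cannot kill
  a fit.

## The oracle

Every closed form above is certified by `brute_force_level_moments()` /
`brute_force_evidence()`, which integrate the *exact* per-level posterior
(Gaussian likelihood times flat/flat/Jeffreys priors) by iterated
Gauss–Legendre quadrature and share no closed form with the fast path.
Quadrature details: the location parameters are integrated in
$\sigma$-scaled coordinates ($\beta = c + \sigma s v$, a plain change of
variables), which keeps the conditional integrand's width independent of
$\sigma$; $\log\sigma$ is covered by two wide panels to capture the heavy
power-law tail that dominates $E[\sigma^2]$; grids are re-centered on the
computed posterior mass over two adaptive passes; and the final pass
refuses to report if the boundary density exceeds $10^{-4}$ of the peak.
The oracle ships in the package (not only in tests) so users who modify
kernels can re-certify with `certify()` or the `certify` CLI command.

## The synthetic-data generator

`simulate_mufi()` draws each $\delta_t$ jointly at the union of all pivot
sets from its exact multivariate normal law and composes levels through
the recursion; all randomness flows from one seed through per-level
derived streams, so a given level's draw is reproducible independently.
It is first-class, tested code: Monte-Carlo tests check the mean and
covariance of the draws against the stated law, and a
generative-to-inference round trip over 50 replicates checks that
posterior spreads are calibrated.

`mock_scenario()` is the reference recovery setup: two levels on
$[-1,1]$, trends of orders 10 and 4, truth $\sigma = (0.1, 0.01)$,
$\rho_1 = 3$, $\alpha = (10.1, 20.1)$, 11 high-fidelity pivots. The
low-fidelity design size is not dictated by anything — we chose 41
equispaced pivots (every 4th is a high-fidelity pivot), dense enough that
a 10-function trend is admissible with a wide margin; this choice is
flagged in the simulation metadata. Hyperparameter bounds of $[1, 40]$
per level comfortably bracket both truth values.

`icg_fixture()` emulates the *shapes* of an impedance-cardiography
surrogate study — 24 low-fidelity radii (1–24 mm) with 21 time pivots
over one cardiac cycle, 3 high-fidelity radii (5, 11, 18 mm) with 11
nested time pivots — with admittance-like signals: a baseline near
0.03 $\Omega^{-1}$, a systolic bump, and pulse-shape structure carried by
the level-1 GP ($\sigma_1 = 0.004$, $\alpha_1 = 20$) that three radii
cannot resolve on their own. That regime is the fixture's point: the
held-out queries are full time series at radii with *no* high-fidelity
data (8, 14, 21 mm), where the multi-fidelity model's predictive
uncertainty should be — and in the package's tests is — far below that of
a high-fidelity-only GP. The fixture mimics smoothness and shapes only;
it contains no electro-physiology, no finite elements, and no claim of
physical realism, so passing tests say nothing about any particular
simulator.

What the generator does *not* emulate about real multi-fidelity data:
model discrepancy (real level pairs rarely satisfy the autoregressive
relation exactly), input-dependent coupling $\rho(x)$, observation noise,
and non-nested designs. Results on synthetic data are therefore evidence
that the *inference machinery* is correct, not that the model suits any
particular pair of simulators — that question is what the per-level
evidence is for.

## Problem sizes and defaults used in the shipped checks

The test-suite and acceptance-script workloads were sized to what the
method needs, not more: oracle certifications run on an 8 + 6-pivot
two-level instance (quadrature is exponential in the number of location
parameters, and two trend functions per level already exercise every code
path); recovery and band-coverage studies use 50 and 15 replicates of the
reference scenario; grid-convergence checks compare 100 against 200 nodes
per level. A full mock-scenario fit takes well under a second, and the
complete acceptance run under a minute on one core.

## Known limitations

* Only the isotropic squared-exponential kernel is built in; the
  surface is designed so further kernels slot in, after re-certification.
* One hyperparameter per level: multi-hyperparameter kernels would need
  tensor grids (the per-level integrals stay low-dimensional, but the
  package stops at $N_{\alpha t} = 1$).
* No MCMC / nested-sampling backend for richer kernels; grid quadrature
  is the design point, and gradient-based evidence optimization is
  deliberately out of scope.
* Credible bands are conservative (see above).
* Simulation outputs are treated as exact up to jitter: there is no
  heteroscedastic observation-noise model.
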