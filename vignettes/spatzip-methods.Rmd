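---
title: "Spatial joint modeling of zero-inflated disease counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial joint modeling of zero-inflated disease counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatzip)
```

## The problem

Disease-mapping studies model per-region counts `o_i` of a rare outcome
relative to expected counts `E_i` derived from the population at risk,
through a relative risk `theta_i`:

```
o_i ~ Poisson(E_i * theta_i)
log(theta_i) = alpha_O + x_i' delta + gamma_i
```

with a spatial random effect `gamma_i` borrowing strength across
neighboring regions. For rare outcomes — a cancer with a handful of
cases per year over hundreds of administrative units — 50 to 80 percent
of the regions can report zero cases, far more than a Poisson law
predicts. `spatzip` fits the zero-inflated alternatives:

* **type 1 (mixture)**: `P(o_i) = (1 - p_i) 1(o_i = 0) + p_i
  Poisson(o_i; E_i theta_i)` — zeros arise both structurally and by
  Poisson chance;
* **type 0 (hurdle)**: mass `1 - p_i` on zero, and `p_i` times a
  *zero-truncated* Poisson on positive counts — every zero is
  structural;
* **the joint model**: the occurrence indicator `z_i = 1(o_i > 0)` and
  the positive counts are modeled by two likelihoods — Bernoulli and
  zero-truncated Poisson — sharing one spatial field:

```
z_i ~ Bernoulli(p_i)        logit(p_i) = alpha_z + y_i' omega + beta * gamma_i
o_i | z_i = 1 ~ ztPoisson(E_i theta_i)   log(theta_i) = alpha_O + x_i' delta + gamma_i
```

The same `gamma` enters both predictors; the scaling coefficient `beta`
measures how similar the spatial pattern of *occurrence* is to the
spatial pattern of *intensity*. Formally the joint response is the
misaligned `2n x 2` matrix built by `build_joint_response()`: occurrence
indicators in column 1, counts in column 2, each row carrying exactly
one observation.

## Latent spatial models

Two latent models are available for `gamma`.

**BYM**: `gamma = v + u`, with `v ~ N(0, tau_v^-1 I)` unstructured and
`u` an intrinsic CAR (ICAR) field with precision `tau_u Q`, `Q = D - A`
the graph Laplacian. Both precisions get Gamma(1, 0.01) priors. The two
components are not separately interpretable, and the meaning of a prior
on `tau_u` depends on the graph.

**BYM2** (the recommended parameterization):

```
gamma = (1 / sqrt(tau_gamma)) * (sqrt(1 - phi) v + sqrt(phi) u*)
```

where `u*` is the ICAR field *scaled* so that the geometric mean of its
marginal variances (under the per-component sum-to-zero constraint) is
one — `scale_icar()` computes the scaling constant `c` with
`Q* = c Q`. After scaling, `1/tau_gamma` is the generalized marginal
variance of `gamma` whatever the graph, and `phi` in `[0, 1]` is the
fraction of that variance attributed to the spatially structured
component. The implied covariance is
`Var(gamma) = tau_gamma^-1 ((1 - phi) I + phi (Q*)^-)`.

## Penalized-complexity priors

The BYM2 hyperparameters take penalized-complexity (PC) priors, which
place an exponential density on the distance `d = sqrt(2 KLD)` from a
base model and therefore shrink toward it.

* `tau_gamma`: base model is "no random effect" (`sigma = 1/sqrt(tau) =
  0`); the distance is `sigma` itself, so `sigma ~ Exponential(lambda)`
  with `lambda = -log(alpha)/U` from the tail statement
  `P(sigma > U) = alpha`. Default `U = 1`, `alpha = 0.01`.
* `phi`: base model is the purely unstructured field (`phi = 0`). The
  KLD of the BYM2 Gaussian at mixing value `phi` from the base is
  `0.5 * sum_j [phi (xi_j - 1) - log(1 - phi + phi xi_j)]` over the
  eigenvalues `xi_j` of `(Q*)^-`, so the prior is graph-dependent and
  `pc_phi_lambda()` calibrates its rate by root-finding so that
  `P(phi < U) = alpha`. Default `U = 0.5`, `alpha = 2/3`: two thirds of
  the prior mass favors the less-structured half.

Numerical choices worth recording:

* The per-component null eigenvalue of `(Q*)^-` (`xi = 0`, the constant
  direction) is *kept* in the KLD sum, contributing
  `-phi - log(1 - phi)`; `d(phi)` therefore diverges as `phi -> 1`,
  and the density on `phi` is normalized by truncating the exponential
  at the last tabulated distance.
* `d(phi)` is tabulated once per graph on a graded grid — uniform on
  `[0, 0.9]`, log-spaced in `1 - phi` down to `1 - 1e-8` beyond —
  because a uniform grid under-resolves the divergence near 1; with the
  graded grid the quadrature of the density over `[0, 1)` is 1 within
  about `1e-5`. The derivative `d'(phi)` uses centered finite
  differences on the (nonuniform) grid.
* Calibration solves for the rate by bisection to `1e-6` within
  `[1e-6, 1e3]`.

The fixed effects take the priors commonly used with this model family:
`alpha_O` and `delta` get N(mean 0, precision 1e-4); `alpha_z` and
`omega` get N(mean -1, precision 0.2); `beta` gets N(1, 10). We read
"N(1, 10)" as mean 1 and *variance* 10 — a weakly informative prior
centered on "the two processes share the same spatial pattern" — since
a precision of 10 would be far more dogmatic than the stated intent;
the choice is exposed via `fixed_effect_priors(beta_mean, beta_var)`.
In the single-likelihood ZIP families the zero probability is a single
region-constant parameter, `p = inv_logit(alpha_z)` with the same
`alpha_z` prior, matching the region-constant zero probability those
families have in common software implementations.

## Posterior computation

Latent Gaussian models of this kind are usually fitted with integrated
nested Laplace approximations; `spatzip` instead targets the exact
posterior with an adaptive MCMC scheme designed around one observation:
in the eigenbasis of `Q*` (computed once per graph — dense
eigendecomposition, adequate for the few hundred regions typical of
disease mapping), the marginal prior covariance of `gamma` is diagonal,
with per-coordinate variance `((1 - phi) + phi xi_j) / tau_gamma` for
BYM2 and `1/tau_v + xi_j/tau_u` for BYM. The decomposition `(v, u*)` is
therefore integrated out analytically rather than sampled — removing
the funnel-shaped coupling between the latent components and their
hyperparameters — and `u*`/`v` draws are reconstructed exactly from
their Gaussian conditional given `gamma` when requested
(`store_latent = TRUE`).

Each sweep performs:

1. a full-block Metropolis-adjusted Langevin (MALA) update of `gamma`,
   preconditioned by a fixed diagonal mass matrix (Poisson/logistic
   curvature at the initial state plus the diagonal of the initial
   prior precision), step size adapted toward the 0.574 optimal
   acceptance rate;
2. a *centered* random-walk update of the hyperparameters on internal
   scales (`log tau`, `logit phi`, with Jacobians), holding `gamma`;
3. an *ancillary* (interweaved) hyperparameter update holding the
   standardized coordinates `gamma_tilde / sqrt(s2)` fixed, so `gamma`
   rescales with the proposal and the likelihood enters the ratio.
   The centered move mixes well where the data pin `gamma` (regions
   with large counts); the ancillary move mixes well where they do not
   (regions with no occurrence, whose `gamma` is prior-dominated) —
   the interweaving combination is what makes `phi` mix in the joint
   hurdle model, where half the regions carry no count information;
4. a likelihood-invariant level-shift move `(alpha_O + delta, gamma -
   delta, alpha_z + beta delta)` that breaks the near-confounding of
   the intercept with the field's level;
5. component-wise adaptive random walks on the fixed effects.

All adaptation uses diminishing Robbins–Monro weights (`t^-0.6`), every
stochastic entry point takes an explicit seed (global RNG state is
saved and restored), and a fit is bit-reproducible given its seed.
Initialization is data-driven: `alpha_O` from the aggregate
log-rate, `gamma` from clipped crude log risk ratios, `phi = 0.5`,
`tau = 1`.

Convergence reporting uses split-Rhat (chain halves) and Geyer
initial-positive-sequence effective sample sizes; `diagnostics()` flags
parameters with Rhat above 1.05 or ESS below 200.

## Model comparison

`dic()` implements the classical deviance information criterion with
the plug-in at the posterior mean of the likelihood parameters
(`gamma`, fixed effects — on their natural scales). `cpo()` computes
conditional predictive ordinates with the harmonic-mean estimator under
log-sum-exp stabilization, and `log_score()` summarizes them as the
*mean* of `-log CPO_i` within a likelihood. For the joint model both
criteria are sums of the per-likelihood (occurrence and count) values.
The mean convention for LS (rather than the sum) is what places
single-model LS on a per-observation scale of order 1–3 while DIC
scales with `2n` — the scale separation the model-comparison tables
exhibit — and the joint LS could alternatively have been defined as the
mean over the pooled `2n` CPOs; the block-sum reading is used here.

## The simulation study

`scenario()`/`generate_dataset()`/`run_study()` implement the recovery
study. Its conditions are: three risk surfaces (constant `gamma = 0`;
unstructured `gamma_i` i.i.d. N(0, 0.5); structured `gamma` a scaled
ICAR draw with generalized variance 0.5 — i.e. `1/tau_gamma = 0.5` with
`phi` 0 or 1), two zero types, zero proportions `P` in {0.50, 0.70},
expected counts `E` in {1, 5, 15, 60, 200}, occurrence indicators
`z_i ~ Bernoulli(p_i)` with `logit(p_i) = logit(1 - P) + beta_true *
gamma_i` and `beta_true = 1`, and counts zero-truncated Poisson
(hurdle/type 0) or mixture draws (type 1) with mean `E exp(gamma_i)`.
The study graph is a 19x19 rook lattice (361 regions), standing in for
a real administrative adjacency map of comparable size (the recovery
behavior at moderate-to-large `E` is insensitive to which few-hundred-
node planar graph is used); any graph file can be substituted. The
generator emulates the spatial structure, zero mechanism and offset
scale of real registry data, but not covariate effects, irregular
region sizes (heterogeneous `E_i`), or reporting artifacts — passing
recovery tests supports the inference machinery, not those aspects of
real data.

Replicate-averaged posterior means of `(alpha_z, alpha_O, 1/tau_gamma,
phi, beta)` and of `(DIC, LS)` are reported per scenario. Desk-scale
runs use 20 replicates per scenario with 4000 MCMC iterations (1000
burn-in, thinning 3) per fit — replicate-averaged posterior means are
stable well below these run lengths since the Monte Carlo error of each
per-fit mean (about 0.01 for `phi`) is an order of magnitude below the
between-replicate spread; single final analyses should use the 6000/
1000 defaults or longer and check `diagnostics()`.

## Degenerate inputs and edge cases

* Isolated (zero-neighbor) regions are rejected by `scale_icar()`:
  an ICAR field is undefined there. Disconnected graphs are handled by
  scaling and constraining each connected component separately.
* `phi` is sampled on the logit scale and its prior guard rejects
  `phi >= 1 - 1e-8`; likelihood code accepts the `p = 1` boundary of
  the mixture families through limits.
* Regions with missing counts contribute nothing to the likelihood
  (they are dropped, not zero-filled); a model with *all* responses
  missing reproduces its prior, which the tests exploit.
* Zero-likelihood draws force `CPO_i = 0` and an infinite LS, reported
  with warnings rather than silent `NaN`s.

## Known limitations

* The dense eigendecomposition is cubic in the number of regions;
  beyond a few thousand regions a sparse-Cholesky implementation would
  be needed.
* The harmonic-mean CPO estimator is noisy when the posterior is
  diffuse; leave-one-out refits would be exact but cost `n` fits.
* Posterior standard deviations from MCMC need not match Laplace-
  approximation standard deviations exactly; comparisons of summary
  tables across software should allow for that.
* `beta` is weakly identified when the true field is constant (there
  is no spatial signal to share), and its posterior then largely
  reflects its prior.
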