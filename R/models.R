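#' Per-region observed data
#'
#' Bundles the observation vectors for one study region set: counts `o`
#' (NA allowed for regions whose count is unobserved), optional occurrence
#' indicators `z`, expected counts `E` (the offset, strictly positive),
#' and optional covariate matrices `x` (count predictor) and `y`
#' (occurrence predictor).
#'
#' @param o nonnegative integer counts, NA allowed.
#' @param E positive expected counts.
#' @param z optional binary occurrence indicators, NA allowed.
#' @param x,y optional numeric covariate matrices with one row per region.
#' @return Object of class `observed_data`.
#' @export
observed_data <- function(o, E, z = NULL, x = NULL, y = NULL) {
  n <- length(E)
  if (length(o) != n) stopf("o and E must have equal length")
  if (any(!is.finite(E) | E <= 0)) stopf("E must be positive and finite")
  oo <- o[!is.na(o)]
  if (any(oo < 0 | oo != round(oo))) stopf("o must be nonnegative integers")
  if (!is.null(z)) {
    if (length(z) != n) stopf("z must have length %d", n)
    zz <- z[!is.na(z)]
    if (any(!(zz %in% c(0, 1)))) stopf("z must be 0/1")
    bad <- which(!is.na(z) & z == 0 & !is.na(o) & o > 0)
    if (length(bad))
      stopf("occurrence/count inconsistency in region(s) %s: z = 0 with o > 0",
            paste(head(bad, 5L), collapse = ", "))
  }
  for (nm in c("x", "y")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (nrow(m) != n) stopf("%s must have one row per region", nm)
      assign(nm, m)
    }
  }
  structure(list(o = as.integer(o), E = as.numeric(E),
                 z = if (is.null(z)) NULL else as.integer(z),
                 x = x, y = y, n = n),
            class = "observed_data")
}

#' Derive hurdle occurrence indicators from counts
#'
#' For hurdle-type (type 0 / joint) data every zero is structural, so the
#' occurrence indicator is `z = 1(o > 0)` and the count is treated as
#' missing (zero-truncated support) where `z = 0`.
#'
#' @param o nonnegative integer counts.
#' @param E positive expected counts.
#' @inheritParams observed_data
#' @return An `observed_data` with `z` filled in and `o` set to NA where
#'   `z = 0`.
#' @export
as_hurdle_data <- function(o, E, x = NULL, y = NULL) {
  z <- as.integer(o > 0)
  o2 <- ifelse(z == 1L, o, NA_integer_)
  observed_data(o2, E, z = z, x = x, y = y)
}

#' Misaligned two-column joint response matrix
#'
#' The joint model has two likelihoods — Bernoulli occurrence and
#' zero-truncated Poisson count — so its response is written as a
#' `2n x 2` misaligned matrix `Y`: rows `1..n` carry the occurrence
#' indicators in column 1 (`Z`), rows `n+1..2n` carry the counts in column
#' 2 (`O`), and every other cell is NA. Counts are NA where no event
#' occurred (`z = 0`).
#'
#' @param z binary occurrence indicators, length `n`.
#' @param o counts, length `n`, NA exactly where `z = 0`.
#' @return `2n x 2` matrix with columns `Z`, `O`.
#' @seealso [split_joint_response()] for the inverse.
#' @export
build_joint_response <- function(z, o) {
  n <- length(z)
  if (length(o) != n) stopf("z and o must have equal length")
  if (any(!(z %in% c(0, 1)))) stopf("z must be 0/1")
  if (any(z == 0 & !is.na(o)))
    stopf("occurrence/count inconsistency: o present where z = 0")
  if (any(z == 1 & is.na(o)))
    stopf("occurrence/count inconsistency: o missing where z = 1")
  Y <- matrix(NA_real_, nrow = 2L * n, ncol = 2L,
              dimnames = list(NULL, c("Z", "O")))
  Y[seq_len(n), 1L] <- z
  Y[n + seq_len(n), 2L] <- o
  Y
}

#' @rdname build_joint_response
#' @param Y a matrix from [build_joint_response()].
#' @return `split_joint_response()`: list with vectors `z` and `o`.
#' @export
split_joint_response <- function(Y) {
  n <- nrow(Y) / 2L
  list(z = as.integer(Y[seq_len(n), 1L]), o = Y[n + seq_len(n), 2L])
}

#' Specify a spatial zero-inflated model
#'
#' Assembles an observation family, a latent spatial model and a prior
#' bundle into a fittable specification.
#'
#' Families: `"poisson"` (plain log-linear model), `"zip1"` (zero-inflated
#' mixture), `"zip0"` (hurdle with zero-truncated counts), `"joint"`
#' (shared-effect Bernoulli + zero-truncated Poisson; requires `z`). In
#' every family the count predictor is
#' `log(theta_i) = alpha_O + x_i' delta + gamma_i` with Poisson mean
#' `E_i theta_i`, and the occurrence/count-process probability is
#' `logit(p_i) = alpha_z + y_i' omega + beta gamma_i`; `beta` is a free
#' scaling parameter in the joint family and fixed at 0 in the single
#' families, where `p` reduces to a region-constant zero-probability
#' parameter.
#'
#' Latent models: `"bym2"` — `gamma = (1/sqrt(tau_gamma)) (sqrt(1 - phi) v
#' + sqrt(phi) u*)` with `v` i.i.d. standard normal and `u*` the scaled
#' ICAR effect, so `Var(gamma) = tau_gamma^(-1)((1 - phi) I + phi Q*^-)`;
#' `"bym"` — `gamma = v + u` with independent precisions `tau_v`, `tau_u`.
#'
#' @param data an [observed_data].
#' @param sp a `scaled_precision` for the study graph.
#' @param family,latent model choices, see Details.
#' @param priors a prior bundle from [model_priors()]; built with defaults
#'   when omitted.
#' @return Object of class `zip_model_spec`.
#' @export
zip_model <- function(data, sp,
                      family = c("joint", "zip0", "zip1", "poisson"),
                      latent = c("bym2", "bym"),
                      priors = NULL) {
  family <- match.arg(family)
  latent <- match.arg(latent)
  stopifnot(inherits(data, "observed_data"), inherits(sp, "scaled_precision"))
  if (data$n != sp$n) stopf("data has %d regions but graph has %d",
                            data$n, sp$n)
  if (family == "joint") {
    if (is.null(data$z)) stopf("joint family requires occurrence indicators z")
    if (any(is.na(data$z))) stopf("joint family requires complete z")
  }
  # single-likelihood families: regions with missing o are skipped in the
  # likelihood (they contribute prior information only)
  if (is.null(priors)) priors <- model_priors(sp, latent = latent)
  structure(list(family = family, latent = latent, data = data, sp = sp,
                 priors = priors, n = data$n),
            class = "zip_model_spec")
}

#' @export
print.zip_model_spec <- function(x, ...) {
  cat(sprintf("zip_model_spec: family = %s, latent = %s, n = %d regions\n",
              x$family, x$latent, x$n))
  invisible(x)
}

#' Prior bundle for a model specification
#'
#' Collects the hyperpriors: a PC prior on the BYM2 precision `tau_gamma`
#' (default `U = 1`, `alpha = 0.01`), the graph-calibrated PC prior on the
#' mixing parameter `phi` (default `U = 0.5`, `alpha = 2/3`), Gamma(1,
#' 0.01) priors on the BYM precisions, and the normal fixed-effect priors
#' of [fixed_effect_priors()].
#'
#' @param sp a `scaled_precision` (needed to calibrate the `phi` prior).
#' @param latent `"bym2"` or `"bym"`.
#' @param prec_U,prec_alpha PC precision prior parameters.
#' @param phi_U,phi_alpha PC mixing prior parameters.
#' @param gamma_shape,gamma_rate BYM Gamma prior parameters.
#' @param fixed a [fixed_effect_priors()] bundle.
#' @return List of class `model_priors`.
#' @export
model_priors <- function(sp, latent = "bym2",
                         prec_U = 1, prec_alpha = 0.01,
                         phi_U = 0.5, phi_alpha = 2 / 3,
                         gamma_shape = 1, gamma_rate = 0.01,
                         fixed = fixed_effect_priors()) {
  out <- list(
    prec_lambda = pc_prec_lambda(prec_U, prec_alpha),
    phi = if (latent == "bym2") pc_phi_lambda(phi_U, phi_alpha, sp) else NULL,
    gamma = gamma_prec_prior(gamma_shape, gamma_rate),
    fixed = fixed)
  structure(out, class = "model_priors")
}

n_covariates <- function(m) if (is.null(m)) 0L else ncol(m)

# initial state on the natural scale; data-driven moment starts
initial_state <- function(spec) {
  d <- spec$data
  o <- d$o
  obs <- !is.na(o)
  alpha_o <- if (any(obs)) log(max(sum(o[obs]), 0.5) / sum(d$E[obs])) else 0
  z <- d$z
  alpha_z <- if (!is.null(z)) logit(min(max(mean(z), 0.05), 0.95)) else
    logit(min(max(mean(o > 0), 0.05), 0.95))
  st <- list(gamma = rep(0, spec$n),
             alpha_o = alpha_o, alpha_z = alpha_z,
             delta = rep(0, n_covariates(d$x)),
             omega = rep(0, n_covariates(d$y)),
             beta = if (spec$family == "joint") 1 else 0)
  if (spec$latent == "bym2") {
    st$tau_gamma <- 1; st$phi <- 0.5
  } else {
    st$tau_v <- 1; st$tau_u <- 1
  }
  st
}

#' Linear predictors of a model state
#'
#' Evaluates `log(theta_i) = alpha_O + x_i' delta + gamma_i` and
#' `logit(p_i) = alpha_z + y_i' omega + beta gamma_i` for a parameter
#' state. The same `gamma` vector enters both predictors; the offset
#' `log(E_i)` is applied inside the Poisson mean (`mean = E_i theta_i`),
#' not added here.
#'
#' @param spec a `zip_model_spec`.
#' @param state named list with `gamma`, `alpha_o`, `alpha_z`, `beta`, and
#'   optional `delta`, `omega`.
#' @return List with numeric vectors `log_theta` and `logit_p`.
#' @export
linear_predictors <- function(spec, state) {
  d <- spec$data
  g <- state$gamma
  if (length(g) != spec$n) stopf("gamma must have length %d", spec$n)
  log_theta <- state$alpha_o + g
  if (n_covariates(d$x)) {
    if (length(state$delta) != ncol(d$x))
      stopf("delta must have length %d", ncol(d$x))
    log_theta <- log_theta + drop(d$x %*% state$delta)
  }
  logit_p <- rep(state$alpha_z %||% 0, spec$n) + (state$beta %||% 0) * g
  if (n_covariates(d$y)) {
    if (length(state$omega) != ncol(d$y))
      stopf("omega must have length %d", ncol(d$y))
    logit_p <- logit_p + drop(d$y %*% state$omega)
  }
  list(log_theta = log_theta, logit_p = logit_p)
}

# per-observation log-likelihood contributions, in named blocks; missing
# cells contribute nothing (they are dropped, not zero-filled)
loglik_blocks <- function(spec, state) {
  d <- spec$data
  lp <- linear_predictors(spec, state)
  theta <- exp(lp$log_theta)
  p <- inv_logit(lp$logit_p)
  obs <- which(!is.na(d$o))
  switch(spec$family,
    poisson = list(o = poisson_loglik(d$o[obs], d$E[obs], theta[obs])),
    zip1 = list(o = zip1_loglik(d$o[obs], d$E[obs], theta[obs], p[obs])),
    zip0 = list(o = zip0_loglik(d$o[obs], d$E[obs], theta[obs], p[obs])),
    joint = {
      zi <- d$z
      occ <- which(zi == 1L & !is.na(d$o))
      list(z = bernoulli_loglik(zi, p),
           o = if (length(occ))
             truncated_poisson_loglik(d$o[occ], d$E[occ], theta[occ])
           else numeric(0))
    })
}

log_likelihood <- function(spec, state) {
  sum(vapply(loglik_blocks(spec, state), sum, 0))
}

# gradient of the log likelihood with respect to gamma (length n)
loglik_grad_gamma <- function(spec, state) {
  d <- spec$data
  lp <- linear_predictors(spec, state)
  mu <- d$E * exp(lp$log_theta)
  p <- inv_logit(lp$logit_p)
  beta <- state$beta %||% 0
  grad <- numeric(spec$n)
  if (spec$family == "poisson") {
    obs <- which(!is.na(d$o))
    grad[obs] <- (d$o - mu)[obs]
  } else if (spec$family == "zip1") {
    pos <- which(!is.na(d$o) & d$o > 0)
    zer <- which(!is.na(d$o) & d$o == 0)
    grad[pos] <- (d$o - mu)[pos]
    if (length(zer)) {
      m <- mu[zer]; pp <- p[zer]
      grad[zer] <- -pp * m * exp(-m) / ((1 - pp) + pp * exp(-m))
    }
  } else if (spec$family == "zip0") {
    pos <- which(!is.na(d$o) & d$o > 0)
    grad[pos] <- trunc_pois_grad(d$o[pos], mu[pos])
  } else { # joint
    grad <- beta * (d$z - p)
    occ <- which(d$z == 1L & !is.na(d$o))
    grad[occ] <- grad[occ] + trunc_pois_grad(d$o[occ], mu[occ])
  }
  grad
}

# d/d eta of the zero-truncated Poisson log pmf, eta = log theta, mu = E theta
trunc_pois_grad <- function(o, mu) {
  o - mu - mu * exp(-mu) / (-expm1(-mu))
}

# log prior of gamma marginalized over the latent decomposition: Gaussian
# with covariance diagonal in the eigenbasis of Q* (bym2) or Q (bym)
latent_marginal_sd2 <- function(spec, state) {
  eg <- spec$sp$eigen
  if (spec$latent == "bym2") {
    ((1 - state$phi) + state$phi * eg$xi) / state$tau_gamma
  } else {
    1 / state$tau_v + eg$xi / state$tau_u
  }
}

latent_logprior <- function(spec, state, gamma_tilde = NULL) {
  if (is.null(gamma_tilde))
    gamma_tilde <- drop(crossprod(spec$sp$eigen$vectors, state$gamma))
  s2 <- latent_marginal_sd2(spec, state)
  if (any(s2 <= 0)) return(-Inf)
  -0.5 * sum(log(2 * pi * s2)) - 0.5 * sum(gamma_tilde^2 / s2)
}

hyper_logprior <- function(spec, state) {
  pr <- spec$priors
  if (spec$latent == "bym2") {
    if (!is.finite(state$tau_gamma) || state$tau_gamma <= 0 ||
        !is.finite(state$phi) || state$phi < 0 || state$phi >= 1)
      return(-Inf)
    pc_prec_logpdf(state$tau_gamma, pr$prec_lambda) +
      pc_phi_logpdf(state$phi, pr$phi)
  } else {
    if (any(!is.finite(c(state$tau_v, state$tau_u))) ||
        state$tau_v <= 0 || state$tau_u <= 0)
      return(-Inf)
    gamma_prec_logpdf(state$tau_v, pr$gamma) +
      gamma_prec_logpdf(state$tau_u, pr$gamma)
  }
}

fixed_logprior <- function(spec, state) {
  f <- spec$priors$fixed
  lp <- normal_logpdf(state$alpha_o, f$intercept_o$mean, f$intercept_o$precision)
  if (spec$family != "poisson")
    lp <- lp + normal_logpdf(state$alpha_z, f$intercept_z$mean,
                             f$intercept_z$precision)
  if (length(state$delta))
    lp <- lp + sum(normal_logpdf(state$delta, f$delta$mean, f$delta$precision))
  if (length(state$omega))
    lp <- lp + sum(normal_logpdf(state$omega, f$omega$mean, f$omega$precision))
  if (spec$family == "joint")
    lp <- lp + normal_logpdf(state$beta, f$beta$mean, f$beta$precision)
  lp
}

#' Log posterior density of a model state
#'
#' Sum of the observation log likelihood (missing cells skipped), the
#' marginal Gaussian log density of the shared effect `gamma` given the
#' hyperparameters, and all hyperparameter and fixed-effect prior log
#' densities. All parameters are on their natural scales; states outside
#' the support return `-Inf`.
#'
#' @param spec a `zip_model_spec`.
#' @param state named list of parameter values (see [linear_predictors()]
#'   plus hyperparameters `tau_gamma`/`phi` or `tau_v`/`tau_u`).
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior <- function(spec, state) {
  hp <- hyper_logprior(spec, state)
  if (!is.finite(hp)) return(-Inf)
  lat <- latent_logprior(spec, state)
  if (!is.finite(lat)) return(-Inf)
  log_likelihood(spec, state) + lat + hp + fixed_logprior(spec, state)
}
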