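#' Penalized-complexity prior for a precision parameter
#'
#' The PC prior for a precision `tau` is defined through the standard
#' deviation `sigma = tau^(-1/2)`: the distance from the base model
#' (`sigma = 0`, no random effect) is `sigma` itself, and the prior places
#' an exponential density with rate `lambda` on it. `lambda` is calibrated
#' from a tail statement `P(sigma > U) = alpha`, giving
#' `lambda = -log(alpha) / U`. The study models use `U = 1`,
#' `alpha = 0.01`.
#'
#' @param U positive threshold on the standard-deviation scale.
#' @param alpha tail probability in (0, 1).
#' @return The exponential rate `lambda`.
#' @references Simpson et al. (2017) "Penalising model component
#'   complexity: a principled, practical approach to constructing priors",
#'   Statistical Science 32(1).
#' @export
pc_prec_lambda <- function(U, alpha) {
  assert_scalar_num(U, "U"); assert_scalar_num(alpha, "alpha")
  if (U <= 0) stopf("U must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  -log(alpha) / U
}

#' Log density of the PC precision prior
#'
#' Density of `tau` induced by `sigma = tau^(-1/2) ~ Exponential(lambda)`:
#' `pi(tau) = (lambda / 2) tau^(-3/2) exp(-lambda tau^(-1/2))`.
#'
#' @param tau precision value(s); non-positive values get `-Inf`.
#' @param lambda exponential rate from [pc_prec_lambda()].
#' @return Log density, vectorized over `tau`.
#' @export
pc_prec_logpdf <- function(tau, lambda) {
  assert_scalar_num(lambda, "lambda")
  if (lambda <= 0) stopf("lambda must be positive")
  out <- rep(-Inf, length(tau))
  ok <- is.finite(tau) & tau > 0
  out[ok] <- log(lambda / 2) - 1.5 * log(tau[ok]) - lambda / sqrt(tau[ok])
  out
}

#' Complexity distance for the BYM2 mixing parameter
#'
#' Distance `d(phi) = sqrt(2 KLD(phi))` of the BYM2 latent model at mixing
#' value `phi` from its base model `phi = 0` (purely unstructured effect),
#' where the Kullback-Leibler divergence between the two zero-mean
#' Gaussians is computed over the eigenvalues `xi_j` of the generalized
#' inverse of the scaled precision `Q*`:
#' `KLD = 0.5 * sum_j [phi (xi_j - 1) - log(1 - phi + phi xi_j)]`.
#' Per-component null directions contribute `xi = 0` terms, so `d`
#' diverges as `phi` approaches 1.
#'
#' @param phi mixing value(s) in `[0, 1)`.
#' @param sp a `scaled_precision` from [scale_icar()].
#' @return `d(phi)`, vectorized over `phi`.
#' @export
pc_phi_distance <- function(phi, sp) {
  stopifnot(inherits(sp, "scaled_precision"))
  if (any(!is.finite(phi) | phi < 0 | phi >= 1))
    stopf("phi must lie in [0, 1)")
  xi <- sp$eigen$xi
  vapply(phi, function(p) {
    kld <- 0.5 * sum(p * (xi - 1) - log1p(p * (xi - 1)))
    sqrt(max(2 * kld, 0))
  }, 0)
}

# phi grid and distances reused by calibration and density evaluation.
# d(phi) diverges like sqrt(-log(1 - phi)) as phi -> 1 (null-direction
# term), so the grid is graded: uniform on [0, 0.9], log-spaced in
# (1 - phi) beyond, down to phi_max. Monotone by construction.
phi_distance_table <- function(sp, n_grid = 1001L, phi_max = 1 - 1e-8) {
  n_lo <- round(0.6 * n_grid)
  lo <- seq(0, 0.9, length.out = n_lo)
  hi <- 1 - exp(seq(log(0.1), log(1 - phi_max),
                    length.out = n_grid - n_lo + 1L))[-1L]
  phi <- c(lo, hi)
  list(phi = phi, d = pc_phi_distance(phi, sp))
}

# linear interpolation on a sorted grid, clamped at the ends
interp_sorted <- function(x, y, xout) {
  i <- findInterval(xout, x, all.inside = TRUE)
  w <- (xout - x[i]) / (x[i + 1L] - x[i])
  w <- pmin(pmax(w, 0), 1)
  y[i] * (1 - w) + y[i + 1L] * w
}

# centered finite differences on a (possibly nonuniform) grid
table_dprime <- function(phi, d) {
  m <- length(phi)
  c((d[2L] - d[1L]) / (phi[2L] - phi[1L]),
    (d[3L:m] - d[1L:(m - 2L)]) / (phi[3L:m] - phi[1L:(m - 2L)]),
    (d[m] - d[m - 1L]) / (phi[m] - phi[m - 1L]))
}

#' Calibrate the PC prior rate for the mixing parameter
#'
#' Root-finds the exponential rate `lambda` so that the PC prior on `phi`
#' (exponential with rate `lambda` on the distance `d(phi)`, truncated at
#' the largest tabulated distance) satisfies `P(phi < U) = alpha`. The
#' study models use `U = 0.5`, `alpha = 2/3`, shrinking toward the
#' unstructured base model.
#'
#' @param U threshold in (0, 1) on the `phi` scale.
#' @param alpha probability in (0, 1).
#' @param sp a `scaled_precision`; the prior is graph-dependent.
#' @return List of class `pc_phi_prior`: `lambda`, `U`, `alpha`, `table`
#'   (the `(phi, d)` grid), and `d_max`.
#' @export
pc_phi_lambda <- function(U, alpha, sp) {
  assert_scalar_num(U, "U"); assert_scalar_num(alpha, "alpha")
  if (U <= 0 || U >= 1) stopf("U must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  tab <- phi_distance_table(sp)
  d_max <- tab$d[length(tab$d)]
  dU <- stats::approx(tab$phi, tab$d, xout = U, rule = 2)$y
  # P(phi < U) = (1 - exp(-lambda d(U))) / (1 - exp(-lambda d_max))
  f <- function(lam) {
    (-expm1(-lam * dU)) / (-expm1(-lam * d_max)) - alpha
  }
  lo <- 1e-6; hi <- 1e3
  if (f(lo) * f(hi) > 0)
    stopf("failed to bracket lambda in [%g, %g]: f(lo)=%g, f(hi)=%g",
          lo, hi, f(lo), f(hi))
  lam <- uniroot(f, c(lo, hi), tol = 1e-6)$root
  tab$dprime <- table_dprime(tab$phi, tab$d)
  structure(list(lambda = lam, U = U, alpha = alpha, table = tab,
                 d_max = d_max), class = "pc_phi_prior")
}

#' Log density of the PC mixing prior
#'
#' Density of `phi` obtained by transforming the truncated exponential on
#' the distance scale back through `d(phi)`:
#' `pi(phi) = lambda exp(-lambda d(phi)) / (1 - exp(-lambda d_max)) * d'(phi)`,
#' with `d'(phi)` by centered finite differences on the tabulated grid.
#'
#' @param phi value(s) in `[0, 1)`; values at or above 1 get `-Inf`.
#' @param prior a `pc_phi_prior` from [pc_phi_lambda()], or a positive
#'   rate together with `sp`.
#' @param sp required when `prior` is a bare rate: the `scaled_precision`
#'   defining the distance.
#' @return Log density, vectorized over `phi`.
#' @export
pc_phi_logpdf <- function(phi, prior, sp = NULL) {
  if (!inherits(prior, "pc_phi_prior")) {
    assert_scalar_num(prior, "lambda")
    if (is.null(sp)) stopf("sp is required when prior is a bare rate")
    prior <- structure(list(lambda = prior, table = phi_distance_table(sp)),
                       class = "pc_phi_prior")
    prior$d_max <- prior$table$d[length(prior$table$d)]
  }
  tab <- prior$table
  lam <- prior$lambda
  if (is.null(tab$dprime)) tab$dprime <- table_dprime(tab$phi, tab$d)
  out <- rep(-Inf, length(phi))
  ok <- is.finite(phi) & phi >= 0 & phi < 1
  if (any(ok)) {
    d <- interp_sorted(tab$phi, tab$d, phi[ok])
    dp <- interp_sorted(tab$phi, tab$dprime, phi[ok])
    out[ok] <- log(lam) - lam * d - log(-expm1(-lam * prior$d_max)) + log(dp)
  }
  out
}

#' Gamma prior for BYM precision parameters
#'
#' The classical weakly-informative choice for the BYM model's two
#' precisions: shape 1, rate 0.01.
#'
#' @param shape,rate positive Gamma parameters.
#' @return List of class `gamma_prec_prior`.
#' @export
gamma_prec_prior <- function(shape = 1, rate = 0.01) {
  if (shape <= 0 || rate <= 0) stopf("shape and rate must be positive")
  structure(list(shape = shape, rate = rate), class = "gamma_prec_prior")
}

gamma_prec_logpdf <- function(tau, prior) {
  out <- rep(-Inf, length(tau))
  ok <- is.finite(tau) & tau > 0
  out[ok] <- stats::dgamma(tau[ok], shape = prior$shape, rate = prior$rate,
                           log = TRUE)
  out
}

#' Default fixed-effect priors
#'
#' Normal priors for intercepts, covariate coefficients and the shared-
#' effect scaling coefficient `beta`: the count-model intercept `alpha_O`
#' and coefficients `delta` get mean 0, precision 1e-4 (vague); the
#' occurrence-model intercept `alpha_z` and coefficients `omega` get mean
#' -1, precision 0.2; `beta` gets mean 1, variance 10 (weakly informative,
#' centered on identical spatial patterns in the two processes).
#'
#' @param beta_mean,beta_var prior mean and variance for `beta`.
#' @return Nested list of `(mean, precision)` pairs, class
#'   `fixed_effect_priors`.
#' @export
fixed_effect_priors <- function(beta_mean = 1, beta_var = 10) {
  if (beta_var <= 0) stopf("beta_var must be positive")
  structure(list(
    intercept_o = list(mean = 0, precision = 1e-4),
    intercept_z = list(mean = -1, precision = 0.2),
    delta       = list(mean = 0, precision = 1e-4),
    omega       = list(mean = -1, precision = 0.2),
    beta        = list(mean = beta_mean, precision = 1 / beta_var)
  ), class = "fixed_effect_priors")
}

normal_logpdf <- function(x, mean, precision) {
  0.5 * log(precision) - 0.5 * log(2 * pi) - 0.5 * precision * (x - mean)^2
}
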