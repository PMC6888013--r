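#' Observation-model log likelihoods
#'
#' Per-region log likelihood contributions for the observation families
#' used in zero-inflated disease mapping. All functions are vectorized and
#' numerically stabilized; the Poisson mean is the product of the expected
#' count (offset) `E` and the relative risk `theta`.
#'
#' * `poisson_loglik()`: standard Poisson, `o ~ Poisson(E theta)`.
#' * `truncated_poisson_loglik()`: zero-truncated Poisson for counts known
#'   to be positive, `P(o) = Poisson(o) / (1 - exp(-E theta))`, `o >= 1`.
#' * `zip1_loglik()`: zero-inflated Poisson "type 1" mixture — mass
#'   `(1 - p)` on a structural zero plus `p` times a full Poisson, so
#'   zeros arise both structurally and by chance.
#' * `zip0_loglik()`: "type 0" hurdle — mass `(1 - p)` on zero and `p`
#'   times a zero-truncated Poisson, so every zero is structural.
#' * `bernoulli_loglik()`: occurrence indicator, `z ~ Bernoulli(p)`.
#'
#' Note the mixture orientation: `(1 - p)` is the structural-zero mass and
#' `p` multiplies the count component (some software parameterizes the
#' reverse; `p` here is the probability that the count process is active).
#'
#' @param o nonnegative integer count(s) (`>= 1` for the truncated
#'   family).
#' @param E positive expected count(s) (offset).
#' @param theta positive relative risk(s).
#' @param p probability in (0, 1) that the count process is active
#'   (boundaries handled by their limits).
#' @param z binary occurrence indicator(s).
#' @return Log likelihood value(s).
#' @name likelihoods
NULL

check_counts <- function(o, min = 0) {
  if (any(!is.finite(o) | o < min | o != round(o)))
    stopf("counts must be integers >= %d", min)
}

#' @rdname likelihoods
#' @export
poisson_loglik <- function(o, E, theta) {
  check_counts(o)
  if (any(E <= 0) || any(theta <= 0)) stopf("E and theta must be positive")
  mu <- E * theta
  o * log(mu) - mu - lgamma(o + 1)
}

#' @rdname likelihoods
#' @export
truncated_poisson_loglik <- function(o, E, theta) {
  check_counts(o, min = 1)
  poisson_loglik(o, E, theta) - log1mexp(E * theta)
}

#' @rdname likelihoods
#' @export
zip1_loglik <- function(o, E, theta, p) {
  check_counts(o)
  if (any(p < 0 | p > 1)) stopf("p must lie in [0, 1]")
  n <- max(length(o), length(E), length(theta), length(p))
  o <- rep_len(o, n); E <- rep_len(E, n)
  theta <- rep_len(theta, n); p <- rep_len(p, n)
  out <- numeric(n)
  pos <- o > 0
  if (any(pos))
    out[pos] <- log(p[pos]) + poisson_loglik(o[pos], E[pos], theta[pos])
  if (any(!pos)) {
    mu <- E[!pos] * theta[!pos]
    # log((1-p) + p e^{-mu}) via log-sum-exp
    out[!pos] <- mapply(function(pp, m) {
      logsumexp(c(log1p(-pp), log(pp) - m))
    }, p[!pos], mu)
  }
  out
}

#' @rdname likelihoods
#' @export
zip0_loglik <- function(o, E, theta, p) {
  check_counts(o)
  if (any(p < 0 | p > 1)) stopf("p must lie in [0, 1]")
  n <- max(length(o), length(E), length(theta), length(p))
  o <- rep_len(o, n); E <- rep_len(E, n)
  theta <- rep_len(theta, n); p <- rep_len(p, n)
  out <- numeric(n)
  pos <- o > 0
  if (any(pos))
    out[pos] <- log(p[pos]) +
      truncated_poisson_loglik(o[pos], E[pos], theta[pos])
  out[!pos] <- log1p(-p[!pos])
  out
}

#' @rdname likelihoods
#' @export
bernoulli_loglik <- function(z, p) {
  if (any(!(z %in% c(0, 1)))) stopf("z must be 0 or 1")
  out <- log1p(-p)
  one <- z == 1
  out[one] <- log(p[if (length(p) > 1L) one else 1L])
  out
}

#' Link functions
#'
#' Canonical links for the two latent fields: `log` for the relative risk
#' `theta` and `logit` for the occurrence probability `p`, with their
#' inverses. Boundary values map to infinities.
#'
#' @param p probability in \eqn{[0, 1]}.
#' @param x real value.
#' @return Transformed value(s).
#' @name links
NULL

#' @rdname links
#' @export
logit_link <- function(p) stats::qlogis(p)

#' @rdname links
#' @export
inv_logit_link <- function(x) stats::plogis(x)

#' @rdname links
#' @export
log_link <- function(p) log(p)

#' @rdname links
#' @export
inv_log_link <- function(x) exp(x)
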