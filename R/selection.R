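# per-draw per-observation log-likelihood matrices, one per likelihood
# block ("o" for single models, "z" and "o" for the joint model)
per_draw_loglik <- function(fit) {
  spec <- fit$spec
  nd <- nrow(fit$draws)
  blocks <- NULL
  for (i in seq_len(nd)) {
    st <- as.list(fit$draws[i, , drop = FALSE])
    st$gamma <- fit$gamma[i, ]
    st <- restore_coef_vectors(spec, st)
    bl <- loglik_blocks(spec, st)
    if (is.null(blocks))
      blocks <- lapply(bl, function(b) matrix(NA_real_, length(b), nd))
    for (nm in names(bl)) blocks[[nm]][, i] <- bl[[nm]]
  }
  blocks
}

# draws store covariate coefficients as flat columns delta1.., omega1..
restore_coef_vectors <- function(spec, st) {
  nx <- n_covariates(spec$data$x); ny <- n_covariates(spec$data$y)
  st$delta <- if (nx) unlist(st[paste0("delta", seq_len(nx))]) else numeric(0)
  st$omega <- if (ny) unlist(st[paste0("omega", seq_len(ny))]) else numeric(0)
  st
}

# plug-in state at the posterior mean of the parameters entering the
# likelihood (gamma and fixed effects; hyperparameters do not enter it)
posterior_mean_state <- function(fit) {
  st <- as.list(colMeans(fit$draws))
  st$gamma <- colMeans(fit$gamma)
  restore_coef_vectors(fit$spec, st)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance
#' (`D = -2 log p(data | state)`) and `pD = Dbar - D(posterior mean)` the
#' effective number of parameters, the plug-in evaluated at the posterior
#' means of the likelihood parameters (`gamma`, fixed effects) on their
#' natural scale. For the joint model the per-likelihood decomposition is
#' reported and the total DIC is the sum of the two blocks' DICs.
#'
#' @param fit a `zip_fit`.
#' @return List of class `dic_result`: `DIC`, `pD`, `Dbar`, and `blocks`
#'   (a data frame with one row per likelihood block).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "zip_fit"))
  ll <- per_draw_loglik(fit)
  st_hat <- posterior_mean_state(fit)
  bl_hat <- loglik_blocks(fit$spec, st_hat)
  rows <- lapply(names(ll), function(nm) {
    dev <- -2 * colSums(ll[[nm]])
    bad <- sum(!is.finite(dev))
    if (bad > 0)
      stopf("%d draw(s) with non-finite deviance in block '%s'", bad, nm)
    Dbar <- mean(dev)
    Dhat <- -2 * sum(bl_hat[[nm]])
    data.frame(block = nm, Dbar = Dbar, pD = Dbar - Dhat,
               DIC = 2 * Dbar - Dhat)
  })
  blocks <- do.call(rbind, rows)
  structure(list(DIC = sum(blocks$DIC), pD = sum(blocks$pD),
                 Dbar = sum(blocks$Dbar), blocks = blocks),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.1f (Dbar = %.1f, pD = %.1f)\n", x$DIC, x$Dbar, x$pD))
  if (nrow(x$blocks) > 1L) print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Conditional predictive ordinates
#'
#' Harmonic-mean estimator of `CPO_i = p(obs_i | data_{-i})` from posterior
#' draws: `CPO_i = [mean over draws of 1 / p(obs_i | state)]^(-1)`,
#' computed with log-sum-exp stabilization. A draw assigning zero
#' likelihood to an observation forces `CPO_i = 0`, reported with a
#' warning.
#'
#' @param fit a `zip_fit`.
#' @return Numeric vector of CPO values over all observations, with a
#'   `block` attribute naming the likelihood block of each entry (`"z"`
#'   occurrence / `"o"` count for the joint model).
#' @export
cpo <- function(fit) {
  stopifnot(inherits(fit, "zip_fit"))
  ll <- per_draw_loglik(fit)
  out <- numeric(0); block <- character(0)
  for (nm in names(ll)) {
    m <- ll[[nm]]
    nd <- ncol(m)
    lcpo <- -(apply(-m, 1L, logsumexp) - log(nd))
    v <- exp(lcpo)
    if (any(v == 0))
      warning(sprintf("%d observation(s) in block '%s' with CPO = 0",
                      sum(v == 0), nm), call. = FALSE)
    out <- c(out, v); block <- c(block, rep(nm, length(v)))
  }
  attr(out, "block") <- block
  out
}

#' Logarithmic score from CPO values
#'
#' `LS = mean(-log CPO_i)` within one likelihood; when the CPO vector
#' carries a `block` attribute with several blocks (the joint model), LS
#' is the sum of the per-block means, matching the convention that joint-
#' model criteria are sums of the local ones. Smaller is better. A zero
#' CPO yields an infinite LS, flagged with a warning.
#'
#' @param cpo_vector output of [cpo()] (or any vector of CPO values in
#'   (0, 1]).
#' @return Scalar LS, with attribute `blocks` giving the per-block means.
#' @export
log_score <- function(cpo_vector) {
  block <- attr(cpo_vector, "block") %||% rep("o", length(cpo_vector))
  if (!length(cpo_vector)) stopf("empty CPO vector")
  if (any(cpo_vector == 0))
    warning("zero CPO value(s): LS is infinite", call. = FALSE)
  per <- tapply(-log(as.numeric(cpo_vector)), block, mean)
  ls <- sum(per)
  attr(ls, "blocks") <- per
  ls
}

#' Model selection report
#'
#' Bundles DIC and CPO-based logarithmic score for a fitted model, with
#' the per-likelihood breakdown for joint models.
#'
#' @param fit a `zip_fit`.
#' @return List of class `selection_report`: `DIC`, `pD`, `Dbar`, `LS`,
#'   `CPO`, `dic_blocks`, `ls_blocks`.
#' @export
selection_report <- function(fit) {
  d <- dic(fit)
  cp <- cpo(fit)
  ls <- log_score(cp)
  structure(list(DIC = d$DIC, pD = d$pD, Dbar = d$Dbar,
                 LS = as.numeric(ls), CPO = cp,
                 dic_blocks = d$blocks, ls_blocks = attr(ls, "blocks")),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("DIC = %.1f (pD = %.1f), LS = %.3f\n", x$DIC, x$pD, x$LS))
  invisible(x)
}
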