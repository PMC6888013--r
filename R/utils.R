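#' @importFrom stats rnorm runif dpois dbinom quantile sd var optimize uniroot
#'   integrate plogis qlogis setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

# log(sum(exp(x))) without overflow; returns -Inf for empty/all -Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 - exp(-x)) for x > 0, accurate for both small and large x
log1mexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 0.6931472
  out[big] <- log1p(-exp(-x[big]))
  out[!big] <- log(-expm1(-x[!big]))
  out
}

inv_logit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# evaluate expr under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
}
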