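test_that("joint response matrix matches the misaligned layout", {
  Y <- build_joint_response(z = c(1, 0, 1), o = c(2, NA, 7))
  expect_equal(dim(Y), c(6L, 2L))
  expect_equal(Y[1:3, 1], c(1, 0, 1))
  expect_equal(Y[4:6, 2], c(2, NA, 7))
  expect_true(all(is.na(Y[1:3, 2])))
  expect_true(all(is.na(Y[4:6, 1])))
  # exactly one non-missing cell per row where defined
  expect_equal(rowSums(!is.na(Y)), c(1, 1, 1, 1, 0, 1))

  # all-zero occurrence: count column entirely missing
  Y0 <- build_joint_response(c(0, 0), c(NA, NA))
  expect_true(all(is.na(Y0[, 2])))

  back <- split_joint_response(Y)
  expect_equal(back$z, c(1L, 0L, 1L))
  expect_equal(back$o, c(2, NA, 7))

  expect_error(build_joint_response(c(1, 0), c(2, 3)),
               "occurrence/count inconsistency")
  expect_error(build_joint_response(c(1, 1), c(2, NA)),
               "occurrence/count inconsistency")
})

test_that("observed data validates shapes and hurdle consistency", {
  expect_error(observed_data(o = c(1, 2), E = c(1, -1)), "positive")
  expect_error(observed_data(o = c(1, 2, 3), E = c(1, 1)), "equal length")
  expect_error(observed_data(o = c(3, 0), E = c(1, 1), z = c(0, 0)),
               "inconsistency")
  h <- as_hurdle_data(o = c(0L, 4L, 0L), E = rep(2, 3))
  expect_equal(h$z, c(0L, 1L, 0L))
  expect_equal(h$o, c(NA_integer_, 4L, NA_integer_))
})

test_that("linear predictors share gamma and honor the offset convention", {
  sp <- sp_path3()
  dat <- as_hurdle_data(c(2L, 0L, 5L), E = c(1, 2, 3))
  spec <- zip_model(dat, sp, family = "joint")
  st <- list(gamma = c(0.1, -0.2, 0.1), alpha_o = 0.5, alpha_z = -1,
             beta = 2, delta = numeric(0), omega = numeric(0))
  lp <- linear_predictors(spec, st)
  expect_equal(lp$log_theta, 0.5 + st$gamma)
  expect_equal(lp$logit_p, -1 + 2 * st$gamma)

  # gamma = 0: constant risk and occurrence probability
  st0 <- modifyList(st, list(gamma = rep(0, 3)))
  lp0 <- linear_predictors(spec, st0)
  expect_equal(exp(lp0$log_theta), rep(exp(0.5), 3))
  expect_equal(inv_logit_link(lp0$logit_p), rep(inv_logit_link(-1), 3))

  # beta = 0 decouples the occurrence predictor from gamma
  stb <- modifyList(st, list(beta = 0))
  expect_equal(linear_predictors(spec, stb)$logit_p, rep(-1, 3))

  expect_error(linear_predictors(spec, modifyList(st, list(gamma = 1:2))),
               "length")
})

test_that("log posterior decomposes into likelihood plus priors", {
  sp <- sp_path3()
  st <- list(gamma = c(0.2, -0.1, -0.1), alpha_o = 0.3, alpha_z = -0.5,
             beta = 1.5, delta = numeric(0), omega = numeric(0),
             tau_gamma = 2, phi = 0.4)

  # all responses missing: posterior equals the prior alone
  dat_empty <- observed_data(o = rep(NA_integer_, 3), E = rep(1, 3))
  spec_empty <- zip_model(dat_empty, sp, family = "poisson")
  lp_empty <- log_posterior(spec_empty, st)
  prior_only <- spatzip:::latent_logprior(spec_empty, st) +
    spatzip:::hyper_logprior(spec_empty, st) +
    spatzip:::fixed_logprior(spec_empty, st)
  expect_equal(lp_empty, prior_only, tolerance = 1e-12)

  # two-region joint model vs hand-computed scalar sum
  g2 <- path_graph(2)
  sp2 <- scale_icar(g2)
  dat2 <- observed_data(o = c(3L, NA), E = c(2, 2), z = c(1L, 0L))
  pri <- model_priors(sp2, latent = "bym2")
  spec2 <- zip_model(dat2, sp2, family = "joint", priors = pri)
  st2 <- list(gamma = c(0.3, -0.3), alpha_o = 0.1, alpha_z = -0.8,
              beta = 1.2, delta = numeric(0), omega = numeric(0),
              tau_gamma = 1.5, phi = 0.6)
  theta <- exp(0.1 + st2$gamma)
  p <- plogis(-0.8 + 1.2 * st2$gamma)
  by_hand <- log(p[1]) + log1p(-p[2]) +
    truncated_poisson_loglik(3, 2, theta[1]) +
    spatzip:::latent_logprior(spec2, st2) +
    pc_prec_logpdf(1.5, pri$prec_lambda) + pc_phi_logpdf(0.6, pri$phi) +
    spatzip:::normal_logpdf(0.1, 0, 1e-4) +
    spatzip:::normal_logpdf(-0.8, -1, 0.2) +
    spatzip:::normal_logpdf(1.2, 1, 0.1)
  expect_equal(log_posterior(spec2, st2), by_hand, tolerance = 1e-10)

  # out-of-support hyperparameters
  expect_identical(
    log_posterior(spec2, modifyList(st2, list(tau_gamma = -1))), -Inf)
  expect_identical(
    log_posterior(spec2, modifyList(st2, list(phi = 1))), -Inf)
})

test_that("Poisson term is unimodal in theta around the observed rate", {
  sp <- sp_path3()
  dat <- observed_data(o = c(4L, 1L, 0L), E = rep(2, 3))
  spec <- zip_model(dat, sp, family = "poisson")
  base <- list(alpha_o = 0, alpha_z = 0, beta = 0, delta = numeric(0),
               omega = numeric(0), tau_gamma = 1, phi = 0.5)
  ll_at <- function(g1) {
    st <- c(list(gamma = c(g1, 0, 0)), base)
    spatzip:::log_likelihood(spec, st)
  }
  mode <- log(4 / 2)   # theta = o/E maximizes the first region's term
  grid_lo <- seq(mode - 2, mode, length.out = 20)
  grid_hi <- seq(mode, mode + 2, length.out = 20)
  expect_true(all(diff(vapply(grid_lo, ll_at, 0)) > 0))
  expect_true(all(diff(vapply(grid_hi, ll_at, 0)) < 0))
})

test_that("BYM2 marginal prior has the stated generalized variance", {
  # empirical covariance of prior draws vs tau^-1((1-phi) I + phi (Q*)^-)
  sp <- sp_path3()
  tau <- 2; phi <- 0.7
  eg <- sp$eigen
  s2 <- ((1 - phi) + phi * eg$xi) / tau
  set.seed(1)
  draws <- eg$vectors %*% (sqrt(s2) * matrix(rnorm(3 * 40000), 3))
  emp <- tcrossprod(draws) / ncol(draws)
  target <- ((1 - phi) * diag(3) + phi * dense_pinv(sp$Q_star)) / tau
  expect_equal(max(abs(emp - target)), 0, tolerance = 0.02)

  # phi = 0 is i.i.d. with precision tau; phi -> 1 approaches scaled ICAR
  spec <- zip_model(observed_data(rep(NA_integer_, 3), rep(1, 3)), sp,
                    family = "poisson")
  s2_0 <- spatzip:::latent_marginal_sd2(spec,
    list(tau_gamma = tau, phi = 0))
  expect_equal(s2_0, rep(1 / tau, 3))
  s2_1 <- spatzip:::latent_marginal_sd2(spec,
    list(tau_gamma = tau, phi = 1 - 1e-12))
  expect_equal(s2_1[!eg$is_null], eg$xi[!eg$is_null] / tau,
               tolerance = 1e-9)
})

test_that("joint model with beta 0 and all-occurrence data reduces to the
           truncated count likelihood", {
  sp <- sp_path3()
  o <- c(2L, 1L, 4L); E <- rep(1.5, 3)
  datj <- observed_data(o, E, z = c(1L, 1L, 1L))
  specj <- zip_model(datj, sp, family = "joint")
  st <- list(gamma = c(0.1, 0, -0.1), alpha_o = 0.2, alpha_z = 5,
             beta = 0, delta = numeric(0), omega = numeric(0))
  bl <- spatzip:::loglik_blocks(specj, st)
  expect_equal(bl$o,
               truncated_poisson_loglik(o, E, exp(0.2 + st$gamma)),
               tolerance = 1e-12)
})
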