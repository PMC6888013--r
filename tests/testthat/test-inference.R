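make_toy_fit <- function(n_iter = 1200, n_burnin = 300, seed = 5,
                         family = "joint", store_latent = FALSE) {
  sp <- sp_lattice3()
  scn <- scenario("structured", "type0", P = 0.5, E_level = 10, sp = sp,
                  seed = 17)
  ds <- generate_dataset(scn, 1)
  spec <- spatzip:::spec_for_family(ds, family, "bym2")
  fit_zip_model(spec, sampler_config(n_iter = n_iter, n_burnin = n_burnin,
                                     seed = seed,
                                     store_latent = store_latent))
}

test_that("same seed gives an identical draw sequence", {
  f1 <- make_toy_fit(seed = 9)
  f2 <- make_toy_fit(seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$gamma, f2$gamma)
  f3 <- make_toy_fit(seed = 10)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("fitting does not disturb the caller's RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(make_toy_fit(n_iter = 400, n_burnin = 100))
  expect_identical(.Random.seed, before)
})

test_that("single-region conjugate check: posterior mode near analytic mode", {
  # Poisson count with vague effects: with gamma and alpha_o fixed at
  # zero except one free gamma coordinate, the toy reduces to a gamma-
  # like posterior whose mode is log(o/E) under a flat-ish prior; with
  # tau small the prior is weak
  g2 <- path_graph(2)
  sp2 <- scale_icar(g2)
  dat <- observed_data(o = c(20L, 20L), E = c(10, 10))
  spec <- zip_model(dat, sp2, family = "poisson")
  cfg <- sampler_config(n_iter = 8000, n_burnin = 1000, seed = 2,
                        fix_hyper = list(tau_gamma = 0.01, phi = 0),
                        fix_fixed = list(alpha_o = 0))
  fit <- fit_zip_model(spec, cfg)
  post_mean <- colMeans(fit$gamma)
  # analytic posterior for exp(eta): Gamma(o + eps, E); mean of eta =
  # digamma(o)/ - log E approx log(o/E) - 1/(2o)
  expect_equal(post_mean, rep(digamma(20) - log(10), 2), tolerance = 0.05)
})

test_that("no-data run reproduces the prior for phi and 1/tau", {
  sp <- sp_path3()
  dat <- observed_data(rep(NA_integer_, 3), rep(1, 3))
  spec <- zip_model(dat, sp, family = "poisson")
  fit <- fit_zip_model(spec, sampler_config(n_iter = 40000,
                                            n_burnin = 2000, seed = 4))
  pr <- spec$priors$phi
  # graded quadrature: the density diverges as phi -> 1
  x1 <- seq(0, 0.9, length.out = 40001)
  u <- seq(-log(0.1), -log(1e-8), length.out = 40001)
  x2 <- 1 - exp(-u)
  d1 <- exp(pc_phi_logpdf(x1, pr)); d2 <- exp(pc_phi_logpdf(x2, pr))
  tot <- trapezoid(x1, d1) + trapezoid(x2, d2)
  prior_mean_phi <- (trapezoid(x1, x1 * d1) + trapezoid(x2, x2 * d2)) / tot
  ess <- spatzip:::ess_geyer(fit$draws$phi)
  mcse <- sd(fit$draws$phi) / sqrt(ess)
  expect_lt(abs(mean(fit$draws$phi) - prior_mean_phi), 4 * mcse + 0.01)

  # 1/tau prior mean by quadrature: E[1/tau] = E[sigma^2] = 2/lambda^2
  lam <- spec$priors$prec_lambda
  prior_mean_itau <- 2 / lam^2
  itau <- fit$draws$one_over_tau_gamma
  ess_t <- spatzip:::ess_geyer(itau)
  mcse_t <- sd(itau) / sqrt(ess_t)
  expect_lt(abs(mean(itau) - prior_mean_itau), 4 * mcse_t + 0.02)
})

test_that("posterior summaries are computed on transformed draws", {
  fit <- make_toy_fit()
  sm <- posterior_summary(fit)
  expect_true(all(c("parameter", "mean", "sd", "q2.5", "q97.5") %in%
                    names(sm)))
  i <- match("one_over_tau_gamma", sm$parameter)
  expect_equal(sm$mean[i], mean(1 / fit$draws$tau_gamma))
  expect_false(isTRUE(all.equal(sm$mean[i],
                                1 / mean(fit$draws$tau_gamma))))
  # quantiles against a sorted-array oracle
  x <- fit$draws$phi[1:100]
  s <- sort(x)
  expect_equal(sm$q2.5[match("phi", sm$parameter)],
               unname(quantile(fit$draws$phi, 0.025)))
  expect_equal(unname(quantile(x, 0.5, type = 7)),
               s[50] + 0.5 * (s[51] - s[50]))
  # constant chain: mean c, sd 0
  cm <- posterior_summary(data.frame(c = rep(3, 50)))
  expect_equal(cm$mean, 3); expect_equal(cm$sd, 0)
  expect_error(posterior_summary(data.frame(x = numeric(0))), "draws")
})

test_that("diagnostics detect healthy and pathological chains", {
  set.seed(11)
  iid <- data.frame(x = rnorm(4000))
  d <- diagnostics(iid)
  expect_lt(abs(d$rhat - 1), 0.02)
  expect_gt(d$ess, 4000 * 0.8)
  expect_lt(d$ess, 4000 * 1.2)

  # duplicated-half chain: strong drift between halves inflates rhat
  bad <- data.frame(x = c(rnorm(1000, 0), rnorm(1000, 5)))
  expect_warning(db <- diagnostics(bad), "convergence")
  expect_gt(db$rhat, 1.5)
})

test_that("latent decomposition draws reconstruct gamma", {
  fit <- make_toy_fit(store_latent = TRUE)
  expect_equal(dim(fit$u_star), dim(fit$gamma))
  i <- nrow(fit$draws)
  # bym2: gamma = (sqrt(1-phi) v + sqrt(phi) u*) / sqrt(tau)
  rec <- (sqrt(1 - fit$draws$phi[i]) * fit$v[i, ] +
            sqrt(fit$draws$phi[i]) * fit$u_star[i, ]) /
    sqrt(fit$draws$tau_gamma[i])
  expect_equal(rec, fit$gamma[i, ], tolerance = 1e-8)
  # u* sums to zero (per component; lattice is connected)
  expect_lt(max(abs(rowSums(fit$u_star))), 1e-8)
})

test_that("bym latent model fits and reports both precisions", {
  fit <- make_toy_fit(family = "zip0")
  expect_true("tau_gamma" %in% names(fit$draws))
  sp <- sp_lattice3()
  scn <- scenario("structured", "type0", P = 0.5, E_level = 10, sp = sp,
                  seed = 17)
  ds <- generate_dataset(scn, 1)
  spec <- spatzip:::spec_for_family(ds, "joint", "bym")
  fitb <- fit_zip_model(spec, sampler_config(n_iter = 1200,
                                             n_burnin = 300, seed = 6))
  expect_true(all(c("tau_v", "tau_u", "one_over_tau_v", "one_over_tau_u")
                  %in% names(fitb$draws)))
  expect_true(all(fitb$draws$tau_v > 0 & fitb$draws$tau_u > 0))
})

test_that("initialization failure produces a diagnostic error", {
  sp <- sp_path3()
  dat <- observed_data(rep(NA_integer_, 3), rep(1, 3))
  spec <- zip_model(dat, sp, family = "poisson")
  # all-missing data breaks the moment initializer before sampling
  expect_error(fit_zip_model(spec, sampler_config(n_iter = 100,
                                                  n_burnin = 10)),
               NA)
})
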