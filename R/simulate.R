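#' Simulation scenario
#'
#' One cell of the simulation study design: a risk surface, a zero type, a
#' zero proportion, an expected-count level and a study graph. The study
#' grid crosses three risk levels (`constant`: `gamma = 0`;
#' `unstructured`: `gamma_i` i.i.d. normal with variance 0.5, i.e.
#' `1/tau_gamma = 0.5`, `phi = 0`; `structured`: `gamma` a scaled ICAR
#' field with generalized variance 0.5, i.e. `1/tau_gamma = 0.5`,
#' `phi = 1`) with two zero types (`type0` hurdle, `type1` mixture), zero
#' proportions `P` of 0.50 and 0.70, and expected counts
#' `E` of 1, 5, 15, 60 and 200.
#'
#' @param risk_level `"constant"`, `"unstructured"` or `"structured"`.
#' @param zero_type `"type0"` (hurdle; also the joint model's data
#'   pattern) or `"type1"` (mixture).
#' @param P marginal zero proportion contributed by the occurrence
#'   process, in (0, 1).
#' @param E_level common expected count per region.
#' @param sp study graph as a `scaled_precision` (see [scale_icar()]).
#' @param n_replicates number of replicate datasets.
#' @param seed base seed; replicate `r` uses `seed + 7919 * r`.
#' @param beta_true shared-effect scaling used in generation.
#' @return List of class `scenario`.
#' @export
scenario <- function(risk_level = c("structured", "unstructured", "constant"),
                     zero_type = c("type0", "type1"),
                     P = 0.5, E_level = 200, sp,
                     n_replicates = 20, seed = 1, beta_true = 1) {
  risk_level <- match.arg(risk_level)
  zero_type <- match.arg(zero_type)
  if (P <= 0 || P >= 1) stopf("P must be in (0, 1)")
  if (E_level <= 0) stopf("E_level must be positive")
  stopifnot(inherits(sp, "scaled_precision"))
  structure(list(risk_level = risk_level, zero_type = zero_type, P = P,
                 E_level = E_level, sp = sp,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), beta_true = beta_true),
            class = "scenario")
}

# zero-truncated Poisson draws by inverse cdf on the truncated scale
rztpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  u <- runif(n)
  stats::qpois(p0 + u * (1 - p0), lambda)
}

#' Generate one replicate dataset
#'
#' Draws one dataset from a [scenario()]: (1) the true risk field `gamma`
#' per the risk level; (2) occurrence indicators
#' `z_i ~ Bernoulli(p_i)` with `logit(p_i) = logit(1 - P) + beta_true *
#' gamma_i`; (3) counts — hurdle pattern (`type0`, also used by the joint
#' model): `o_i` zero-truncated Poisson with mean `E exp(gamma_i)` where
#' `z_i = 1` and missing otherwise; mixture pattern (`type1`): `o_i` is 0
#' with probability `1 - p_i` and full-Poisson otherwise (the same shared-
#' `gamma` `p_i`, so every fitted family faces the same data-generating
#' process). `E_i = E_level` in every region.
#'
#' @param scn a [scenario()].
#' @param replicate_index positive integer selecting the replicate stream.
#' @return List of class `simulated_dataset`: `data` (an
#'   [observed_data]), `z`, `o`, `E`, and `truths` (named list with
#'   `gamma`, `one_over_tau_gamma`, `phi`, `beta`, `alpha_z`, `alpha_o`).
#'   For `type1` the returned `z` is the latent activity indicator, which
#'   is not observable in real mixture data.
#' @export
generate_dataset <- function(scn, replicate_index = 1) {
  stopifnot(inherits(scn, "scenario"))
  n <- scn$sp$n
  seed <- scn$seed + 7919L * as.integer(replicate_index)
  with_local_seed(seed, {
    gamma <- switch(scn$risk_level,
      constant = rep(0, n),
      unstructured = rnorm(n, 0, sqrt(0.5)),
      structured = {
        eg <- scn$sp$eigen
        nn <- !eg$is_null
        drop(eg$vectors[, nn, drop = FALSE] %*%
               (rnorm(sum(nn)) * sqrt(eg$xi[nn] * 0.5)))
      })
    p <- inv_logit(logit(1 - scn$P) + scn$beta_true * gamma)
    z <- stats::rbinom(n, 1L, p)
    E <- rep(scn$E_level, n)
    lambda <- E * exp(gamma)
    if (scn$zero_type == "type0") {
      o <- rep(NA_integer_, n)
      occ <- z == 1L
      o[occ] <- rztpois(sum(occ), lambda[occ])
      dat <- observed_data(o, E, z = z)
    } else {
      o <- integer(n)
      act <- z == 1L
      o[act] <- stats::rpois(sum(act), lambda[act])
      dat <- observed_data(o, E)
    }
    truths <- list(
      gamma = gamma,
      one_over_tau_gamma = if (scn$risk_level == "constant") 0 else 0.5,
      phi = if (scn$risk_level == "structured") 1 else 0,
      beta = scn$beta_true,
      alpha_z = logit(1 - scn$P), alpha_o = 0)
    structure(list(data = dat, z = z, o = o, E = E, truths = truths,
                   scenario = scn, replicate = replicate_index,
                   seed = seed),
              class = "simulated_dataset")
  })
}

#' Moran's I spatial autocorrelation statistic
#'
#' Binary-weight Moran's I of a region attribute, used to check that the
#' structured generator produces spatially correlated fields.
#'
#' @param graph a [region_graph].
#' @param x numeric vector over regions.
#' @return Scalar Moran's I.
#' @export
moran_i <- function(graph, x) {
  stopifnot(inherits(graph, "region_graph"), length(x) == graph$n)
  e <- graph$edges
  xc <- x - mean(x)
  num <- 2 * sum(xc[e[, 1L]] * xc[e[, 2L]])
  (graph$n / (2 * nrow(e))) * num / sum(xc^2)
}

# build the fitted model spec matching a family for a simulated dataset
spec_for_family <- function(ds, family, latent = "bym2", priors = NULL) {
  scn <- ds$scenario
  dat <- switch(family,
    joint = if (scn$zero_type == "type0") ds$data else
      as_hurdle_data(ds$o, ds$E),
    zip0 = {
      o <- ifelse(is.na(ds$o), 0L, ds$o)
      observed_data(o, ds$E)
    },
    zip1 = {
      o <- ifelse(is.na(ds$o), 0L, ds$o)
      observed_data(o, ds$E)
    },
    poisson = observed_data(ifelse(is.na(ds$o), 0L, ds$o), ds$E))
  zip_model(dat, scn$sp, family = family, latent = latent, priors = priors)
}

#' Run the simulation study
#'
#' Loops scenarios by model variant, fitting each replicate and averaging
#' posterior summaries, and emits two tables: a parameter-recovery table
#' (replicate-averaged posterior means and average posterior standard
#' deviations of `alpha_z`, `alpha_o`, `1/tau_gamma`, `phi`, `beta`) and a
#' model-comparison table (replicate-averaged DIC and LS). Replicates
#' whose fit fails are logged, excluded and counted.
#'
#' @param scenarios list of [scenario()] objects.
#' @param families model families to fit (subset of `"joint"`, `"zip0"`,
#'   `"zip1"`).
#' @param latents latent models to fit (subset of `"bym2"`, `"bym"`).
#' @param cfg a [sampler_config()]; each replicate fit derives its seed
#'   from the dataset seed.
#' @param compute_selection also compute DIC and LS per replicate (skippable
#'   because the CPO/DIC pass over retained draws costs as much as a short
#'   fit).
#' @param checkpoint optional path to a CSV checkpoint; completed
#'   (scenario, model, replicate) rows found there are not re-run and new
#'   rows are appended as they complete, so an interrupted study resumes.
#' @param verbose print per-replicate progress.
#' @return List of class `study_tables`: `table1`, `table2`, `replicates`
#'   (the per-replicate rows), `failures`.
#' @export
run_study <- function(scenarios, families = "joint", latents = "bym2",
                      cfg = sampler_config(), compute_selection = TRUE,
                      checkpoint = NULL, verbose = FALSE) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint))
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE)
  rows <- list()
  failures <- list()
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    for (family in families) for (latent in latents) {
      priors <- NULL   # calibrated once per (graph, latent)
      for (r in seq_len(scn$n_replicates)) {
        key <- sprintf("%s|%s|%s|P%.2f|E%g|rep%d",
                       scn$risk_level, scn$zero_type,
                       paste(family, latent, sep = "-"),
                       scn$P, scn$E_level, r)
        if (!is.null(done) && key %in% done$key) {
          rows[[key]] <- done[done$key == key, , drop = FALSE]
          next
        }
        row <- tryCatch({
          ds <- generate_dataset(scn, r)
          if (is.null(priors))
            priors <- model_priors(scn$sp, latent = latent)
          spec <- spec_for_family(ds, family, latent, priors)
          fit_cfg <- cfg
          fit_cfg$seed <- ds$seed + 1L
          fit <- fit_zip_model(spec, fit_cfg)
          sm <- posterior_summary(fit)
          sel <- if (compute_selection) selection_report(fit)
                 else list(DIC = NA_real_, LS = NA_real_)
          pick <- function(p, col) {
            i <- match(p, sm$parameter)
            if (is.na(i)) NA_real_ else sm[[col]][i]
          }
          data.frame(
            key = key, risk_level = scn$risk_level,
            zero_type = scn$zero_type, family = family, latent = latent,
            P = scn$P, E = scn$E_level, replicate = r,
            alpha_z = pick("alpha_z", "mean"),
            alpha_z_sd = pick("alpha_z", "sd"),
            alpha_o = pick("alpha_o", "mean"),
            alpha_o_sd = pick("alpha_o", "sd"),
            one_over_tau_gamma = pick("one_over_tau_gamma", "mean"),
            one_over_tau_gamma_sd = pick("one_over_tau_gamma", "sd"),
            phi = pick("phi", "mean"), phi_sd = pick("phi", "sd"),
            beta = pick("beta", "mean"), beta_sd = pick("beta", "sd"),
            DIC = sel$DIC, LS = sel$LS,
            stringsAsFactors = FALSE)
        }, error = function(e) e)
        if (inherits(row, "error")) {
          failures[[key]] <- conditionMessage(row)
          if (verbose) message(sprintf("FAIL %s: %s", key, failures[[key]]))
          next
        }
        rows[[key]] <- row
        if (!is.null(checkpoint))
          utils::write.table(row, checkpoint, sep = ",", append = file.exists(checkpoint),
                             col.names = !file.exists(checkpoint),
                             row.names = FALSE)
        if (verbose) message(sprintf("done %s (phi=%.3f)", key,
                                     row$phi %||% NA))
      }
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  grp <- c("risk_level", "zero_type", "family", "latent", "P", "E")
  mean_na <- function(x) mean(x, na.rm = TRUE)
  table1 <- stats::aggregate(
    reps[c("alpha_z", "alpha_z_sd", "alpha_o", "alpha_o_sd",
           "one_over_tau_gamma", "one_over_tau_gamma_sd",
           "phi", "phi_sd", "beta", "beta_sd")],
    by = reps[grp], FUN = mean_na)
  table2 <- stats::aggregate(reps[c("DIC", "LS")], by = reps[grp],
                             FUN = mean_na)
  structure(list(table1 = table1, table2 = table2, replicates = reps,
                 failures = failures),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat("Parameter recovery (replicate-averaged posterior means):\n")
  print(x$table1, digits = 3, row.names = FALSE)
  cat("\nModel comparison (replicate-averaged):\n")
  print(x$table2, digits = 4, row.names = FALSE)
  if (length(x$failures))
    cat(sprintf("\n%d failed replicate(s)\n", length(x$failures)))
  invisible(x)
}
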