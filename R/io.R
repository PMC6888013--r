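#' Read and write region data CSV files
#'
#' The on-disk format is a comma-separated UTF-8 file with a header row
#' and columns `region_id`, `o`, `E`, optionally `z`, and any further
#' columns treated as covariates (names starting with `x_` go to the
#' count predictor, `y_` to the occurrence predictor). Missing values are
#' written as the string `NA`.
#'
#' @param path CSV file path.
#' @return `read_data_csv()`: an [observed_data] with region labels from
#'   `region_id`.
#' @export
read_data_csv <- function(path) {
  if (!file.exists(path)) stopf("data file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("o", "E"))
    if (!col %in% names(df)) stopf("missing required column '%s'", col)
  xc <- grep("^x_", names(df), value = TRUE)
  yc <- grep("^y_", names(df), value = TRUE)
  dat <- observed_data(
    o = df$o, E = df$E, z = if ("z" %in% names(df)) df$z else NULL,
    x = if (length(xc)) as.matrix(df[xc]) else NULL,
    y = if (length(yc)) as.matrix(df[yc]) else NULL)
  attr(dat, "region_id") <- if ("region_id" %in% names(df)) df$region_id
                            else seq_len(nrow(df))
  dat
}

#' @rdname read_data_csv
#' @param data an [observed_data].
#' @return `write_data_csv()`: `path`, invisibly.
#' @export
write_data_csv <- function(data, path) {
  stopifnot(inherits(data, "observed_data"))
  df <- data.frame(region_id = attr(data, "region_id") %||%
                     seq_len(data$n),
                   o = data$o, E = data$E)
  if (!is.null(data$z)) df$z <- data$z
  if (!is.null(data$x)) {
    x <- as.data.frame(data$x)
    names(x) <- paste0("x_", seq_len(ncol(x)))
    df <- cbind(df, x)
  }
  if (!is.null(data$y)) {
    y <- as.data.frame(data$y)
    names(y) <- paste0("y_", seq_len(ncol(y)))
    df <- cbind(df, y)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write posterior summary and samples CSV files
#'
#' `write_summary_csv()` writes the [posterior_summary()] table, stamped
#' with the seed and a configuration digest in comment-free extra
#' columns; `write_samples_csv()` writes one row per retained draw of the
#' scalar parameters.
#'
#' @param fit a `zip_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(fit, path) {
  sm <- posterior_summary(fit)
  sm$seed <- fit$cfg$seed
  sm$config_digest <- config_digest(fit$cfg)
  utils::write.csv(sm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
write_samples_csv <- function(fit, path) {
  utils::write.csv(fit$draws, path, row.names = FALSE)
  invisible(path)
}

# small stable digest of a configuration list (no external deps)
config_digest <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (k in v) h <- (h * 33 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a run configuration file
#'
#' A declarative JSON file naming the model (`family`, `latent`), prior
#' parameters, sampler settings and seed; unknown fields are kept and
#' passed through. See `inst/cli/spatzip` for the command-line surface
#' that consumes these files.
#'
#' @param path JSON file path.
#' @return Named list with at least `family`, `latent` and a
#'   [sampler_config()] under `$sampler`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$family <- cfg$family %||% "joint"
  cfg$latent <- cfg$latent %||% "bym2"
  sc <- cfg$sampler %||% list()
  cfg$sampler <- sampler_config(
    n_iter = sc$n_iter %||% 6000, n_burnin = sc$n_burnin %||% 1000,
    thin = sc$thin %||% 1, seed = sc$seed %||% cfg$seed %||% 1)
  cfg
}

#' Fit a model from files
#'
#' Thin end-to-end wrapper tying the I/O to the model fit: reads a data
#' CSV and a graph file, fits the requested model and writes the summary,
#' samples and model-selection CSVs. This is the function behind the
#' `fit` subcommand of the command-line script.
#'
#' @param data_csv path to a data CSV (see [read_data_csv()]).
#' @param graph_file path to a graph file.
#' @param graph_format `"edge_list"` or `"inla_graph"`.
#' @param family,latent model choices as in [zip_model()].
#' @param cfg a [sampler_config()].
#' @param out_prefix prefix for the output files
#'   (`<prefix>_summary.csv`, `<prefix>_samples.csv`,
#'   `<prefix>_selection.csv`).
#' @return The `zip_fit`, invisibly; called for its file side effects.
#' @export
cli_fit <- function(data_csv, graph_file,
                    graph_format = c("edge_list", "inla_graph"),
                    family = "joint", latent = "bym2",
                    cfg = sampler_config(), out_prefix = "fit") {
  graph_format <- match.arg(graph_format)
  dat <- read_data_csv(data_csv)
  g <- read_graph(graph_file, graph_format)
  sp <- scale_icar(g)
  if (family == "joint" && is.null(dat$z))
    dat <- as_hurdle_data(dat$o, dat$E, x = dat$x, y = dat$y)
  spec <- zip_model(dat, sp, family = family, latent = latent)
  fit <- fit_zip_model(spec, cfg)
  write_summary_csv(fit, paste0(out_prefix, "_summary.csv"))
  write_samples_csv(fit, paste0(out_prefix, "_samples.csv"))
  sel <- selection_report(fit)
  utils::write.csv(
    data.frame(model = paste(family, latent, sep = "-"),
               DIC = sel$DIC, pD = sel$pD, LS = sel$LS,
               seed = cfg$seed, config_digest = config_digest(cfg)),
    paste0(out_prefix, "_selection.csv"), row.names = FALSE)
  invisible(fit)
}
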