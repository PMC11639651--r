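#' Read and validate a run configuration
#'
#' Configurations drive [run_dca()] and [run_simulation()] and may come
#' from a YAML or JSON file or be given directly as a list. Recognized
#' keys: `mode` (`"binary"`, `"survival"` or `"simulate"`), `input`
#' (CSV path), `thresholds` (either a list of values or
#' `{min, max, step}`), `horizon`, `priors` (`p`/`se`/`sp` or
#' `positivity` as `[shape1, shape2]`; `weibull` as
#' `{family, shape, scale}`), `draws`, `mcmc`
#' (`{chains, warmup, draws}`), `external_prevalence`
#' (`[cases, noncases]`, binary mode only), `seed`, `output`
#' (directory), `plots` (logical), and for simulations `setting`,
#' `reps`, `expected_events`, `population_size`.
#'
#' @param config A list, or a path to a `.yaml`/`.yml`/`.json` file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or file path",
                             call. = FALSE)
  mode <- config$mode %||% stop("config needs a 'mode'", call. = FALSE)
  if (!mode %in% c("binary", "survival", "simulate")) {
    stop("mode must be binary, survival or simulate", call. = FALSE)
  }
  if (mode == "survival" && is.null(config$horizon)) {
    stop("survival mode requires a prediction horizon", call. = FALSE)
  }
  if (mode != "binary" && !is.null(config$external_prevalence)) {
    stop("external_prevalence is only valid in binary mode",
         call. = FALSE)
  }
  if (mode %in% c("binary", "survival") && is.null(config$input)) {
    stop("mode '", mode, "' requires an 'input' CSV path", call. = FALSE)
  }
  if (mode == "simulate" && is.null(config$setting)) {
    stop("simulate mode requires a 'setting' id", call. = FALSE)
  }
  config
}

config_grid <- function(spec) {
  if (is.null(spec)) return(threshold_grid())
  if (is.numeric(spec)) return(threshold_grid(spec))
  if (is.list(spec) && all(c("min", "max", "step") %in% names(spec))) {
    return(threshold_grid(min = spec$min, max = spec$max,
                          step = spec$step))
  }
  if (is.list(spec) && is.numeric(unlist(spec))) {
    return(threshold_grid(unlist(spec)))
  }
  stop("cannot interpret thresholds specification", call. = FALSE)
}

config_priors <- function(spec, mode) {
  if (is.null(spec)) return(NULL)
  out <- list()
  as_beta <- function(x) beta_prior(x[[1]], x[[2]])
  for (key in c("p", "se", "sp", "positivity")) {
    if (!is.null(spec[[key]])) out[[key]] <- as_beta(spec[[key]])
  }
  if (!is.null(spec$weibull)) {
    w <- spec$weibull
    out$weibull <- weibull_prior(family = w$family %||% "half_t",
                                 shape = unlist(w$shape),
                                 scale = unlist(w$scale))
  }
  out
}

write_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(config = config,
                     package = "postDCA",
                     package_version = as.character(packageVersion("postDCA")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run a complete Bayesian decision curve analysis from a configuration
#'
#' Reads the validation CSV, fits the binary or survival model over the
#' threshold grid, interrogates the posterior curves and writes
#' `curves.csv` (posterior summaries), `interrogation.csv`/`.json`,
#' `nb_draws.csv` (long-format draws), `diagnostics.json` (survival
#' MCMC), a reproducibility `manifest.json` and, when `plots: true`,
#' decision-curve/probability/EVPI figures into the output directory.
#'
#' @param config Configuration list or file path
#'   (see [read_run_config()]).
#' @return Invisibly, a list with the fitted `dca_set`, the
#'   interrogation data frame and the written file paths.
#' @export
run_dca <- function(config) {
  config <- read_run_config(config)
  mode <- config$mode
  stopifnot(mode %in% c("binary", "survival"))
  out_dir <- config$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- config_grid(config$thresholds)
  priors <- config_priors(config$priors, mode)
  seed <- config$seed

  if (mode == "binary") {
    data <- read_validation_csv(config$input, "binary")
    set <- dca_binary(data, grid, priors = priors,
                      M = config$draws %||% 4000, seed = seed,
                      external_prevalence =
                        if (!is.null(config$external_prevalence))
                          unlist(config$external_prevalence))
  } else {
    data <- read_validation_csv(config$input, "survival",
                                horizon = config$horizon)
    set <- dca_survival(data, grid, horizon = config$horizon,
                        priors = priors, mcmc = config$mcmc %||% list(),
                        seed = seed)
  }

  res <- interrogate(set)
  paths <- list(
    curves = file.path(out_dir, "curves.csv"),
    interrogation_csv = file.path(out_dir, "interrogation.csv"),
    interrogation_json = file.path(out_dir, "interrogation.json"),
    draws = file.path(out_dir, "nb_draws.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write.csv(summarize_curves(set), paths$curves, row.names = FALSE)
  write_interrogation(res, csv = paths$interrogation_csv,
                      json = paths$interrogation_json)
  export_nb_draws(set, paths$draws)
  if (mode == "survival") {
    paths$diagnostics <- file.path(out_dir, "diagnostics.json")
    jsonlite::write_json(mcmc_diagnostics(set), paths$diagnostics,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (isTRUE(config$plots)) {
    paths$plots <- export_plots(res, out_dir)
  }
  write_manifest(paths$manifest, config,
                 extra = list(n = data$n,
                              strategies = set$strategies,
                              zero_positive_cells = sum(set$flags)))
  invisible(list(set = set, interrogation = res, paths = paths))
}

#' Run a simulation study from a configuration
#'
#' Drives [run_simulation_study()] for a canonical setting id and writes
#' `report.csv` (per-threshold coverage, MAPE, bias) plus a
#' `manifest.json` capturing the configuration and seeds.
#'
#' @param config Configuration list or file path; requires `setting`,
#'   honours `reps`, `seed`, `thresholds`, `draws`, `expected_events`,
#'   `population_size`, `mcmc`, `output`.
#' @return Invisibly, a list with the `simulation_report` and file paths.
#' @export
run_simulation <- function(config) {
  config <- read_run_config(config)
  stopifnot(config$mode == "simulate")
  out_dir <- config$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- if (is.null(config$thresholds)) {
    threshold_grid(min = 0.05, max = 0.45, step = 0.05)
  } else {
    config_grid(config$thresholds)
  }
  report <- run_simulation_study(
    config$setting, n_reps = config$reps %||% 500, grid = grid,
    M = config$draws %||% 4000,
    expected_events = config$expected_events %||% 100,
    population_size = config$population_size %||% 1e5,
    seed = config$seed %||% 1,
    mcmc = config$mcmc %||% list())
  paths <- list(report = file.path(out_dir, "report.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write.csv(as.data.frame(report), paths$report, row.names = FALSE)
  write_manifest(paths$manifest, config,
                 extra = list(setting = attr(report, "setting"),
                              failed_reps = attr(report, "failed")))
  invisible(list(report = report, paths = paths))
}
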