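# Pipeline orchestration: simulate (optional) -> fit -> ensemble stats ->
# microscopic inference -> capacity report, with a manifest for
# reproducibility. The pipeline is a pure function of (input data, config,
# seeds).

#' Pipeline configuration
#'
#' @param input Path to a dose-response CSV, or NULL to simulate a panel
#'   from `generator` instead.
#' @param generator A [generator_spec()] (used when `input` is NULL).
#' @param out_dir Output directory (created if absent).
#' @param corr_threshold Fit-reliability threshold, default 0.9.
#' @param min_partners Minimum activating partners per odorant for the
#'   microscopic table, default 20.
#' @param N_r,M,L Perception constants: receptor types, odorant count,
#'   OR copies per neuron.
#' @param sigma_ec50 Ensemble EC50 width (decades) for the Weber and
#'   capacity report, default 1.5.
#' @param seed Seed for stochastic stages (mixture-EM restarts).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            out_dir = tempfile("orkin_run_"),
                            corr_threshold = 0.9, min_partners = 20,
                            N_r = 330, M = 1e4, L = 2.5e4,
                            sigma_ec50 = 1.5, seed = 1) {
  if (corr_threshold < -1 || corr_threshold > 1) {
    stop("pipeline_config: corr_threshold must lie in [-1, 1]")
  }
  stopifnot(min_partners >= 1, N_r >= 1, M > 1, L >= 1, sigma_ec50 > 0)
  if (is.null(input) && is.null(generator)) {
    stop("pipeline_config: supply an input CSV or a generator_spec")
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_spec"))
  structure(list(input = input, generator = generator, out_dir = out_dir,
                 corr_threshold = corr_threshold,
                 min_partners = min_partners, N_r = N_r, M = M, L = L,
                 sigma_ec50 = sigma_ec50, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (optionally) simulate a synthetic panel; fit every pair's Hill
#' curve; classify and summarize the parameter ensemble; build the
#' odorant-averaged microscopic-constant table; compute the perception
#' (Weber/capacity) report. Artifacts are written under
#' `config$out_dir`: `panel.csv` (+ `truth.csv`) when simulating,
#' `fits.csv`, `ensemble.json`, `micro_table.csv`, `capacity.json` and a
#' `manifest.json` recording inputs, configuration and package version.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages. Default FALSE.
#' @return A list with `fits`, `ensemble`, `micro_table`, `capacity`,
#'   `paths` (invisible file map), and `counts`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[orkin] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (is.null(config$input)) {
    say("simulate: generating synthetic panel (seed ",
        config$generator$seed, ")")
    sim <- generate_dataset(config$generator)
    data <- sim$data
    paths$panel <- file.path(config$out_dir, "panel.csv")
    paths$truth <- file.path(config$out_dir, "truth.csv")
    write_dose_response(data, paths$panel)
    utils::write.csv(sim$truth, paths$truth, row.names = FALSE)
  } else {
    say("load: ", config$input)
    data <- read_dose_response(config$input)
  }

  say("fit: ", length(unique(paste(data$receptor_id, data$odorant_id))),
      " pairs")
  fits <- fit_panel(data, fit_config(corr_threshold = config$corr_threshold))
  paths$fits <- file.path(config$out_dir, "fits.csv")
  write_fit_records(fits, paths$fits)

  say("stats: ensemble model")
  ensemble <- fit_ensemble_model(fits, config$corr_threshold,
                                 seed = config$seed)
  paths$ensemble <- file.path(config$out_dir, "ensemble.json")
  jsonlite::write_json(
    list(ec50_activating = ensemble$ec50_activating,
         ec50_all = ensemble$ec50_all,
         efficacy_mixture = ensemble$efficacy_mixture[
           c("phi", "mean1", "mean2", "loglik", "lr_stat")],
         dSmax_mixture = ensemble$dSmax_mixture[
           c("phi", "mean1", "mean2", "loglik", "lr_stat")],
         counts = as.list(ensemble$counts)),
    paths$ensemble, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("infer: microscopic table (min_partners = ", config$min_partners, ")")
  micro <- build_micro_table(fits, min_partners = config$min_partners)
  paths$micro <- file.path(config$out_dir, "micro_table.csv")
  utils::write.csv(micro, paths$micro, row.names = FALSE)

  say("capacity: perception report")
  cap <- list(
    N_r = config$N_r, M = config$M, L = config$L,
    sigma_ec50 = config$sigma_ec50,
    code_capacity_log10 = code_capacity_log10(config$N_r),
    weber_ratio_min = weber_ratio_min(config$N_r, config$sigma_ec50),
    weber_ratio_uniform = weber_ratio_uniform(config$N_r,
                                              config$sigma_ec50)$weber,
    mixture_capacity = mixture_capacity_mmax(config$M, config$N_r))
  paths$capacity <- file.path(config$out_dir, "capacity.json")
  jsonlite::write_json(cap, paths$capacity, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(
    package = "orkin",
    version = as.character(utils::packageVersion("orkin")),
    r_version = as.character(getRversion()),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    input = if (is.null(config$input)) "simulated" else config$input,
    config = config[setdiff(names(config), "generator")],
    generator = if (!is.null(config$generator)) {
      unclass(config$generator)
    },
    outputs = paths)
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  say("done in ", sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")),
      " s")
  out <- list(fits = fits, ensemble = ensemble, micro_table = micro,
              capacity = cap, counts = ensemble$counts, paths = paths)
  invisible(out)
}
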