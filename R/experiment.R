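#' Experiment configuration
#'
#' Declarative description of a full study: the trait sampler, the model
#' environment, the regime grid (continuous supply plus a grid of pulsing
#' intervals — the continuous run is mandatory because all overlap metrics
#' are defined relative to it), variant switches and solver controls.
#'
#' @param sampler a [sampler_config()].
#' @param intervals pulsing-interval grid in hours (study grid:
#'   `c(0.5, 1, 2, 4, 12, 24)`); the continuous regime is always included.
#' @param resource_rule `"substitutable"` or `"essential"`; with
#'   `"essential"` the sampler's `rate_convention` should be `"min"`.
#' @param mortality_mode,pulse_dialect see [supply_regime()].
#' @param mortality_rate,dilution_rate,supply_concentration,quota model
#'   environment; see [model_spec()].
#' @param init_density initial density of every consumer.
#' @param extinction_frac extinction threshold as a fraction of
#'   `init_density`.
#' @param horizon_h maximum simulated time per run, hours.
#' @param controls a [solver_controls()].
#' @param compute_stability also compute the per-combination stability
#'   report.
#' @param seed master seed; overrides `sampler$seed` so one integer pins the
#'   whole study.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sampler = sampler_config(),
                              intervals = c(0.5, 1, 2, 4, 12, 24),
                              resource_rule = c("substitutable", "essential"),
                              mortality_mode = c("intermittent", "continuous"),
                              pulse_dialect = c("serial_transfer", "additive"),
                              mortality_rate = 0.2,
                              dilution_rate = 0.2,
                              supply_concentration = 1,
                              quota = 1,
                              init_density = 0.01,
                              extinction_frac = 1e-4,
                              horizon_h = 8000,
                              controls = solver_controls(),
                              compute_stability = TRUE,
                              seed = NULL) {
  resource_rule <- match.arg(resource_rule)
  mortality_mode <- match.arg(mortality_mode)
  pulse_dialect <- match.arg(pulse_dialect)
  if (length(intervals) < 1 || any(intervals <= 0)) {
    stop("`intervals` must be positive pulsing intervals in hours")
  }
  if (!is.null(seed)) sampler$seed <- as.integer(seed)
  structure(
    list(sampler = sampler, intervals = sort(as.numeric(intervals)),
         resource_rule = resource_rule, mortality_mode = mortality_mode,
         pulse_dialect = pulse_dialect, mortality_rate = mortality_rate,
         dilution_rate = dilution_rate,
         supply_concentration = supply_concentration, quota = quota,
         init_density = init_density, extinction_frac = extinction_frac,
         horizon_h = horizon_h, controls = controls,
         compute_stability = compute_stability),
    class = "experiment_config"
  )
}

build_spec <- function(traits, config) {
  traits$quota[] <- config$quota
  model_spec(traits, resource_rule = config$resource_rule,
             mortality_rate = config$mortality_rate,
             supply_concentration = config$supply_concentration,
             dilution_rate = config$dilution_rate)
}

simulate_combo <- function(traits, config) {
  spec <- build_spec(traits, config)
  init <- system_state(rep(config$init_density, traits$n_consumers),
                       spec$supply_concentration)
  cont <- simulate_community(spec, supply_regime("continuous"), init = init,
                             horizon_h = config$horizon_h,
                             controls = config$controls)
  pulsed <- lapply(config$intervals, function(T) {
    simulate_community(
      spec,
      supply_regime("pulsed", interval_h = T,
                    mortality_mode = config$mortality_mode,
                    pulse_dialect = config$pulse_dialect),
      init = init, horizon_h = config$horizon_h, controls = config$controls
    )
  })
  names(pulsed) <- as.character(config$intervals)
  list(continuous = cont, pulsed = pulsed, spec = spec)
}

#' Run the full study
#'
#' Samples the configured number of competitor combinations, simulates each
#' under continuous supply and under every pulsing interval of the grid,
#' summarises compositional overlap, richness and weighted mean traits, and
#' (optionally) the stability report.  Every result is a pure function of
#' the configuration; per-combination child seeds are derived from the
#' master seed so execution order cannot change the outcome.
#'
#' @param config an [experiment_config()].
#' @param n_combos number of combinations to run (defaults to the full study
#'   size); see [reduced_run()].
#' @param out_dir optional output directory; when given, writes `traits.csv`,
#'   `runs.csv`, `combo_summary.csv`, `interval_summary.csv`,
#'   `stability.csv` (if computed) and `manifest.json`.
#' @param progress print one line per combination to stderr.
#' @return A list of class `crm_experiment` with `study`, the
#'   [summarise_study()] tables, `stability`, and `manifest`.
#' @export
run_experiment <- function(config, n_combos = config$sampler$n_combos,
                           out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  study <- sample_study(config$sampler, n_combos = n_combos)
  results <- vector("list", n_combos)
  for (ci in seq_len(n_combos)) {
    results[[ci]] <- simulate_combo(study$traits[[ci]], config)
    if (progress) {
      conv <- vapply(c(list(results[[ci]]$continuous), results[[ci]]$pulsed),
                     function(s) s$converged, logical(1))
      message(sprintf("combo %d/%d: %d/%d runs steady",
                      ci, n_combos, sum(conv), length(conv)))
    }
  }
  tables <- summarise_study(results, study,
                            extinction_frac = config$extinction_frac)
  stability <- NULL
  if (config$compute_stability) {
    stability <- stability_report(
      lapply(results, `[[`, "spec"),
      lapply(results, `[[`, "continuous"),
      tables$combo_summary,
      extinction_frac = config$extinction_frac
    )
  }
  manifest <- list(
    package = "pulseCR",
    version = as.character(utils::packageVersion("pulseCR")),
    n_combos = n_combos,
    combo_seeds = study$seeds,
    config = config_to_list(config)
  )
  out <- structure(
    list(study = study, runs = tables$runs,
         combo_summary = tables$combo_summary,
         interval_summary = tables$interval_summary,
         stability = stability, manifest = manifest),
    class = "crm_experiment"
  )
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' Run the pipeline on a prefix of the study
#'
#' Identical to [run_experiment()] but restricted to the first `n_combos`
#' child seeds of the configured study, so a reduced run is always a prefix
#' of the full one.
#'
#' @inheritParams run_experiment
#' @param n_combos number of combinations (1 to `config$sampler$n_combos`).
#' @return See [run_experiment()].
#' @export
reduced_run <- function(config, n_combos, out_dir = NULL, progress = FALSE) {
  if (n_combos < 1) stop("`n_combos` must be at least 1")
  if (n_combos > config$sampler$n_combos) {
    stop("`n_combos` exceeds the configured study size")
  }
  run_experiment(config, n_combos = n_combos, out_dir = out_dir,
                 progress = progress)
}

#' @export
print.crm_experiment <- function(x, ...) {
  cat("<crm_experiment> ", x$manifest$n_combos, " combos; tradeoff = ",
      x$manifest$config$sampler$tradeoff, "; rule = ",
      x$manifest$config$resource_rule, "\n", sep = "")
  print(x$interval_summary)
  invisible(x)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$sampler <- unclass(out$sampler)
  out$controls <- unclass(out$controls)
  out
}

#' Rebuild an experiment configuration from a plain list
#'
#' Inverse of the representation stored in manifests and YAML config files.
#'
#' @param x a named list with (subsets of) the fields of
#'   [experiment_config()], [sampler_config()] and [solver_controls()].
#' @return An [experiment_config()].
#' @export
as_experiment_config <- function(x) {
  sampler <- do.call(sampler_config, as.list(x$sampler))
  controls <- do.call(solver_controls, as.list(x$controls))
  args <- x[setdiff(names(x), c("sampler", "controls"))]
  args$intervals <- as.numeric(unlist(args$intervals))
  do.call(experiment_config, c(list(sampler = sampler, controls = controls),
                               args))
}

#' Read and write experiment configurations as YAML
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  as_experiment_config(yaml::read_yaml(path))
}

#' Write the tables of an experiment to disk
#'
#' Writes `traits.csv` (long format over all combinations), `runs.csv`,
#' `combo_summary.csv`, `interval_summary.csv`, `stability.csv` (when
#' computed) and a `manifest.json` holding the complete configuration —
#' every default included — plus the per-combination seeds, so the run can
#' be reproduced from the manifest alone.
#'
#' @param experiment a [run_experiment()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(experiment, out_dir) {
  stopifnot(inherits(experiment, "crm_experiment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traits_long <- dplyr::bind_rows(lapply(
    names(experiment$study$traits),
    function(id) as_trait_tibble(experiment$study$traits[[id]], combo_id = id)
  ))
  readr::write_csv(traits_long, file.path(out_dir, "traits.csv"))
  readr::write_csv(experiment$runs, file.path(out_dir, "runs.csv"))
  readr::write_csv(experiment$combo_summary,
                   file.path(out_dir, "combo_summary.csv"))
  readr::write_csv(experiment$interval_summary,
                   file.path(out_dir, "interval_summary.csv"))
  if (!is.null(experiment$stability)) {
    readr::write_csv(experiment$stability, file.path(out_dir, "stability.csv"))
  }
  jsonlite::write_json(experiment$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-run an experiment from its manifest
#'
#' @param path path to a `manifest.json` written by [write_experiment()].
#' @param out_dir optional output directory for the re-run.
#' @return See [run_experiment()].
#' @export
run_from_manifest <- function(path, out_dir = NULL) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- as_experiment_config(man$config)
  run_experiment(config, n_combos = man$n_combos, out_dir = out_dir)
}

#' Minimal summary plot of compositional overlap across intervals
#'
#' Mean Jaccard similarity (vs. the continuous run) against the pulsing
#' interval, one line per experiment.
#'
#' @param ... named [run_experiment()] results.
#' @return A ggplot object.
#' @export
plot_interval_summary <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("`plot_interval_summary()` needs ggplot2")
  }
  exps <- list(...)
  if (is.null(names(exps)) || any(names(exps) == "")) {
    names(exps) <- paste0("experiment", seq_along(exps))
  }
  df <- dplyr::bind_rows(lapply(names(exps), function(nm) {
    dplyr::mutate(
      dplyr::filter(exps[[nm]]$interval_summary, !is.na(.data$interval_h)),
      parametrisation = nm
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$interval_h, .data$mean_jaccard,
                                   colour = .data$parametrisation)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_jaccard - .data$se_jaccard,
      ymax = .data$mean_jaccard + .data$se_jaccard
    )) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "pulsing interval (h)",
                  y = "Jaccard similarity vs. continuous supply") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
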