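# The two-scenario experiment: run alternative fertility assumptions over a
# shared base population, shared schedules, shared participation model, and
# a shared seed (common random numbers), then compare dependency indicators.

#' Experiment configuration
#'
#' Scenarios differ in the TFR only; every other assumption — base
#' population, schedules, participation parameters, seed — is shared, so
#' projected differences are attributable to fertility alone.
#'
#' @param scenarios named numeric vector of scenario TFRs (default: the low
#'   0.8 / high 1.7 pair).
#' @param seed shared seed for the counter-based streams.
#' @param start,horizon projection window.
#' @param normalize_to period the indicator series are normalized to
#'   (default: `start`).
#' @param ... further arguments passed to [scenario_config()] (sampling
#'   constants, sex ratio at birth, ladder).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(scenarios = c(tfr_low = 0.8, tfr_high = 1.7),
                              seed = 1L, start = 2015L, horizon = 2070L,
                              normalize_to = start, ...) {
  if (!length(scenarios) || any(scenarios < 0))
    stop("scenarios must be nonnegative TFRs")
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- paste0("tfr_", scenarios)
  configs <- lapply(scenarios, function(tfr)
    scenario_config(tfr = tfr, start = start, horizon = horizon,
                    seed = seed, ...))
  structure(list(scenarios = scenarios, configs = configs, seed = seed,
                 start = start, horizon = horizon,
                 normalize_to = normalize_to),
            class = "experiment_config")
}

#' Run the multi-scenario experiment
#'
#' Builds (or accepts) the base population, runs every scenario with common
#' random numbers, and computes raw and normalized indicator series plus a
#' combined comparison table. Any stage error aborts with the scenario and
#' stage named.
#'
#' @param estimates aggregate base estimates (data.frame) shared by all
#'   scenarios.
#' @param schedules a [rate_schedules()] shared by all scenarios.
#' @param lfp_params an [lfp_logit_params()].
#' @param weights a [derive_productivity_weights()] vector.
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, per-scenario frame CSVs,
#'   event tallies, indicator CSVs and a run manifest are written there.
#' @return object of class `lf_experiment`: per-scenario `projections`,
#'   `indicators` (raw) and `indicators_norm`, and a long `comparison`
#'   table (scenario, period, indicator, value, value_norm).
#' @export
run_experiment <- function(estimates, schedules, lfp_params, weights, cfg,
                           out_dir = NULL) {
  stage <- function(what, scn, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", what, "' failed",
           if (nzchar(scn)) paste0(" [scenario ", scn, "]") else "",
           ": ", conditionMessage(e), call. = FALSE))
  }

  projections <- indicators <- indicators_norm <- list()
  for (scn in names(cfg$scenarios)) {
    scfg <- cfg$configs[[scn]]
    base <- stage("base_population", scn,
                  build_base_population(estimates, scfg))
    proj <- stage("projection", scn,
                  run_projection(base, schedules, lfp_params, scfg))
    ind <- stage("indicators", scn, indicator_series(proj, weights))
    projections[[scn]] <- proj
    indicators[[scn]] <- ind
    indicators_norm[[scn]] <- normalize_series(ind, cfg$normalize_to)
  }

  comparison <- do.call(rbind, lapply(names(indicators), function(scn) {
    raw <- indicators[[scn]]; nrm <- indicators_norm[[scn]]
    do.call(rbind, lapply(c("adr", "lfdr", "pwlfdr"), function(ind)
      data.frame(scenario = scn, period = raw$period, indicator = ind,
                 value = raw[[ind]], value_norm = nrm[[ind]])))
  }))

  out <- structure(list(projections = projections, indicators = indicators,
                        indicators_norm = indicators_norm,
                        comparison = comparison, config = cfg),
                   class = "lf_experiment")
  if (!is.null(out_dir)) write_experiment(out, weights, out_dir)
  out
}

# Write every experiment output plus a manifest from which the run is
# reproducible (scenario TFRs, seed, window, package version).
write_experiment <- function(exp, weights, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (scn in names(exp$projections)) {
    sdir <- file.path(out_dir, scn)
    dir.create(sdir, showWarnings = FALSE)
    proj <- exp$projections[[scn]]
    for (p in names(proj$frames))
      write_frame_csv(proj$frames[[p]], file.path(sdir, paste0("frame_", p, ".csv")))
    write.csv(proj$tallies, file.path(sdir, "events.csv"), row.names = FALSE)
    ind <- merge(exp$indicators[[scn]], exp$indicators_norm[[scn]],
                 by = "period", suffixes = c("", "_norm"))
    write.csv(ind, file.path(sdir, "indicators.csv"), row.names = FALSE)
  }
  write.csv(exp$comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)
  write.csv(data.frame(education = names(weights), weight = as.numeric(weights)),
            file.path(out_dir, "productivity_weights.csv"), row.names = FALSE)
  manifest <- list(
    scenarios = as.list(exp$config$scenarios),
    seed = exp$config$seed,
    start = exp$config$start, horizon = exp$config$horizon,
    normalize_to = exp$config$normalize_to,
    package_version = as.character(utils::packageVersion("lfdemosim")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the experiment entirely from a synthetic world
#'
#' Convenience wrapper: generates estimates, schedules and survey microdata
#' from the spec, fits the participation and wage models on the synthetic
#' survey, derives productivity weights, and runs the scenarios.
#'
#' @param spec a [synthetic_world_spec()].
#' @param cfg an [experiment_config()].
#' @param survey_n synthetic survey sample size used for calibration.
#' @param out_dir optional output directory (see [run_experiment()]).
#' @return an `lf_experiment`, with the calibrated `lfp_params` and
#'   `weights` attached.
#' @export
run_experiment_synthetic <- function(spec, cfg, survey_n = 57411L,
                                     out_dir = NULL) {
  estimates <- make_aggregate_estimates(spec)
  schedules <- make_rate_schedules(spec, cfg$start, cfg$horizon)
  survey <- make_survey_microdata(spec, survey_n, seed = cfg$seed)
  lfp <- fit_lfp_logit(survey$records, spec$ladder)
  wage <- fit_wage_poisson(survey$records, spec$ladder)
  weights <- derive_productivity_weights(wage)
  out <- run_experiment(estimates, schedules, lfp, weights, cfg, out_dir)
  out$lfp_params <- lfp
  out$weights <- weights
  out
}
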