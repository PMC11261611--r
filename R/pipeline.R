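#' Run a dose-response scenario end to end
#'
#' Simulates the scenario, processes traces to iRatio peaks with reference
#' correction against the non-responding (umami) receptor group, and fits
#' the Hill curve on the per-spot responses of the sweet receptor.
#'
#' @param scenario A dose-response scenario from [preset_scenario()].
#' @param seed Integer seed for the trace simulation.
#' @return List with `fit` (a `hill_fit`), `table` (per-spot dose/response
#'   rows) and `trace_set`.
#' @export
run_dose_response <- function(scenario, seed = 1) {
  stopifnot(scenario$kind == "dose_response")
  ts <- simulate_traces(scenario$spots, scenario$models, scenario$flow_config,
                        scenario$schedule, scenario$noise, seed = seed)
  tbl <- iratio_table(ts, reference_receptor = scenario$reference_receptor)
  sweet <- tbl[tbl$receptor == "TAS1R2_R3", , drop = FALSE]
  inj_ids <- vapply(scenario$schedule, `[[`, character(1), "injection_id")
  dose_of <- stats::setNames(scenario$doses, inj_ids)
  sweet$dose <- dose_of[sweet$injection_id]
  fit <- fit_hill(sweet$dose, sweet$iratio)
  list(fit = fit, table = sweet, trace_set = ts)
}

#' Run a kinetics scenario end to end
#'
#' Simulates the scenario, builds the reference-corrected mean ratio trace
#' of the sweet receptor group, takes the dye exposure profile of the
#' reference injection as the fluorescein curve, and computes the kinetic
#' metrics for the EC50-dose and maximum-dose injections.
#'
#' @param scenario A kinetics scenario from [preset_scenario()].
#' @param seed Integer seed.
#' @param onset_mode Passed to [kinetic_metrics()].
#' @return List with `high` and `ec50` (`kinetic_metrics`), plus the curves.
#' @export
run_kinetics <- function(scenario, seed = 1, onset_mode = "peak_max") {
  stopifnot(scenario$kind == "kinetics")
  ts <- simulate_traces(scenario$spots, scenario$models, scenario$flow_config,
                        scenario$schedule, scenario$noise, seed = seed)
  spots <- qc_filter(ts$spots)
  ratios <- compute_ratio(ts, spots = spots)
  ref_trace <- mean_ratio_trace(ratios, scenario$reference_receptor)
  sweet_mean <- mean_ratio_trace(ratios, "TAS1R2_R3")
  corrected <- reference_correct(sweet_mean, ref_trace)
  v <- vapply(scenario$schedule, `[[`, numeric(1), "valve_time")
  dye <- simulate_exposure(scenario$flow_config, valve_times = v[1], dt = 0.5,
                           duration = max(corrected$times))
  dye_prof <- list(times = dye$times, values = dye$concentration)
  met <- function(valve) kinetic_metrics(corrected, dye_prof, valve,
                                         reference_valve_time = v[1],
                                         onset_mode = onset_mode)
  list(high = suppressWarnings(met(v[3])), ec50 = suppressWarnings(met(v[2])),
       corrected = corrected, dye = dye_prof, trace_set = ts)
}

#' Run the antagonist-blocking scenario end to end
#'
#' Simulates the scenario, computes the iRatio table, fits the mixed-model
#' contrasts of every treatment injection against the blank control plus the
#' intersample pairs (mixture vs first agonist injection; repeat agonist vs
#' first), and derives blocking percentages for the responding bitter
#' receptors.
#'
#' @param scenario The blocking scenario from [preset_scenario()].
#' @param seed Integer seed.
#' @param receptors Receptors for which a blocking percentage is computed.
#' @return List with `contrasts` (data.frame), `blocking` (named vector, %),
#'   and `table`.
#' @export
run_blocking <- function(scenario, seed = 1,
                         receptors = c("TAS2R8", "TAS2R31", "TAS2R43")) {
  stopifnot(scenario$kind == "blocking")
  ts <- simulate_traces(scenario$spots, scenario$models, scenario$flow_config,
                        scenario$schedule, scenario$noise, seed = seed)
  tbl <- iratio_table(ts)
  ctl <- scenario$control_injection
  trt <- scenario$treatment_injections
  pairs <- rbind(
    data.frame(treatment = unname(trt), control = ctl),
    data.frame(treatment = c(trt[["mix"]], trt[["repeat_pure"]]),
               control = trt[["pure"]]))
  cs <- fit_contrasts(tbl, pairs)
  blocking <- vapply(receptors, function(r) {
    ep <- cs[cs$receptor == r & cs$treatment == trt[["pure"]] &
               cs$control == ctl, , drop = FALSE]
    em <- cs[cs$receptor == r & cs$treatment == trt[["mix"]] &
               cs$control == ctl, , drop = FALSE]
    blocking_percent(ep, em)
  }, numeric(1))
  list(contrasts = cs, blocking = blocking, table = tbl, trace_set = ts)
}

#' Run a preset scenario (or a full run configuration) end to end
#'
#' Dispatches on the scenario kind: flow calibration produces the
#' calibration table; dose-response scenarios produce Hill fits; kinetics
#' scenarios produce kinetic metric sets; the blocking scenario produces
#' contrasts and blocking percentages. Composite presets return one result
#' per sub-scenario. When `out_dir` is given, all tabular outputs are
#' written as CSV/JSON together with a machine-readable run log carrying
#' the seed, parameters and a configuration hash.
#'
#' @param scenario A scenario from [preset_scenario()], or a preset name.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return The result list (see details), invisibly when writing to disk.
#' @export
run_pipeline <- function(scenario, seed = 1, out_dir = NULL) {
  if (is.character(scenario)) scenario <- preset_scenario(scenario, seed = seed)
  res <- switch(
    scenario$kind,
    calibration = calibration_table(scenario$cell_volumes,
                                    scenario$injection_volumes,
                                    scenario$flow_rates,
                                    n_tanks = scenario$n_tanks),
    dose_response = run_dose_response(scenario, seed = seed),
    dose_response_set = lapply(scenario$series, run_dose_response, seed = seed),
    kinetics = run_kinetics(scenario, seed = seed),
    kinetics_set = lapply(scenario$series, run_kinetics, seed = seed),
    blocking = run_blocking(scenario, seed = seed),
    stop("unknown scenario kind: ", scenario$kind, call. = FALSE))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    hash <- config_hash(list(kind = scenario$kind, seed = seed))
    write_pipeline_outputs(res, scenario, out_dir)
    jsonlite::write_json(
      list(kind = scenario$kind, seed = seed, config_hash = hash,
           package_version = as.character(utils::packageVersion("receptomics")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, scenario, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (scenario$kind == "calibration") {
    utils::write.csv(res, file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
  } else if (scenario$kind == "dose_response") {
    utils::write.csv(res$table, file.path(out_dir, "iratio.csv"),
                     row.names = FALSE)
    f <- res$fit
    jsonlite::write_json(list(ec50 = f$ec50, hill = f$hill, top = f$top,
                              bottom = f$bottom, converged = f$converged),
                         file.path(out_dir, "hill_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (scenario$kind == "blocking") {
    utils::write.csv(res$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(receptor = names(res$blocking),
                                blocking_pct = unname(res$blocking)),
                     file.path(out_dir, "blocking.csv"), row.names = FALSE)
  } else if (scenario$kind == "kinetics") {
    m <- res$high
    utils::write.csv(as.data.frame(unclass(m)),
                     file.path(out_dir, "kinetics_high.csv"),
                     row.names = FALSE)
  } else if (scenario$kind %in% c("dose_response_set", "kinetics_set")) {
    for (nm in names(res))
      write_pipeline_outputs(res[[nm]],
                             list(kind = sub("_set$", "", scenario$kind)),
                             file.path(out_dir, nm))
  }
  invisible(NULL)
}
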