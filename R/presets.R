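# Scenario presets encoding the study conditions: array composition,
# receptor pharmacology, injection schedules and fluidics. The kinetic
# constants (k_act, k_dec, linger_weight, linger_tau per sweetener, and the
# cyclamate Ki per bitter receptor) were calibrated once by grid search
# (tools/calibrate_presets.R) so that the noiseless end-to-end pipeline
# reproduces the target kinetic metrics and blocking percentages; they are
# frozen here and are not tuning knobs.

# Published EC50s (mM) of the sweet receptor used as generator ground truth.
SWEET_EC50 <- c(sucrose = 35, advantame = 0.0015, aspartame = 0.625,
                saccharine = 0.3)

# Calibrated activation/clearance kinetics of the sweet receptor per ligand.
sweet_kinetics <- function(ligand) {
  tab <- list(
    sucrose    = list(k_act = 0.129, k_dec = 0.669, linger_weight = 0.338,
                      linger_tau = 306),
    advantame  = list(k_act = 0.186, k_dec = 0.182, linger_weight = 0.700,
                      linger_tau = 137),
    aspartame  = list(k_act = 0.092, k_dec = 0.589, linger_weight = 0.482,
                      linger_tau = 212),
    saccharine = list(k_act = 0.097, k_dec = 0.347, linger_weight = 0.609,
                      linger_tau = 212))
  tab[[ligand]]
}

sweet_model <- function(ligand, amplitude = 1) {
  kin <- sweet_kinetics(ligand)
  receptor_model(amplitude = amplitude, k_act = kin$k_act, k_dec = kin$k_dec,
                 linger_weight = kin$linger_weight,
                 linger_tau = kin$linger_tau, desens_factor = 0.9,
                 ligands = stats::setNames(
                   list(list(ec50 = SWEET_EC50[[ligand]], hill = 1)), ligand))
}

# Bitter receptor models for the saccharine/cyclamate blocking experiment.
# EC50s (mM, saccharine) follow the known sensitivity ordering
# TAS2R43 >> TAS2R31 > TAS2R8; cyclamate Ki values (mM) are calibrated so the
# pipeline reproduces the target blocking percentages.
bitter_models <- function() {
  kin <- list(k_act = 0.35, k_dec = 0.15, linger_weight = 0.10,
              linger_tau = 40)
  mk <- function(ec50, amplitude, ki = NULL, desens = 1) {
    receptor_model(amplitude = amplitude, k_act = kin$k_act,
                   k_dec = kin$k_dec, linger_weight = kin$linger_weight,
                   linger_tau = kin$linger_tau, desens_factor = desens,
                   ligands = list(saccharine = list(ec50 = ec50, hill = 1)),
                   antagonists = if (is.null(ki)) list() else
                     list(cyclamate = list(ki = ki)))
  }
  list(
    TAS2R8  = mk(ec50 = 8,   amplitude = 0.50, ki = 23.9),
    TAS2R31 = mk(ec50 = 2,   amplitude = 0.50, ki = 4.54),
    TAS2R43 = mk(ec50 = 0.3, amplitude = 0.22, ki = 0.18, desens = 0.55)
    # TAS2R3 / TAS2R14 / TAS2R46 carry no saccharine or cyclamate ligand
    # entry: they only show the non-specific dip, like the mock.
  )
}

default_flow <- function() flow_config(cell_volume = 50, injection_volume = 300,
                                       flow_rate = 300, n_tanks = 3)

# Ascending dose series per sweetener (mM), ending at the maximum dose used
# in the response-profile experiments.
dose_series <- function(ligand) {
  switch(ligand,
         sucrose    = c(1, 3, 10, 30, 100),
         advantame  = c(0.15, 0.5, 1.5, 5, 15) * 1e-3,
         aspartame  = c(0.06, 0.2, 0.625, 2, 5),
         saccharine = c(0.03, 0.1, 0.3, 1.5, 5),
         stop("unknown ligand: ", ligand, call. = FALSE))
}

# Replication levels of the dose-response experiments (spots per array).
DOSE_RESPONSE_N <- c(advantame = 15, saccharine = 11, aspartame = 13,
                     sucrose = 11)

dose_response_scenario <- function(ligand, seed = 1) {
  n_sweet <- DOSE_RESPONSE_N[[ligand]]
  spots <- make_array(c(TAS1R2_R3 = n_sweet, TAS1R1_R3 = 6, MOCK = 6,
                        YC_CONTROL = 3),
                      seed = seed, pixel_range = c(20, 60))
  doses <- dose_series(ligand)
  sched <- injection_schedule(
    valve_times = 60 + 300 * (seq_along(doses) - 1),
    sample_ids = sprintf("%s_%g_mM", ligand, doses),
    compositions = lapply(doses, function(d)
      stats::setNames(d, ligand)))
  list(kind = "dose_response", ligand = ligand, doses = doses,
       spots = spots, models = list(TAS1R2_R3 = sweet_model(ligand)),
       flow_config = default_flow(), schedule = sched,
       noise = noise_config(), reference_receptor = "TAS1R1_R3")
}

kinetics_scenario <- function(ligand, seed = 1) {
  ec50 <- SWEET_EC50[[ligand]]
  high <- max(dose_series(ligand))
  spots <- make_array(c(TAS1R2_R3 = 11, TAS1R1_R3 = 11, MOCK = 6,
                        YC_CONTROL = 3),
                      seed = seed, pixel_range = c(20, 60))
  sched <- injection_schedule(
    valve_times = c(60, 360, 660),
    sample_ids = c("fluorescein",
                   sprintf("%s_ec50", ligand), sprintf("%s_high", ligand)),
    compositions = list(c(fluorescein = 0.1),
                        stats::setNames(ec50, ligand),
                        stats::setNames(high, ligand)))
  list(kind = "kinetics", ligand = ligand, ec50_dose = ec50, high_dose = high,
       spots = spots, models = list(TAS1R2_R3 = sweet_model(ligand)),
       flow_config = default_flow(), schedule = sched,
       noise = noise_config(), reference_receptor = "TAS1R1_R3",
       reference_injection = "inj01")
}

#' Preset scenarios of the study's experiments
#'
#' Returns a self-contained scenario (spot layout, receptor models, fluidics
#' and injection schedule) for one of the encoded experiments:
#' \describe{
#'   \item{`table1_calibration`}{Dye-only flow calibration over the 16-row
#'     grid of cell volume x injection volume x flow rate conditions; no
#'     receptor spots.}
#'   \item{`fig2_sucrose_series`}{Ascending sucrose dose series (1-100 mM)
#'     on a sweet/umami/mock/sensor-control array, 11 sweet replicates.}
#'   \item{`fig2_all_sweeteners`}{Four dose-response series (advantame,
#'     saccharine, aspartame, sucrose) on separate arrays at the published
#'     replication levels.}
#'   \item{`table2_kinetics`}{Per-sweetener kinetics runs: a fluorescein
#'     reference injection followed by the ~EC50 and the maximum dose.}
#'   \item{`fig4_blocking`}{Sweet + six bitter receptor array challenged
#'     with blank, 10 mM saccharine, 10 mM saccharine + 20 mM cyclamate,
#'     10 mM saccharine again, and 20 mM cyclamate.}
#' }
#'
#' @param name Scenario name (see above).
#' @param seed Integer seed used for the array layout.
#' @return A scenario list; composite presets (`fig2_all_sweeteners`,
#'   `table2_kinetics`) contain a named `series` list of sub-scenarios.
#' @export
preset_scenario <- function(name, seed = 1) {
  switch(
    name,
    table1_calibration = list(
      kind = "calibration",
      cell_volumes = c(50, 100), injection_volumes = c(300, 1000),
      flow_rates = c(100, 300, 600, 900), n_tanks = 3,
      spots = make_array(c(YC_CONTROL = 1), seed = seed)[0, ],
      models = list(), flow_config = default_flow(),
      schedule = injection_schedule(60, "fluorescein",
                                    list(c(fluorescein = 0.1))),
      noise = noise_config()),
    fig2_sucrose_series = dose_response_scenario("sucrose", seed = seed),
    fig2_all_sweeteners = list(
      kind = "dose_response_set",
      series = stats::setNames(
        lapply(names(DOSE_RESPONSE_N), dose_response_scenario, seed = seed),
        names(DOSE_RESPONSE_N))),
    table2_kinetics = list(
      kind = "kinetics_set",
      series = stats::setNames(
        lapply(names(SWEET_EC50), kinetics_scenario, seed = seed),
        names(SWEET_EC50))),
    fig4_blocking = {
      spots <- make_array(c(TAS1R2_R3 = 11, TAS2R3 = 14, TAS2R8 = 14,
                            TAS2R14 = 14, TAS2R31 = 14, TAS2R43 = 14,
                            TAS2R46 = 14, MOCK = 8, YC_CONTROL = 4),
                          seed = seed, pixel_range = c(10, 60))
      sched <- injection_schedule(
        valve_times = 60 + 300 * (0:8),
        sample_ids = c("blank", "blank", "blank",
                       "saccharine_10mM", "saccharine_10mM_cyclamate_20mM",
                       "saccharine_10mM", "cyclamate_20mM",
                       "blank", "blank"),
        compositions = list(
          numeric(0), numeric(0), numeric(0),
          c(saccharine = 10),
          c(saccharine = 10, cyclamate = 20),
          c(saccharine = 10),
          c(cyclamate = 20),
          numeric(0), numeric(0)))
      models <- c(list(TAS1R2_R3 = {
        m <- sweet_model("saccharine")
        m$ligands$cyclamate <- list(ec50 = 3, hill = 1)
        m
      }), bitter_models())
      list(kind = "blocking", spots = spots, models = models,
           flow_config = default_flow(), schedule = sched,
           noise = noise_config(),
           control_injection = "inj03",
           treatment_injections = c(pure = "inj04", mix = "inj05",
                                    repeat_pure = "inj06", antagonist = "inj07"))
    },
    stop("unknown preset: ", name, call. = FALSE))
}
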