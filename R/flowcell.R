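#' Flow-cell configuration
#'
#' Describes the loop-injection fluidics as a linear residence-time system:
#' the sample loop delivers an undiluted plug (a boxcar in time) into a
#' constant carrier flow, and the flow cell disperses it through a cascade of
#' `n_tanks` well-mixed compartments (tanks-in-series), optionally mixed with
#' a slow exponential "dead-zone" tail that delays wash-out.
#'
#' @param cell_volume Flow-cell volume in uL.
#' @param injection_volume Sample-loop volume in uL.
#' @param flow_rate Carrier flow in uL/min.
#' @param n_tanks Number of dispersion stages (>= 1). More stages give
#'   sharper, more plug-like flanks; fewer give exponential tails.
#' @param tailing_fraction Weight in `[0, 1)` of the slow dead-zone component
#'   of the dispersion kernel. 0 disables tailing.
#' @param tailing_tau Time constant (s) of the dead-zone component.
#' @param effective_loop_volume Optional override (uL) for the volume the
#'   loop actually delivers, when the nominal loop volume is not trusted.
#' @return An object of class `flow_config`.
#' @examples
#' cfg <- flow_config(cell_volume = 50, injection_volume = 300, flow_rate = 300)
#' theoretical_exposure(cfg) # 60 s
#' @export
flow_config <- function(cell_volume = 50, injection_volume = 300,
                        flow_rate = 300, n_tanks = 3,
                        tailing_fraction = 0, tailing_tau = 30,
                        effective_loop_volume = NULL) {
  if (!is.numeric(cell_volume) || cell_volume <= 0)
    stop("invalid flow config: cell_volume must be > 0", call. = FALSE)
  if (!is.numeric(injection_volume) || injection_volume <= 0)
    stop("invalid flow config: injection_volume must be > 0", call. = FALSE)
  if (!is.numeric(flow_rate) || flow_rate <= 0)
    stop("invalid flow config: flow_rate must be > 0", call. = FALSE)
  n_tanks <- as.integer(n_tanks)
  if (is.na(n_tanks) || n_tanks < 1)
    stop("invalid flow config: n_tanks must be a positive integer", call. = FALSE)
  if (tailing_fraction < 0 || tailing_fraction >= 1)
    stop("invalid flow config: tailing_fraction must be in [0, 1)", call. = FALSE)
  if (tailing_fraction > 0 && tailing_tau <= 0)
    stop("invalid flow config: tailing_tau must be > 0", call. = FALSE)
  if (!is.null(effective_loop_volume) && effective_loop_volume <= 0)
    stop("invalid flow config: effective_loop_volume must be > 0", call. = FALSE)
  structure(
    list(cell_volume = cell_volume,
         injection_volume = injection_volume,
         flow_rate = flow_rate,
         n_tanks = n_tanks,
         tailing_fraction = tailing_fraction,
         tailing_tau = tailing_tau,
         effective_loop_volume = effective_loop_volume),
    class = "flow_config")
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf("<flow_config> cell %g uL, loop %g uL, flow %g uL/min\n",
              x$cell_volume, x$injection_volume, x$flow_rate))
  cat(sprintf("  %d tank(s), mean residence %.1f s, tailing %.2f (tau %.0f s)\n",
              x$n_tanks, 60 * x$cell_volume / x$flow_rate,
              x$tailing_fraction, x$tailing_tau))
  cat(sprintf("  theoretical exposure %.1f s\n", theoretical_exposure(x)))
  invisible(x)
}

#' Theoretical exposure duration of an injected plug
#'
#' Duration (s) for which undiluted sample would pass the array if no
#' dispersion occurred: loop volume divided by flow rate.
#'
#' @param config A [flow_config()].
#' @return Exposure time in seconds.
#' @export
theoretical_exposure <- function(config) {
  stopifnot(inherits(config, "flow_config"))
  vol <- config$effective_loop_volume %||% config$injection_volume
  60 * vol / config$flow_rate
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalized dispersion kernel on a dt grid: Erlang (tanks-in-series) density
# with total mean residence time cell_volume/flow_rate, mixed with an optional
# exponential dead-zone tail. Discretized and renormalized to unit sum*dt.
dispersion_kernel <- function(config, dt) {
  tau_cell <- 60 * config$cell_volume / config$flow_rate
  rate <- config$n_tanks / tau_cell
  t_max <- max(8 * tau_cell,
               if (config$tailing_fraction > 0) 8 * config$tailing_tau else 0,
               10 * dt)
  tk <- seq(0, t_max, by = dt)
  k <- (1 - config$tailing_fraction) * stats::dgamma(tk, shape = config$n_tanks,
                                                     rate = rate)
  if (config$tailing_fraction > 0)
    k <- k + config$tailing_fraction * stats::dexp(tk, rate = 1 / config$tailing_tau)
  k / (sum(k) * dt)
}

#' Simulate the relative-concentration exposure profile at the array
#'
#' Each injection contributes a boxcar of height 1 (undiluted sample) and
#' width [theoretical_exposure()], convolved with the normalized dispersion
#' kernel of the flow cell. Contributions of successive injections superpose
#' additively; the result is clipped at 1.
#'
#' @param config A [flow_config()].
#' @param valve_times Numeric vector of injection (valve) times in s. May also
#'   be an `injection_schedule`, in which case its valve times are used.
#' @param dt Time step of the simulation grid (s).
#' @param duration Total simulated duration (s). Defaults to the last valve
#'   time plus the exposure duration plus five mean residence times
#'   (plus five tailing time constants when tailing is enabled).
#' @return An `exposure_profile`: list with `times` and `concentration`
#'   (relative concentration in `[0, 1]`).
#' @examples
#' prof <- simulate_exposure(flow_config(), valve_times = 0, dt = 0.1)
#' max(prof$concentration)
#' @export
simulate_exposure <- function(config, valve_times = 0, dt = 0.5,
                              duration = NULL) {
  stopifnot(inherits(config, "flow_config"))
  if (inherits(valve_times, "injection_schedule"))
    valve_times <- vapply(valve_times, function(x) x$valve_time, numeric(1))
  if (length(valve_times) < 1) stop("at least one injection required", call. = FALSE)
  if (is.unsorted(valve_times, strictly = TRUE) && length(valve_times) > 1)
    stop("valve_times must be strictly increasing", call. = FALSE)
  t_exp <- theoretical_exposure(config)
  tau_cell <- 60 * config$cell_volume / config$flow_rate
  washout <- 5 * tau_cell + t_exp +
    (if (config$tailing_fraction > 0) 5 * config$tailing_tau else 0)
  need <- max(valve_times) + washout
  if (is.null(duration)) duration <- need
  if (duration < need)
    warning(sprintf("duration %.0f s truncates the washout of the last injection (need %.0f s)",
                    duration, need))
  times <- seq(0, duration, by = dt)
  input <- rep(0, length(times))
  for (v in valve_times) {
    # boxcar of height 1 from valve time to valve time + exposure
    input <- input + as.numeric(times >= v & times < v + t_exp)
  }
  kern <- dispersion_kernel(config, dt)
  conc <- stats::convolve(input, rev(kern), type = "open")[seq_along(times)] * dt
  conc <- pmin(pmax(conc, 0), 1)
  structure(list(times = times, concentration = conc), class = "exposure_profile")
}

#' Peak-shape metrics of a single-injection exposure profile
#'
#' Computes the calibration metrics of a dye (fluorescein) exposure peak:
#' full width at half maximum from linearly interpolated half-maximum
#' crossings (first upward, last downward), and the maximum rise and fall
#' rates of the curve expressed in percent of the peak maximum per second
#' (central finite differences, unsmoothed).
#'
#' @param profile An `exposure_profile` (or any list with `times` and
#'   `concentration`) containing exactly one peak.
#' @param config The [flow_config()] used to generate the profile, for the
#'   theoretical exposure column; optional.
#' @return A list with `theoretical_exposure` (s, `NA` when `config` is
#'   missing), `fwhm` (s), `max_rise` (%/s) and `max_fall` (%/s, negative).
#' @export
exposure_metrics <- function(profile, config = NULL) {
  y <- profile$concentration
  tt <- profile$times
  pk <- max(y)
  if (!is.finite(pk) || pk <= 0 || pk - min(y) <= 0)
    stop("no peak: profile is flat", call. = FALSE)
  f <- peak_fwhm_raw(tt, y)
  # derivative in % of peak max per second, central differences
  d <- central_diff(y / pk * 100, tt)
  list(theoretical_exposure = if (is.null(config)) NA_real_ else theoretical_exposure(config),
       fwhm = f,
       max_rise = max(d),
       max_fall = min(d))
}

# fwhm of (t, y) relative to max(y) (or a supplied peak-level estimate), by
# linear interpolation between the samples bracketing the first upward and
# last downward half-max crossing.
peak_fwhm_raw <- function(tt, y, level = 0.5, peak_level = NULL) {
  half <- level * (peak_level %||% max(y))
  above <- y >= half
  if (!any(above)) stop("no peak: curve never reaches the half-maximum", call. = FALSE)
  i1 <- which(above)[1]
  i2 <- which(above)[length(which(above))]
  if (i1 == 1 && i2 == length(y))
    stop("no peak: curve never falls below the half-maximum", call. = FALSE)
  t_up <- if (i1 == 1) tt[1] else
    tt[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (tt[i1] - tt[i1 - 1])
  t_dn <- if (i2 == length(y)) tt[i2] else
    tt[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * (tt[i2 + 1] - tt[i2])
  t_dn - t_up
}

central_diff <- function(y, tt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (tt[2] - tt[1])
  d[n] <- (y[n] - y[n - 1]) / (tt[n] - tt[n - 1])
  d
}

#' Exposure calibration table over a grid of fluidic conditions
#'
#' Simulates a single dye injection for every combination of the supplied
#' cell volumes, injection volumes and flow rates, and tabulates the
#' theoretical exposure alongside the measured peak metrics — the layout of
#' a flow-calibration table.
#'
#' @param cell_volumes,injection_volumes,flow_rates Numeric vectors (uL, uL,
#'   uL/min) defining the condition grid.
#' @param n_tanks,tailing_fraction,tailing_tau Dispersion parameters shared
#'   by all conditions; see [flow_config()].
#' @param dt Simulation time step (s); 0.1 s for calibration use.
#' @param file Optional path; when given the table is also written as CSV.
#' @return A data.frame with columns `cell_volume`, `injection_volume`,
#'   `flow_rate`, `theoretical_exposure_s`, `fwhm_s`, `max_rise_pct_s`,
#'   `max_fall_pct_s`.
#' @export
calibration_table <- function(cell_volumes = c(50, 100),
                              injection_volumes = c(300, 1000),
                              flow_rates = c(100, 300, 600, 900),
                              n_tanks = 3, tailing_fraction = 0,
                              tailing_tau = 30, dt = 0.1, file = NULL) {
  grid <- expand.grid(flow_rate = flow_rates,
                      injection_volume = injection_volumes,
                      cell_volume = cell_volumes)
  grid <- grid[, c("cell_volume", "injection_volume", "flow_rate")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- flow_config(cell_volume = grid$cell_volume[i],
                       injection_volume = grid$injection_volume[i],
                       flow_rate = grid$flow_rate[i],
                       n_tanks = n_tanks,
                       tailing_fraction = tailing_fraction,
                       tailing_tau = tailing_tau)
    prof <- simulate_exposure(cfg, valve_times = 0, dt = dt)
    m <- exposure_metrics(prof, cfg)
    data.frame(cell_volume = cfg$cell_volume,
               injection_volume = cfg$injection_volume,
               flow_rate = cfg$flow_rate,
               theoretical_exposure_s = m$theoretical_exposure,
               fwhm_s = m$fwhm,
               max_rise_pct_s = m$max_rise,
               max_fall_pct_s = m$max_fall)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
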