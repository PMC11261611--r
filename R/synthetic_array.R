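#' Receptor spot layout for a synthetic array
#'
#' Generates the spot table of a reverse-transfected receptor array:
#' replicate spots per receptor type, a fluorescent pixel count per spot
#' (spots below the QC threshold of 15 pixels are meant to occur when the
#' lower bound allows it), and a small per-spot arrival delay of the sample
#' front that depends on the position on the array.
#'
#' @param layout Named integer vector: replicate spot count per receptor
#'   type. Names are receptor labels such as `"TAS1R2_R3"`, `"TAS2R43"`,
#'   `"MOCK"`, `"YC_CONTROL"`.
#' @param seed Integer seed; the layout is deterministic given `(layout, seed)`.
#' @param pixel_range Integer range from which pixel counts are drawn
#'   uniformly.
#' @param max_delay Maximum positional arrival delay in s, spread linearly
#'   across the spot index (the sample front sweeps the array in a few
#'   seconds).
#' @return A data.frame with columns `spot_id`, `receptor`, `pixel_count`,
#'   `position_delay`.
#' @examples
#' make_array(c(TAS1R2_R3 = 11, MOCK = 6), seed = 1)
#' @export
make_array <- function(layout, seed = 1, pixel_range = c(10, 60),
                       max_delay = 4) {
  if (is.null(names(layout)) || any(!nzchar(names(layout))))
    stop("layout must be a named vector of replicate counts", call. = FALSE)
  if (any(layout < 1))
    stop(sprintf("zero replicates requested for receptor(s): %s",
                 paste(names(layout)[layout < 1], collapse = ", ")),
         call. = FALSE)
  n <- sum(layout)
  receptor <- rep(names(layout), times = layout)
  set.seed(seed)
  # interleave receptor types across the array so positional delay is not
  # confounded with receptor identity
  ord <- sample.int(n)
  receptor <- receptor[ord]
  pixel_count <- sample(seq(pixel_range[1], pixel_range[2]), n, replace = TRUE)
  position_delay <- if (n > 1) (seq_len(n) - 1) / (n - 1) * max_delay else 0
  data.frame(spot_id = sprintf("spot%03d", seq_len(n)),
             receptor = receptor,
             pixel_count = pixel_count,
             position_delay = position_delay,
             stringsAsFactors = FALSE)
}

#' Receptor activation model
#'
#' Pharmacological and kinetic parameters of one receptor type in the
#' generator. Ligand occupancy follows a Hill curve per agonist; competitive
#' antagonists shift the effective EC50 by `(1 + [I]/Ki)`; the calcium
#' signal tracks the occupancy through two parallel asymmetric first-order
#' paths that share the activation (rise) rate `k_act` but clear at
#' different rates — a fast path (`k_dec`) and a slow "lingering" path
#' (`1/linger_tau`, weight `linger_weight`). Decoupling rise from decay is
#' what lets a response peak with the exposure yet linger after it.
#'
#' @param amplitude Maximal fractional calcium signal at full occupancy.
#' @param k_act Activation (rise) rate, 1/s.
#' @param k_dec Fast clearance rate, 1/s.
#' @param linger_weight Weight in `[0, 1)` of the slow clearance path.
#' @param linger_tau Time constant (s) of the slow path.
#' @param desens_factor Multiplicative amplitude retention per prior
#'   near-saturating exposure, in `(0, 1]` (1 = no desensitization).
#' @param ligands Named list of agonists, each a list with `ec50` (mM) and
#'   `hill` (slope).
#' @param antagonists Named list of competitive antagonists, each a list with
#'   `ki` (mM).
#' @return An object of class `receptor_model`.
#' @export
receptor_model <- function(amplitude = 1, k_act = 0.3, k_dec = 0.1,
                           linger_weight = 0, linger_tau = 30,
                           desens_factor = 1, ligands = list(),
                           antagonists = list()) {
  stopifnot(amplitude >= 0, k_act > 0, k_dec > 0,
            linger_weight >= 0, linger_weight < 1, linger_tau > 0,
            desens_factor > 0, desens_factor <= 1)
  for (lg in ligands) stopifnot(lg$ec50 > 0, lg$hill > 0)
  for (an in antagonists) stopifnot(an$ki > 0)
  structure(list(amplitude = amplitude, k_act = k_act, k_dec = k_dec,
                 linger_weight = linger_weight, linger_tau = linger_tau,
                 desens_factor = desens_factor, ligands = ligands,
                 antagonists = antagonists),
            class = "receptor_model")
}

#' Injection schedule
#'
#' Ordered loop injections: valve time, sample label, and the sample
#' composition as a named vector of ligand concentrations in mM.
#'
#' @param valve_times Strictly increasing valve times in s.
#' @param sample_ids Character vector of sample labels.
#' @param compositions List of named numeric vectors (ligand -> mM); an empty
#'   vector is a buffer blank.
#' @param min_spacing Minimum allowed spacing between injections in s
#'   (wash-out); default 240 s.
#' @return An object of class `injection_schedule` (list of injections, each
#'   with `injection_id`, `valve_time`, `sample_id`, `composition`).
#' @export
injection_schedule <- function(valve_times, sample_ids, compositions,
                               min_spacing = 240) {
  n <- length(valve_times)
  stopifnot(length(sample_ids) == n, length(compositions) == n)
  if (n > 1 && any(diff(valve_times) <= 0))
    stop("valve_times must be strictly increasing", call. = FALSE)
  if (n > 1 && any(diff(valve_times) < min_spacing))
    stop(sprintf("injection spacing below wash-out minimum of %g s", min_spacing),
         call. = FALSE)
  for (cmp in compositions) {
    if (length(cmp) > 0 && (is.null(names(cmp)) || any(cmp < 0)))
      stop("compositions must be named, non-negative concentrations (mM)",
           call. = FALSE)
  }
  inj <- lapply(seq_len(n), function(i) {
    list(injection_id = sprintf("inj%02d", i),
         valve_time = valve_times[i],
         sample_id = sample_ids[i],
         composition = compositions[[i]])
  })
  structure(inj, class = "injection_schedule")
}

#' Noise and artifact configuration of the trace generator
#'
#' @param channel_cv Multiplicative Gaussian noise CV applied independently
#'   to each channel sample (default 1%).
#' @param dip_gamma Amplitude of the non-specific osmolarity "dip" artifact,
#'   in calcium-signal units per 100 mM of total solute.
#' @param amp_sdlog Log-sd of the per-spot lognormal amplitude multiplier
#'   (biological spot-to-spot variability; this is the spot random effect the
#'   mixed model absorbs).
#' @param baseline_cfp,baseline_yfp Channel baselines in arbitrary units.
#' @param alpha,beta Fractional YFP gain and CFP loss at calcium signal 1.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(channel_cv = 0.01, dip_gamma = 0.05,
                         amp_sdlog = 0.25, baseline_cfp = 1000,
                         baseline_yfp = 1000, alpha = 0.15, beta = 0.15) {
  stopifnot(channel_cv >= 0, dip_gamma >= 0, amp_sdlog >= 0,
            baseline_cfp > 0, baseline_yfp > 0, alpha > 0, beta > 0, beta < 1)
  structure(list(channel_cv = channel_cv, dip_gamma = dip_gamma,
                 amp_sdlog = amp_sdlog, baseline_cfp = baseline_cfp,
                 baseline_yfp = baseline_yfp, alpha = alpha, beta = beta),
            class = "noise_config")
}

# Hill occupancy fraction with a (possibly time-varying) competitive shift.
hill_occupancy <- function(conc, ec50, hill, shift = 1) {
  ch <- conc^hill
  ch / (ch + (ec50 * shift)^hill)
}

# Dose giving 95% of maximal occupancy (used for the desensitization
# threshold), with antagonists at their full injected dose.
saturating_dose <- function(ec50, hill, shift = 1) {
  ec50 * shift * 19^(1 / hill)
}

# Canonical calcium curve of one receptor model across a whole schedule, on
# the simulation grid, for a spot with unit amplitude multiplier and zero
# positional delay. Returns amplitude * filtered occupancy drive.
receptor_response_curve <- function(model, schedule, pulse, times, dt) {
  drive <- numeric(length(times))
  n_strong <- 0L
  for (inj in schedule) {
    comp <- inj$composition
    if (length(comp) == 0) next
    p <- shift_curve(pulse, times, inj$valve_time)
    ant <- intersect(names(comp), names(model$antagonists))
    ago <- intersect(names(comp), names(model$ligands))
    desens <- model$desens_factor^n_strong
    # full-dose competitive shift, for the desensitization threshold
    shift_full <- 1 + sum(vapply(ant, function(a)
      comp[[a]] / model$antagonists[[a]]$ki, numeric(1)))
    strong <- FALSE
    if (length(ago) > 0) {
      shift_t <- 1 + Reduce(`+`, lapply(ant, function(a)
        comp[[a]] * p / model$antagonists[[a]]$ki), accumulate = FALSE,
        init = 0)
      frac <- 0
      for (a in ago) {
        lg <- model$ligands[[a]]
        frac <- frac + hill_occupancy(comp[[a]] * p, lg$ec50, lg$hill, shift_t)
        if (comp[[a]] >= 0.8 * saturating_dose(lg$ec50, lg$hill, shift_full))
          strong <- TRUE
      }
      drive <- drive + desens * pmin(frac, 1)
    }
    if (strong) n_strong <- n_strong + 1L
  }
  # calcium signal: occupancy tracked by two parallel asymmetric first-order
  # paths sharing the activation rate but with distinct clearance rates — a
  # fast path (k_dec) and a slow "lingering" path (1/linger_tau). Release is
  # fast relative to clearance, so the peak can coincide with the exposure
  # while the decay lingers.
  fast <- asym_filter(drive, model$k_act, model$k_dec, dt)
  s <- if (model$linger_weight > 0) {
    slow <- asym_filter(drive, model$k_act, 1 / model$linger_tau, dt)
    (1 - model$linger_weight) * fast + model$linger_weight * slow
  } else fast
  model$amplitude * s
}

# Shift a curve sampled on `times` (starting at 0) so it starts at `delay`.
shift_curve <- function(y, times, delay) {
  if (delay == 0) return(y)
  stats::approx(times + delay, y, xout = times, yleft = 0,
                yright = y[length(y)])$y
}

#' Simulate two-channel FRET traces for a receptor array
#'
#' For each spot, the ligand exposure is the flow-cell concentration profile
#' shifted by the spot's positional delay; receptor occupancy follows the
#' spot's [receptor_model()] (Hill activation, competitive antagonist shift,
#' desensitization on repeated near-saturating doses); the calcium signal
#' tracks the occupancy through the model's asymmetric rise/clearance
#' filter; a
#' non-specific osmolarity dip is subtracted for all non-sensor-control
#' spots; and the donor (CFP) and acceptor (YFP) channels are rendered on
#' interleaved timestamps with multiplicative Gaussian noise. Sensor-control
#' (`YC_CONTROL`) spots carry no calcium signal and no dip.
#'
#' @param spots Spot table from [make_array()].
#' @param models Named list of [receptor_model()]s; receptors without a model
#'   (e.g. `MOCK`) carry no specific signal.
#' @param flow_config A [flow_config()].
#' @param schedule An [injection_schedule()].
#' @param noise A [noise_config()].
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @param dt_sim Internal simulation grid step in s.
#' @param sample_dt Channel sampling interval in s; YFP samples lag CFP by
#'   `sample_dt / 2` (interleaved acquisition).
#' @param duration Total duration in s (default: schedule plus washout).
#' @return A `trace_set`: list with `traces` (long data.frame: `time_s`,
#'   `spot_id`, `channel`, `intensity`), plus the `spots`, `schedule`,
#'   `flow_config` and `noise` used.
#' @export
simulate_traces <- function(spots, models, flow_config, schedule,
                            noise = noise_config(), seed = 1,
                            dt_sim = 0.2, sample_dt = 2, duration = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"))
  for (inj in schedule) if (any(inj$composition < 0))
    stop("negative concentrations in schedule", call. = FALSE)
  valve_times <- vapply(schedule, function(x) x$valve_time, numeric(1))
  t_exp <- theoretical_exposure(flow_config)
  tau_cell <- 60 * flow_config$cell_volume / flow_config$flow_rate
  if (is.null(duration))
    duration <- max(valve_times) + t_exp + 5 * tau_cell + 180
  times <- seq(0, duration, by = dt_sim)

  # single-injection relative-concentration pulse starting at t = 0
  pulse_prof <- simulate_exposure(flow_config, valve_times = 0, dt = dt_sim,
                                  duration = duration)
  pulse <- pulse_prof$concentration

  # canonical calcium curve per receptor type present on the array
  receptors <- unique(spots$receptor)
  canon <- list()
  for (r in receptors) {
    canon[[r]] <- if (!is.null(models[[r]]))
      receptor_response_curve(models[[r]], schedule, pulse, times, dt_sim)
    else numeric(length(times))
  }

  # canonical osmolarity dip (calcium-signal units), shared by non-YC spots
  dip <- numeric(length(times))
  if (noise$dip_gamma > 0) {
    for (inj in schedule) {
      osmo <- sum(inj$composition) / 100 # total solute in units of 100 mM
      if (osmo > 0)
        dip <- dip + noise$dip_gamma * osmo *
          shift_curve(pulse, times, inj$valve_time)
    }
  }

  t_cfp <- seq(0, duration, by = sample_dt)
  t_yfp <- t_cfp + sample_dt / 2
  t_yfp <- t_yfp[t_yfp <= duration]
  t_cfp <- t_cfp[seq_along(t_yfp)] # keep channels the same length

  set.seed(seed)
  amp_mult <- exp(stats::rnorm(nrow(spots), 0, noise$amp_sdlog))
  out <- vector("list", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    r <- spots$receptor[i]
    delay <- spots$position_delay[i]
    if (r == "YC_CONTROL") {
      s_tot_c <- numeric(length(t_cfp))
      s_tot_y <- numeric(length(t_yfp))
    } else {
      s <- amp_mult[i] * canon[[r]] - dip
      s_shift <- shift_curve(s, times, delay)
      s_tot_c <- stats::approx(times, s_shift, xout = t_cfp, rule = 2)$y
      s_tot_y <- stats::approx(times, s_shift, xout = t_yfp, rule = 2)$y
    }
    cv <- noise$channel_cv
    eps_c <- if (cv > 0) stats::rnorm(length(t_cfp), 0, cv) else 0
    eps_y <- if (cv > 0) stats::rnorm(length(t_yfp), 0, cv) else 0
    cfp <- noise$baseline_cfp * (1 - noise$beta * s_tot_c) * (1 + eps_c)
    yfp <- noise$baseline_yfp * (1 + noise$alpha * s_tot_y) * (1 + eps_y)
    out[[i]] <- data.frame(
      time_s = c(t_cfp, t_yfp),
      spot_id = spots$spot_id[i],
      channel = rep(c("CFP", "YFP"), c(length(t_cfp), length(t_yfp))),
      intensity = c(cfp, yfp),
      stringsAsFactors = FALSE)
  }
  traces <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(time_s = numeric(), spot_id = character(),
               channel = character(), intensity = numeric())
  structure(list(traces = traces, spots = spots, schedule = schedule,
                 flow_config = flow_config, noise = noise),
            class = "trace_set")
}
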