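# Analytic percent-curves used as oracles for the kinetic metrics.

pct_curve <- function(times, pct) {
  structure(list(times = times, pct = pct), class = "pct_curve")
}

boxcar_curve <- function(width, t0 = 50, dt = 0.1, t_end = 400) {
  tt <- seq(0, t_end, by = dt)
  pct_curve(tt, ifelse(tt >= t0 & tt < t0 + width, 100, 0))
}

gaussian_curve <- function(sigma, mu = 150, dt = 0.1, t_end = 400) {
  tt <- seq(0, t_end, by = dt)
  pct_curve(tt, 100 * exp(-(tt - mu)^2 / (2 * sigma^2)))
}

triangle_curve <- function(half_base, apex = 150, dt = 0.1, t_end = 400) {
  tt <- seq(0, t_end, by = dt)
  pct_curve(tt, pmax(0, 100 * (1 - abs(tt - apex) / half_base)))
}

# Minimal ratio_trace constructor for direct peak-statistic tests.
make_ratio_trace <- function(times, ratio, spot_id = "s1", receptor = "TAS1R2_R3") {
  structure(list(spot_id = spot_id, receptor = receptor,
                 times = times, ratio = ratio),
            class = "ratio_trace")
}

# Two-injection schedule helper.
simple_schedule <- function(valve_times, ligand = "sucrose", doses = NULL) {
  if (is.null(doses)) doses <- rep(100, length(valve_times))
  injection_schedule(valve_times,
                     sample_ids = sprintf("%s_%g", ligand, doses),
                     compositions = lapply(doses, function(d)
                       stats::setNames(d, ligand)))
}
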