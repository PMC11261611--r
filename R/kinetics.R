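#' Normalize a response curve to percent and synchronize to the valve event
#'
#' Shifts time so the valve event sits at `sync_time` (curves from different
#' injections become superimposable) and maps values so the pre-injection
#' baseline is 0% and the peak maximum is 100%.
#'
#' @param times,values The curve (uniform grid).
#' @param valve_time Valve event time of this curve's injection (s).
#' @param sync_time Where the valve event is placed after the shift (s);
#'   default 50 s.
#' @param baseline_window Length (s) of the pre-valve window averaged for
#'   the 0% level.
#' @return A `pct_curve`: list with `times` (shifted) and `pct` in percent.
#' @export
normalize_and_sync <- function(times, values, valve_time,
                               sync_time = 50, baseline_window = 10) {
  stopifnot(length(times) == length(values))
  shift <- sync_time - valve_time
  tt <- times + shift
  base_idx <- times >= valve_time - baseline_window & times < valve_time
  base <- if (any(base_idx)) mean(values[base_idx]) else values[1]
  pk <- max(values)
  if (pk - base <= 0)
    stop("degenerate curve: zero dynamic range", call. = FALSE)
  structure(list(times = tt, pct = (values - base) / (pk - base) * 100),
            class = "pct_curve")
}

#' Full width at half maximum of a normalized response peak
#'
#' Time between the first upward and the last downward crossing of the 50%
#' level, with linear interpolation between the bracketing samples.
#'
#' @param curve A `pct_curve` from [normalize_and_sync()], or any list with
#'   `times` and `pct`.
#' @return fwhm in seconds.
#' @export
peak_fwhm <- function(curve) {
  peak_fwhm_raw(curve$times, curve$pct)
}

# First time a curve attains its maximum. A filtered signal approaches a
# plateau asymptotically and noise inflates the observed maximum of a flat
# plateau, so an exact argmax would report an arbitrary point late in the
# plateau. Attainment is therefore the first sample reaching
# (1 - attain_tol) of the plateau level, with the plateau level estimated
# from a heavily smoothed copy of the curve so that channel noise neither
# raises the threshold nor delays the crossing.
time_at_max <- function(curve, attain_tol = 0.05) {
  level <- max(moving_average(curve$pct, 25))
  thr <- (1 - attain_tol) * level
  curve$times[which(curve$pct >= thr)[1]]
}

# First interpolated upward crossing of `level` % of the maximum.
time_at_level <- function(curve, level) {
  y <- curve$pct
  thr <- level / 100 * max(y)
  i <- which(y >= thr)[1]
  if (is.na(i)) stop("curve never reaches ", level, "% of maximum", call. = FALSE)
  if (i == 1) return(curve$times[1])
  t0 <- curve$times[i - 1]
  t1 <- curve$times[i]
  t0 + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (t1 - t0)
}

#' Response onset relative to the dye reference
#'
#' Delay of the response peak maximum relative to the dye (fluorescein)
#' reference peak maximum from the same run, both synchronized to their
#' valve events. Mode `"peak_max"` uses the first sample attaining the
#' maximum (within a 5% attainment band around a noise-robust plateau
#' estimate, which resolves plateau ties);
#' mode `"p90"` uses the first upward crossing of 90% of the maximum.
#'
#' @param response,reference `pct_curve`s synchronized to the same valve
#'   position ([normalize_and_sync()]).
#' @param mode `"peak_max"` (default) or `"p90"`.
#' @param warn_plateau Emit a warning when the response maximum plateau
#'   (samples within the attainment band) is wider than 25% of the fwhm —
#'   long exposures give broad maxima and an ill-defined onset.
#' @return Onset in s, with attribute `"uncertainty"` = one grid step.
#' @export
response_onset <- function(response, reference, mode = c("peak_max", "p90"),
                           warn_plateau = TRUE) {
  mode <- match.arg(mode)
  if (mode == "p90") {
    t_resp <- time_at_level(response, 90)
    t_ref <- time_at_level(reference, 90)
  } else {
    t_resp <- time_at_max(response)
    t_ref <- time_at_max(reference)
    if (warn_plateau) {
      plat <- sum(response$pct >= 99) * median(diff(response$times))
      if (plat > 0.25 * peak_fwhm(response))
        warning("broad maximum: plateau wider than 25% of fwhm; shorten the sample exposure")
    }
  }
  out <- t_resp - t_ref
  attr(out, "uncertainty") <- stats::median(diff(response$times))
  out
}

#' Lingering (delta-fwhm) of a response relative to the dye reference
#'
#' `peak_fwhm(response) - peak_fwhm(reference)`: the excess persistence of
#' the receptor signal over the physical exposure, the in vitro analog of
#' sensory lingering. Non-positive values mean no lingering.
#'
#' @inheritParams response_onset
#' @return Delta-fwhm in s (may be <= 0; [format_lingering()] renders such
#'   values as `"none"`).
#' @export
lingering <- function(response, reference) {
  peak_fwhm(response) - peak_fwhm(reference)
}

#' @rdname lingering
#' @param delta A delta-fwhm value.
#' @param digits Rounding for the printed value.
#' @export
format_lingering <- function(delta, digits = 0) {
  if (delta <= 0) "none" else as.character(round(delta, digits))
}

#' Maximum rise and fall rates of a normalized curve
#'
#' Extrema of the central-difference derivative in %/s, plus the same
#' extrema relative to the dye reference curve (in % of the reference's
#' rates).
#'
#' @inheritParams response_onset
#' @return List with `max_rise`, `max_fall` (%/s; fall is negative),
#'   `rel_rise_pct`, `rel_fall_pct`.
#' @export
slope_metrics <- function(response, reference = NULL) {
  d <- central_diff(response$pct, response$times)
  out <- list(max_rise = max(d), max_fall = min(d),
              rel_rise_pct = NA_real_, rel_fall_pct = NA_real_)
  if (!is.null(reference)) {
    dr <- central_diff(reference$pct, reference$times)
    out$rel_rise_pct <- out$max_rise / max(dr) * 100
    out$rel_fall_pct <- out$max_fall / min(dr) * 100
  }
  out
}

#' Kinetic metrics of a response window against its dye reference
#'
#' Extracts one injection window from a ratio trace, normalizes and
#' synchronizes it, and computes the full metric set (onset, fwhm,
#' delta-fwhm lingering, rise/fall rates absolute and relative).
#'
#' @param ratio_trace A `ratio_trace` (typically the reference-corrected
#'   mean trace of the responding receptor group).
#' @param reference_profile The dye exposure curve of the reference
#'   injection as a list with `times` and `values` (e.g. from the simulated
#'   exposure profile, or a measured dye trace).
#' @param valve_time Valve time (s) of the response injection.
#' @param reference_valve_time Valve time (s) of the dye injection.
#' @param window_length Window (s) after the valve used for the curve.
#' @param sync_time See [normalize_and_sync()].
#' @param onset_mode See [response_onset()].
#' @param smooth_window Moving-average window (samples) applied to both
#'   curves before normalization, suppressing channel noise in the metric
#'   extraction.
#' @return A list of class `kinetic_metrics`: `onset`, `onset_uncertainty`,
#'   `fwhm`, `reference_fwhm`, `delta_fwhm`, `lingering_label`, `max_rise`,
#'   `max_fall`, `rel_rise_pct`, `rel_fall_pct`.
#' @export
kinetic_metrics <- function(ratio_trace, reference_profile, valve_time,
                            reference_valve_time, window_length = 240,
                            sync_time = 50, onset_mode = "peak_max",
                            smooth_window = 9) {
  resp <- window_pct_curve(ratio_trace$times, ratio_trace$ratio,
                           valve_time, window_length, sync_time,
                           smooth_window = smooth_window)
  ref <- window_pct_curve(reference_profile$times, reference_profile$values,
                          reference_valve_time, window_length, sync_time,
                          smooth_window = smooth_window)
  on <- response_onset(resp, ref, mode = onset_mode)
  # width measured on a heavily smoothed copy of each curve: channel noise
  # both inflates the raw maximum (raising the half-max level) and perturbs
  # the shallow tail crossings, either of which biases the width
  f_resp <- peak_fwhm_raw(resp$times, moving_average(resp$pct, 25))
  f_ref <- peak_fwhm_raw(ref$times, moving_average(ref$pct, 25))
  sl <- slope_metrics(resp, ref)
  structure(list(onset = as.numeric(on),
                 onset_uncertainty = attr(on, "uncertainty"),
                 fwhm = f_resp, reference_fwhm = f_ref,
                 delta_fwhm = f_resp - f_ref,
                 lingering_label = format_lingering(f_resp - f_ref),
                 max_rise = sl$max_rise, max_fall = sl$max_fall,
                 rel_rise_pct = sl$rel_rise_pct,
                 rel_fall_pct = sl$rel_fall_pct),
            class = "kinetic_metrics")
}

# Cut [valve - 30 s, valve + window] from a (times, values) curve, smooth
# it, and normalize/synchronize it.
window_pct_curve <- function(times, values, valve_time, window_length,
                             sync_time = 50, smooth_window = 1) {
  sel <- times >= valve_time - 30 & times <= valve_time + window_length
  normalize_and_sync(times[sel], moving_average(values[sel], smooth_window),
                     valve_time, sync_time)
}
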