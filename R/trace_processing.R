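#' Quality-control filter for array spots
#'
#' Drops spots with fewer than `min_pixels` fluorescent pixels, then drops
#' entire receptor groups whose surviving replicate count is below
#' `min_replicates`. Every removal is reported via `message()`.
#'
#' @param spots Spot table ([make_array()] format).
#' @param min_pixels Minimum pixel count per spot (strict: a spot with
#'   `min_pixels` pixels is retained). Default 15.
#' @param min_replicates Minimum surviving replicates per receptor group
#'   (strict: a group of exactly `min_replicates` is retained). Default 5.
#' @return The retained subset of `spots`.
#' @export
qc_filter <- function(spots, min_pixels = 15, min_replicates = 5) {
  dim_spots <- spots$pixel_count < min_pixels
  if (any(dim_spots))
    message(sprintf("qc_filter: removing %d spot(s) with < %d pixels: %s",
                    sum(dim_spots), min_pixels,
                    paste(spots$spot_id[dim_spots], collapse = ", ")))
  kept <- spots[!dim_spots, , drop = FALSE]
  counts <- table(kept$receptor)
  low <- names(counts)[counts < min_replicates]
  if (length(low) > 0)
    message(sprintf("qc_filter: removing receptor group(s) with < %d replicates: %s",
                    min_replicates, paste(low, collapse = ", ")))
  kept <- kept[!kept$receptor %in% low, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("qc_filter removed every spot", call. = FALSE)
  rownames(kept) <- NULL
  kept
}

#' Compute ratio traces from two-channel intensities
#'
#' Each channel is smoothed with a centered moving average and linearly
#' interpolated onto a common uniform grid (removing the acquisition timing
#' offset between the donor and acceptor channels); the ratio is
#' acceptor/donor (YFP/CFP), so calcium increases give upward peaks.
#'
#' @param trace_set A `trace_set` from [simulate_traces()] or [read_traces()].
#' @param smooth_window Moving-average window in samples (odd; default 3).
#' @param dt_out Output grid step in s (default 1).
#' @param spots Optional spot table restricting which spots are processed
#'   (e.g. the output of [qc_filter()]); defaults to all spots in the set.
#' @return A list of `ratio_trace` objects (one per spot), each a list with
#'   `spot_id`, `receptor`, `times`, `ratio`.
#' @export
compute_ratio <- function(trace_set, smooth_window = 3, dt_out = 1,
                          spots = NULL) {
  stopifnot(inherits(trace_set, "trace_set"))
  if (is.null(spots)) spots <- trace_set$spots
  tr <- trace_set$traces
  if (any(tr$intensity <= 0)) {
    bad <- tr[tr$intensity <= 0, ][1, ]
    stop(sprintf("non-positive intensity for spot %s at t = %g s",
                 bad$spot_id, bad$time_s), call. = FALSE)
  }
  out <- vector("list", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    sid <- spots$spot_id[i]
    sub <- tr[tr$spot_id == sid, , drop = FALSE]
    cfp <- sub[sub$channel == "CFP", , drop = FALSE]
    yfp <- sub[sub$channel == "YFP", , drop = FALSE]
    if (nrow(cfp) == 0 || nrow(yfp) == 0)
      stop("spot ", sid, " is missing a channel", call. = FALSE)
    t0 <- max(min(cfp$time_s), min(yfp$time_s))
    t1 <- min(max(cfp$time_s), max(yfp$time_s))
    grid <- seq(ceiling(t0 / dt_out) * dt_out, t1, by = dt_out)
    c_s <- moving_average(cfp$intensity, smooth_window)
    y_s <- moving_average(yfp$intensity, smooth_window)
    c_i <- stats::approx(cfp$time_s, c_s, xout = grid)$y
    y_i <- stats::approx(yfp$time_s, y_s, xout = grid)$y
    out[[i]] <- structure(list(spot_id = sid,
                               receptor = spots$receptor[i],
                               times = grid, ratio = y_i / c_i),
                          class = "ratio_trace")
  }
  names(out) <- spots$spot_id
  out
}

# Centered moving average with shrinking windows at the edges, so constant
# inputs are exactly invariant.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  h <- (window - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' iRatio peak responses per injection
#'
#' For each injection window, the baseline is the mean ratio over the 10 s
#' preceding the valve time (plus a position-independent transit offset),
#' and the iRatio is the maximum ratio in the window minus that baseline,
#' floored at 0.
#'
#' @param ratio_trace A `ratio_trace` from [compute_ratio()].
#' @param schedule An [injection_schedule()].
#' @param window_length Response window length in s; default exposure
#'   duration + 120 s (supply via `...` from the flow config when known).
#' @param transit_offset Delay (s) between the valve event and sample
#'   arrival at the array; default 0.
#' @param baseline_window Length (s) of the pre-injection baseline mean.
#' @return A data.frame with one row per injection: `spot_id`, `receptor`,
#'   `injection_id`, `sample_id`, `baseline`, `iratio`, `window_start`,
#'   `window_end`.
#' @export
iratio_response <- function(ratio_trace, schedule, window_length = 180,
                            transit_offset = 0, baseline_window = 10) {
  stopifnot(inherits(ratio_trace, "ratio_trace"))
  tt <- ratio_trace$times
  rr <- ratio_trace$ratio
  rows <- lapply(schedule, function(inj) {
    w0 <- inj$valve_time + transit_offset
    w1 <- w0 + window_length
    if (w1 > max(tt)) {
      warning(sprintf("window for %s truncated at trace end (%g > %g s)",
                      inj$injection_id, w1, max(tt)))
      w1 <- max(tt)
    }
    base_idx <- tt >= w0 - baseline_window & tt < w0
    base <- if (any(base_idx)) mean(rr[base_idx]) else rr[which.min(abs(tt - w0))]
    win <- tt >= w0 & tt <= w1
    ir <- max(0, max(rr[win]) - base)
    data.frame(spot_id = ratio_trace$spot_id,
               receptor = ratio_trace$receptor %||% NA_character_,
               injection_id = inj$injection_id,
               sample_id = inj$sample_id,
               baseline = base, iratio = ir,
               window_start = w0, window_end = w1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' iRatio table for a whole trace set
#'
#' Convenience wrapper: QC-filters the spots, computes ratio traces, and
#' stacks [iratio_response()] over all retained spots.
#'
#' @inheritParams compute_ratio
#' @inheritParams iratio_response
#' @inheritParams qc_filter
#' @param reference_receptor Optional receptor label whose mean ratio trace
#'   is subtracted from every spot (see [reference_correct()]) before peak
#'   extraction, removing shared non-specific dips.
#' @return A tidy data.frame (`spot_id`, `receptor`, `injection_id`,
#'   `sample_id`, `baseline`, `iratio`, ...).
#' @export
iratio_table <- function(trace_set, min_pixels = 15, min_replicates = 5,
                         smooth_window = 3, dt_out = 1,
                         window_length = NULL, transit_offset = 0,
                         reference_receptor = NULL) {
  spots <- qc_filter(trace_set$spots, min_pixels, min_replicates)
  if (is.null(window_length))
    window_length <- theoretical_exposure(trace_set$flow_config) + 120
  ratios <- compute_ratio(trace_set, smooth_window, dt_out, spots = spots)
  if (!is.null(reference_receptor)) {
    ref <- mean_ratio_trace(ratios, reference_receptor)
    ratios <- lapply(ratios, function(rt) {
      if (rt$receptor == reference_receptor) rt else reference_correct(rt, ref)
    })
  }
  do.call(rbind, lapply(ratios, iratio_response, schedule = trace_set$schedule,
                        window_length = window_length,
                        transit_offset = transit_offset))
}

#' Mean ratio trace of a receptor group
#'
#' @param ratios List of `ratio_trace`s from [compute_ratio()].
#' @param receptor Receptor label to average over.
#' @return A `ratio_trace` with `spot_id = "mean(<receptor>)"`.
#' @export
mean_ratio_trace <- function(ratios, receptor) {
  sel <- Filter(function(rt) rt$receptor == receptor, ratios)
  if (length(sel) == 0)
    stop("no ratio traces for receptor ", receptor, call. = FALSE)
  tt <- sel[[1]]$times
  for (rt in sel) if (!isTRUE(all.equal(rt$times, tt)))
    stop("ratio traces are not on a common grid", call. = FALSE)
  m <- rowMeans(do.call(cbind, lapply(sel, `[[`, "ratio")))
  structure(list(spot_id = sprintf("mean(%s)", receptor),
                 receptor = receptor, times = tt, ratio = m),
            class = "ratio_trace")
}

#' Reference correction of a ratio trace
#'
#' Subtracts the baseline-anchored excursion of a non-responding reference
#' receptor (umami preferred, mock as fallback) from the target trace:
#' `corrected(t) = target(t) - (reference(t) - reference_baseline)`. This
#' removes shared non-specific artifacts (the osmolarity dip) while leaving
#' the receptor-specific peak untouched.
#'
#' @param target,reference `ratio_trace` objects on the same time grid.
#' @param reference_baseline Baseline of the reference; default the mean of
#'   its first 30 s.
#' @return The corrected `ratio_trace`.
#' @export
reference_correct <- function(target, reference, reference_baseline = NULL) {
  if (length(target$times) != length(reference$times) ||
      !isTRUE(all.equal(target$times, reference$times)))
    stop("target and reference traces are not on the same grid", call. = FALSE)
  if (is.null(reference_baseline))
    reference_baseline <- mean(reference$ratio[reference$times <=
                                               reference$times[1] + 30])
  out <- target
  out$ratio <- target$ratio - (reference$ratio - reference_baseline)
  out
}
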