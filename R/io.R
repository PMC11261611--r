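#' Write a trace set to disk
#'
#' Writes the long-format channel table (`traces.csv`: `time_s`, `spot_id`,
#' `channel`, `intensity`), the array layout (`layout.json`), the injection
#' schedule (`schedule.json`) and the flow configuration (`flow.json`).
#'
#' @param trace_set A `trace_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_traces <- function(trace_set, dir) {
  stopifnot(inherits(trace_set, "trace_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(trace_set$traces, file.path(dir, "traces.csv"),
                   row.names = FALSE)
  jsonlite::write_json(trace_set$spots, file.path(dir, "layout.json"),
                       digits = NA)
  sched <- lapply(trace_set$schedule, function(inj) {
    list(injection_id = inj$injection_id, valve_time = inj$valve_time,
         sample_id = inj$sample_id,
         composition = as.list(inj$composition))
  })
  jsonlite::write_json(sched, file.path(dir, "schedule.json"),
                       auto_unbox = TRUE, digits = NA)
  fc <- trace_set$flow_config
  jsonlite::write_json(fc[!vapply(fc, is.null, logical(1))],
                       file.path(dir, "flow.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a trace set from disk
#'
#' Counterpart of [write_traces()]; validates the schema and returns a
#' `trace_set`. Unknown receptor labels are preserved as opaque strings.
#'
#' @param dir Directory containing `traces.csv`, `layout.json`,
#'   `schedule.json` and `flow.json`.
#' @return A `trace_set`.
#' @export
read_traces <- function(dir) {
  tr_path <- file.path(dir, "traces.csv")
  if (!file.exists(tr_path)) stop("missing traces.csv in ", dir, call. = FALSE)
  traces <- utils::read.csv(tr_path, stringsAsFactors = FALSE)
  need <- c("time_s", "spot_id", "channel", "intensity")
  miss <- setdiff(need, names(traces))
  if (length(miss) > 0)
    stop("traces.csv is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  spots <- as.data.frame(jsonlite::read_json(file.path(dir, "layout.json"),
                                             simplifyVector = TRUE))
  orphans <- setdiff(unique(traces$spot_id), spots$spot_id)
  if (length(orphans) > 0)
    stop("traces.csv contains spot ids absent from layout.json: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  # per spot x channel, times must be strictly increasing
  ord_ok <- vapply(split(traces$time_s, paste(traces$spot_id, traces$channel)),
                   function(tt) !is.unsorted(tt, strictly = TRUE), logical(1))
  if (!all(ord_ok)) {
    bad <- names(ord_ok)[!ord_ok][1]
    stop("non-monotone timestamps for ", bad, call. = FALSE)
  }
  sj <- jsonlite::read_json(file.path(dir, "schedule.json"),
                            simplifyVector = FALSE)
  schedule <- injection_schedule(
    valve_times = vapply(sj, function(x) as.numeric(x$valve_time), numeric(1)),
    sample_ids = vapply(sj, function(x) x$sample_id, character(1)),
    compositions = lapply(sj, function(x) {
      cmp <- unlist(x$composition)
      if (is.null(cmp)) numeric(0) else cmp
    }))
  fj <- jsonlite::read_json(file.path(dir, "flow.json"), simplifyVector = TRUE)
  fc <- flow_config(cell_volume = fj$cell_volume,
                    injection_volume = fj$injection_volume,
                    flow_rate = fj$flow_rate, n_tanks = fj$n_tanks,
                    tailing_fraction = fj$tailing_fraction %||% 0,
                    tailing_tau = fj$tailing_tau %||% 30)
  structure(list(traces = traces, spots = spots, schedule = schedule,
                 flow_config = fc, noise = NULL),
            class = "trace_set")
}

# Small stable string hash (31-base polynomial, mod 2^31) used to stamp
# output tables with the configuration they came from.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
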