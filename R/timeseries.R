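# Uniformly sampled macroscopic time series with provenance metadata.
# Stored as a data.frame (t_ms first, then named channels) with attributes
# recording the model, parameters, solver, step and seed.

new_series <- function(df, meta) {
  stopifnot(is.data.frame(df), "t_ms" %in% names(df))
  if (nrow(df) > 1 && any(diff(df$t_ms) <= 0))
    stop_numeric("time series must have strictly increasing times")
  structure(df, meta = meta, class = c("qiffre_series", "data.frame"))
}

#' @export
print.qiffre_series <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("time series: %d samples, t = %g..%g ms (dt = %g ms)\n",
              nrow(x), x$t_ms[1], x$t_ms[nrow(x)],
              if (nrow(x) > 1) x$t_ms[2] - x$t_ms[1] else NA))
  cat("  channels:", paste(setdiff(names(x), "t_ms"), collapse = ", "), "\n")
  if (!is.null(m$model)) cat("  model:", m$model, "\n")
  if (!is.null(m$solver))
    cat(sprintf("  solver: %s (dt = %g ms)\n", m$solver, m$dt))
  invisible(x)
}

#' Metadata attached to a simulation time series
#'
#' @param x A `qiffre_series` object.
#' @return A list with the resolved model tag, parameters, solver, step
#'   size and (where applicable) seed.
#' @export
series_meta <- function(x) attr(x, "meta")

#' Write or read a time series as CSV with a JSON sidecar
#'
#' The CSV holds the time column `t_ms` and the channel columns (rates in
#' Hz); the sidecar `<path>.json` records the full provenance (model tag,
#' parameters, solver, step, seed) so a run can be reproduced exactly.
#'
#' @param x A `qiffre_series` object.
#' @param path Output CSV path.
#' @return `write_series()`: `path`, invisibly. `read_series()`: the
#'   reconstructed `qiffre_series`.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "qiffre_series"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- attr(x, "meta")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  new_series(df, meta)
}

#' Spike rasters
#'
#' A raster is the list of spike events `(neuron, t_ms)` emitted by a
#' spiking-network simulation, with the neuron count and total duration
#' attached.
#'
#' @param neuron Integer neuron indices (1-based).
#' @param t_ms Spike times in ms.
#' @param N Number of neurons in the network.
#' @param duration Simulated duration in ms.
#' @return An object of class `spike_raster` (a data.frame).
#' @export
spike_raster <- function(neuron, t_ms, N, duration) {
  if (length(neuron) != length(t_ms))
    stop_user("neuron and t_ms must have equal length")
  if (length(t_ms) && (min(t_ms) < 0 || max(t_ms) > duration + 1e-9))
    stop_user("spike times must lie within [0, duration]")
  structure(data.frame(neuron = as.integer(neuron), t_ms = t_ms),
            N = N, duration = duration,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d spikes from %d neurons over %g ms\n",
              nrow(x), attr(x, "N"), attr(x, "duration")))
  invisible(x)
}

#' @rdname spike_raster
#' @param x A `spike_raster`.
#' @param path Output path; the raster is written as two-column
#'   whitespace-separated text (neuron index, spike time in ms).
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "spike_raster"))
  utils::write.table(as.data.frame(x), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Windowed population firing-rate estimator
#'
#' Estimates the instantaneous population rate from a spike raster as the
#' spike count in a trailing window of length `tau_s` divided by
#' `N * tau_s` -- the finite-window version of the empirical rate measure
#' whose `tau_s -> 0` limit defines the population rate.
#'
#' @param raster A [spike_raster()].
#' @param tau_s Window length in ms (> 0).
#' @param times Sample times (ms) at which to evaluate the estimator.
#' @param units `"Hz"` (default) or `"1/ms"`.
#' @return Numeric vector of rates, one per sample time.
#' @export
estimate_rate <- function(raster, tau_s, times, units = c("Hz", "1/ms")) {
  units <- match.arg(units)
  stopifnot(inherits(raster, "spike_raster"))
  if (tau_s <= 0) stop_user("tau_s must be positive")
  N <- attr(raster, "N")
  st <- sort(raster$t_ms)
  counts <- findInterval(times, st) - findInterval(times - tau_s, st)
  r <- counts / (N * tau_s)  # 1/ms
  if (units == "Hz") 1000 * r else r
}
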