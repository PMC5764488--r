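#' Deterministic Lorentzian sample grid
#'
#' Quantile grid representing a Lorentzian (Cauchy) distribution:
#' `center + halfwidth * tan(pi/2 * (2i - N - 1)/(N + 1))` for
#' `i = 1, ..., N`.  The grid is sorted, symmetric about the center, and
#' places no point at the poles of the tangent.  It is used both for the
#' quenched input currents of the spiking networks and for deterministic
#' initial voltage spreads.
#'
#' @param N Number of samples (>= 1).
#' @param center Distribution center.
#' @param halfwidth Half-width at half-maximum (>= 0).
#' @return Sorted numeric vector of length `N`.
#' @examples
#' lorentzian_grid(3, 0, 1)  # -1, 0, 1
#' @export
lorentzian_grid <- function(N, center, halfwidth) {
  if (N < 1) stop_user("N must be at least 1")
  if (halfwidth < 0) stop_user("halfwidth must be non-negative")
  i <- seq_len(N)
  center + halfwidth * tan(pi / 2 * (2 * i - N - 1) / (N + 1))
}

#' Parameters of the QIF network simulator
#'
#' Microscopic counterpart of the QIF-FRE: `N` all-to-all coupled
#' inhibitory QIF neurons `tau_m dV_i/dt = V_i^2 + eta_i - J tau_m S` with
#' quenched currents `eta_i` drawn deterministically from a Lorentzian of
#' center `Theta` and half-width `Delta` (see [lorentzian_grid()]).  A
#' neuron reaching `+V_theta` spikes, is held for a refractory period
#' `2 tau_m / V_theta`, and re-enters at `-V_theta`; the two threshold
#' tails plus the refractory hold approximate the infinite-threshold
#' transit.
#'
#' @param N Number of neurons.
#' @param tau_m,J,Theta,Delta,tau_d As in [fre_params()].
#' @param V_theta Threshold/reset magnitude (default 100; a warning is
#'   issued below 10, where the QIF normal-form approximation degrades).
#' @param tau_s Rate-estimator window (ms; default `1e-2 * tau_m`).
#' @param dt Euler step (ms; default `1e-3 * tau_m`, must be `< tau_s`).
#' @return An object of class `qif_net_params`.
#' @export
qif_net_params <- function(N = 5000, tau_m = 10, J = 21, Theta = 4,
                           Delta = 0.3, tau_d = 5, V_theta = 100,
                           tau_s = 1e-2 * tau_m, dt = 1e-3 * tau_m) {
  validate_fre_params(list(tau_m = tau_m, tau_d = tau_d, J = J,
                           Theta = Theta, Delta = Delta))
  if (N < 1) stop_user("N must be at least 1")
  if (V_theta < 10) warning("V_theta < 10: threshold is not large compared to 1")
  if (dt >= tau_s) stop_user("dt must be smaller than the estimator window tau_s")
  structure(list(N = as.integer(N), tau_m = tau_m, J = J, Theta = Theta,
                 Delta = Delta, tau_d = tau_d, V_theta = V_theta,
                 tau_s = tau_s, dt = dt),
            class = "qif_net_params")
}

#' Simulate an all-to-all inhibitory QIF network
#'
#' Euler simulation of the microscopic network underlying the QIF-FRE.
#' The population rate channel is the trailing-window estimator
#' ([estimate_rate()]) evaluated on-line; the shared gating variable obeys
#' `tau_d dS/dt = -S + R` driven by the instantaneous estimate.  Initial
#' voltages default to a deterministic Lorentzian grid centered at `v0`
#' with half-width `pi * tau_m * r0`, which is the voltage spread the
#' mean-field theory associates with rate `r0` -- so the network starts on
#' the same macroscopic state as the rate equations.  With
#' `init = "random"` the voltages are instead drawn from that Lorentzian
#' (seed recorded in the metadata).
#'
#' @param p A [qif_net_params()] object.
#' @param duration Simulated span (ms).
#' @param r0_hz,v0,s0_hz Initial macroscopic state (defaults 5 Hz, 0, 5 Hz).
#' @param init `"grid"` (deterministic, default), `"random"`, or a numeric
#'   vector of `N` initial voltages.
#' @param seed Seed used when `init = "random"`.
#' @param record_dt Output sampling interval (ms).
#' @param smoothing `"methods"` uses the estimator window `p$tau_s`;
#'   `"wide"` uses `3e-2 * tau_m`, the smoother variant used for
#'   rate-trace comparisons with the mean-field model.
#' @param spike_timing `"crossing"` stamps spikes at the threshold-crossing
#'   step (default); `"midpoint"` stamps them half-way through the
#'   refractory hold, approximating the transit through infinity.
#' @param raster Keep the spike raster? (memory: one row per spike).
#' @return A list of class `qif_net_sim` with elements `series` (a
#'   `qiffre_series` with channels `r_hz`, `s_hz`, `v_mean`; the mean
#'   voltage excludes refractory neurons) and `raster` (a
#'   [spike_raster()] or `NULL`).
#' @export
simulate_qif_network <- function(p, duration, r0_hz = 5, v0 = 0,
                                 s0_hz = r0_hz, init = "grid", seed = NULL,
                                 record_dt = 0.1,
                                 smoothing = c("methods", "wide"),
                                 spike_timing = c("crossing", "midpoint"),
                                 raster = TRUE) {
  stopifnot(inherits(p, "qif_net_params"))
  smoothing <- match.arg(smoothing)
  spike_timing <- match.arg(spike_timing)
  tau_s <- if (smoothing == "methods") p$tau_s else 3e-2 * p$tau_m
  hw <- pi * p$tau_m * r0_hz / 1000
  if (is.numeric(init)) {
    if (length(init) != p$N) stop_user("init voltages must have length N")
    v_init <- init
  } else if (identical(init, "grid")) {
    v_init <- lorentzian_grid(p$N, v0, hw)
  } else if (identical(init, "random")) {
    if (!is.null(seed)) set.seed(seed)
    v_init <- v0 + hw * rcauchy(p$N)
  } else stop_user("init must be 'grid', 'random', or a numeric vector")
  # entering beyond the threshold just means an immediate spike; clamp
  v_init <- pmin(pmax(v_init, -p$V_theta), p$V_theta - 1e-9)

  eta <- lorentzian_grid(p$N, p$Theta, p$Delta)
  out <- qif_net_sim(eta, p$tau_m, p$J, p$tau_d, p$V_theta, p$dt, duration,
                     tau_s, v_init, s0_hz / 1000, record_dt, raster,
                     spike_timing == "midpoint")
  meta <- list(model = "qif_net", params = unclass(p), solver = "euler",
               dt = p$dt, record_dt = record_dt, duration = duration,
               tau_s = tau_s, spike_timing = spike_timing,
               init = if (is.numeric(init)) "vector" else init, seed = seed)
  series <- new_series(data.frame(t_ms = out$time, r_hz = 1000 * out$r,
                                  s_hz = 1000 * out$s, v_mean = out$v_mean),
                       meta)
  structure(list(
    series = series,
    raster = if (raster) spike_raster(out$spike_neuron, out$spike_time,
                                      p$N, duration) else NULL,
    final = list(v = out$v_final, s_hz = 1000 * out$s_final)),
    class = "qif_net_sim")
}

#' @export
print.qif_net_sim <- function(x, ...) {
  print(x$series)
  if (!is.null(x$raster)) print(x$raster)
  invisible(x)
}

#' Free-running period of a single QIF neuron
#'
#' Closed-form period of an isolated QIF neuron with positive input
#' current `eta`: the transit time of `tau_m dV/dt = V^2 + eta` from
#' `-V_theta` to `+V_theta`, `(2 tau_m / sqrt(eta)) atan(V_theta /
#' sqrt(eta))`, plus the refractory hold `2 tau_m / V_theta`.  As
#' `V_theta` grows this converges to `pi tau_m / sqrt(eta)` (the
#' refractory hold compensates the truncated transit tails to leading
#' order, so convergence is fast).
#'
#' @param eta Input current (> 0; at or below 0 the neuron is excitable
#'   and has no periodic solution).
#' @param tau_m Membrane time constant (ms).
#' @param V_theta Threshold magnitude; `Inf` gives the ideal QIF period.
#' @return Period in ms.
#' @examples
#' single_qif_period(4, 10)  # 15.71 ms
#' @export
single_qif_period <- function(eta, tau_m = 10, V_theta = Inf) {
  if (eta <= 0)
    stop_user("eta must be positive: no periodic firing below threshold")
  if (is.infinite(V_theta)) return(pi * tau_m / sqrt(eta))
  2 * tau_m / sqrt(eta) * atan(V_theta / sqrt(eta)) + 2 * tau_m / V_theta
}
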