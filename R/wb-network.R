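#' Parameters of the Wang-Buzsaki network simulator
#'
#' Conductance-based hippocampal interneuron model with transient sodium
#' (instantaneous activation, inactivation `h`), delayed-rectifier
#' potassium (`n`) and leak currents, gating kinetics accelerated by the
#' temperature-like factor `phi`.  The neurons are Class 1 excitable: the
#' transition to repetitive firing is a saddle-node-on-invariant-circle
#' (SNIC) bifurcation, and the constant offset `I0 = 0.1601` uA/cm^2
#' places an isolated neuron exactly at that bifurcation when its applied
#' current is zero.  The applied currents are drawn deterministically from
#' a Lorentzian of center `I_bar` and half-width `sigma`; inhibition is
#' injected as a current `I_syn = k * C_m * S` identical for all neurons,
#' with `S` obeying first-order kinetics driven by the population rate.
#'
#' @param N Number of neurons.
#' @param C_m Membrane capacitance (uF/cm^2).
#' @param g_L,E_L Leak conductance (mS/cm^2) and reversal (mV); the
#'   passive time constant is `C_m / g_L = 10` ms at defaults.
#' @param g_Na,E_Na Sodium conductance (mS/cm^2) and reversal (mV).
#' @param g_K,E_K Potassium conductance (mS/cm^2) and reversal (mV).
#' @param phi Gating rate scale factor.
#' @param I0 Constant current offset placing the neuron at the SNIC
#'   threshold (uA/cm^2).
#' @param I_bar,sigma Center and half-width of the Lorentzian applied
#'   currents (uA/cm^2); `sigma / I_bar` is the relative heterogeneity.
#' @param k Inhibitory coupling strength (mV).
#' @param tau_d Synaptic decay constant (ms).
#' @param tau_s Rate-estimator window (ms; default 0.01).
#' @param dt Euler step (ms; default 0.001).
#' @return An object of class `wb_params`.
#' @export
wb_params <- function(N = 1000, C_m = 1, g_L = 0.1, E_L = -65, g_Na = 35,
                      E_Na = 55, g_K = 9, E_K = -90, phi = 5, I0 = 0.1601,
                      I_bar = 0.5, sigma = 0.01, k = 6, tau_d = 5,
                      tau_s = 0.01, dt = 0.001) {
  if (any(c(g_L, g_Na, g_K) < 0)) stop_user("conductances must be non-negative")
  if (sigma < 0) stop_user("sigma must be non-negative")
  if (tau_d < 0) stop_user("tau_d must be non-negative")
  if (dt <= 0 || tau_s <= 0) stop_user("dt and tau_s must be positive")
  if (N < 1) stop_user("N must be at least 1")
  structure(list(N = as.integer(N), C_m = C_m, g_L = g_L, E_L = E_L,
                 g_Na = g_Na, E_Na = E_Na, g_K = g_K, E_K = E_K, phi = phi,
                 I0 = I0, I_bar = I_bar, sigma = sigma, k = k, tau_d = tau_d,
                 tau_s = tau_s, dt = dt),
            class = "wb_params")
}

#' Gating rate functions of the Wang-Buzsaki model
#'
#' Voltage-dependent opening/closing rates (1/ms) for sodium activation
#' (`alpha_m`, `beta_m`; activation is instantaneous, `m = m_inf`),
#' sodium inactivation (`alpha_h`, `beta_h`) and potassium activation
#' (`alpha_n`, `beta_n`).  The removable singularities of `alpha_m` at
#' `V = -35` mV and `alpha_n` at `V = -34` mV are evaluated as their
#' analytic limits (1 and 0.1).
#'
#' @param V Membrane potential(s), mV.
#' @return A data.frame with columns `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, `m_inf`.
#' @export
wb_rates <- function(V) {
  lim_ratio <- function(x, scale) {
    # scale * x / (exp(x) - 1) with the limit value at x = 0
    out <- ifelse(abs(x) < 1e-7, scale * (1 - x / 2), scale * x / (exp(x) - 1))
    out
  }
  alpha_m <- lim_ratio(-0.1 * (V + 35), 1)
  beta_m <- 4 * exp(-(V + 60) / 18)
  alpha_h <- 0.07 * exp(-(V + 58) / 20)
  beta_h <- 1 / (exp(-0.1 * (V + 28)) + 1)
  alpha_n <- lim_ratio(-0.1 * (V + 34), 0.1)
  beta_n <- 0.125 * exp(-(V + 44) / 80)
  data.frame(alpha_m = alpha_m, beta_m = beta_m, alpha_h = alpha_h,
             beta_h = beta_h, alpha_n = alpha_n, beta_n = beta_n,
             m_inf = alpha_m / (alpha_m + beta_m))
}

#' Right-hand side of a single Wang-Buzsaki neuron
#'
#' Reference implementation of the membrane and gating equations, mainly
#' for testing and inspection; network simulation uses the compiled core
#' in [simulate_wb_network()].
#'
#' @param state Named vector or list with `v` (mV), `h`, `n`.
#' @param p A [wb_params()] object.
#' @param I_app Applied current (uA/cm^2).
#' @param I_syn Synaptic current (uA/cm^2).
#' @return Named vector `c(v, h, n)` of time derivatives.
#' @export
wb_rhs <- function(state, p, I_app = 0, I_syn = 0) {
  v <- state[["v"]]; h <- state[["h"]]; n <- state[["n"]]
  rt <- wb_rates(v)
  I_Na <- p$g_Na * rt$m_inf^3 * h * (v - p$E_Na)
  I_K <- p$g_K * n^4 * (v - p$E_K)
  I_L <- p$g_L * (v - p$E_L)
  c(v = (-I_Na - I_K - I_L - I_syn + I_app + p$I0) / p$C_m,
    h = p$phi * (rt$alpha_h * (1 - h) - rt$beta_h * h),
    n = p$phi * (rt$alpha_n * (1 - n) - rt$beta_n * n))
}

#' Simulate an all-to-all inhibitory Wang-Buzsaki network
#'
#' Euler simulation (step `p$dt`) of `N` WB neurons with shared
#' first-order inhibitory synapses.  A neuron emits a spike when its
#' membrane potential crosses 0 mV upward; spike times are linearly
#' interpolated between steps.  Initial voltages default to a
#' deterministic Lorentzian spread (half-width 5 mV, center -62 mV),
#' truncated to [-90, 30] mV -- membrane potentials far outside the
#' physiological range are meaningless for the gating kinetics.  Gating
#' variables start at their steady states for the initial voltage unless
#' supplied (e.g. when continuing a previous run from its `final` state).
#'
#' @param p A [wb_params()] object.
#' @param duration Simulated span (ms).
#' @param init_v `"grid"` (default), `"random"` (Lorentzian draw, seed
#'   recorded) or a numeric vector of `N` initial voltages (mV).
#' @param v_center,v_halfwidth Center and half-width of the initial
#'   voltage spread (mV).
#' @param init_h,init_n Optional initial gating vectors.
#' @param s0 Initial synaptic activation (1/ms).
#' @param seed Seed used when `init_v = "random"`.
#' @param tau_s Estimator window override (ms), e.g. 2 ms for smoothed
#'   rate traces; defaults to `p$tau_s`.
#' @param record_dt Output sampling interval (ms).
#' @param raster Keep the spike raster?
#' @param exact_rates Evaluate the gating rate functions exactly instead
#'   of via interpolation tables (slower; tables are accurate to ~1e-9).
#' @return A list of class `wb_net_sim` with `series` (channels `r_hz`,
#'   `s_hz`, `v_mean`), `raster`, and `final` (state for continuation).
#' @export
simulate_wb_network <- function(p, duration, init_v = "grid",
                                v_center = -62, v_halfwidth = 5,
                                init_h = NULL, init_n = NULL, s0 = 0,
                                seed = NULL, tau_s = p$tau_s,
                                record_dt = 0.1, raster = TRUE,
                                exact_rates = FALSE) {
  stopifnot(inherits(p, "wb_params"))
  if (is.numeric(init_v)) {
    if (length(init_v) != p$N) stop_user("init_v must have length N")
    v0 <- init_v
  } else if (identical(init_v, "grid")) {
    v0 <- lorentzian_grid(p$N, v_center, v_halfwidth)
  } else if (identical(init_v, "random")) {
    if (!is.null(seed)) set.seed(seed)
    v0 <- v_center + v_halfwidth * rcauchy(p$N)
  } else stop_user("init_v must be 'grid', 'random', or a numeric vector")
  v0 <- pmin(pmax(v0, -90), 30)

  I_app <- lorentzian_grid(p$N, p$I_bar, p$sigma)
  out <- wb_net_sim(I_app, p$C_m, p$g_L, p$E_L, p$g_Na, p$E_Na, p$g_K,
                    p$E_K, p$phi, p$I0, p$k, p$tau_d, p$dt, duration,
                    tau_s, v0, s0, record_dt, raster, !exact_rates,
                    if (is.null(init_h)) numeric(0) else init_h,
                    if (is.null(init_n)) numeric(0) else init_n)
  meta <- list(model = "wb_net", params = unclass(p), solver = "euler",
               dt = p$dt, record_dt = record_dt, duration = duration,
               tau_s = tau_s, seed = seed,
               init = if (is.numeric(init_v)) "vector" else init_v)
  series <- new_series(data.frame(t_ms = out$time, r_hz = 1000 * out$r,
                                  s_hz = 1000 * out$s, v_mean = out$v_mean),
                       meta)
  structure(list(
    series = series,
    raster = if (raster) spike_raster(out$spike_neuron, out$spike_time,
                                      p$N, duration) else NULL,
    final = list(v = out$v_final, h = out$h_final, n = out$n_final,
                 s = out$s_final)),
    class = "wb_net_sim")
}

#' @export
print.wb_net_sim <- function(x, ...) {
  print(x$series)
  if (!is.null(x$raster)) print(x$raster)
  invisible(x)
}

#' Rheobase of a single Wang-Buzsaki neuron (SNIC threshold)
#'
#' Bisection on the onset of repetitive firing of one isolated neuron
#' under constant current: for each candidate current the neuron is
#' simulated from rest for a discard interval plus a probe window, and the
#' criterion is the presence of any 0 mV upward crossing inside the probe
#' window.  Because the bifurcation is a SNIC, the firing period diverges
#' at threshold; the probe window must be long enough that the window
#' bias stays below the requested tolerance.  The constant offset `I0` is
#' excluded: the returned value is the total constant current at
#' threshold, which for the stated conductances is the `I0` that places
#' the neuron at the bifurcation.
#'
#' @param p A [wb_params()] object (only the single-neuron fields are
#'   used).
#' @param bracket Current interval (uA/cm^2) straddling the threshold;
#'   endpoint behavior is verified.
#' @param tol Bisection tolerance (uA/cm^2).
#' @param discard,probe Discard and probe durations (ms).
#' @param v_init Initial membrane potential (mV).
#' @return The threshold current (uA/cm^2), with attributes `iterations`
#'   and `bracket`.
#' @examples
#' \donttest{
#' snic_threshold(wb_params())  # ~0.1601 uA/cm^2
#' }
#' @export
snic_threshold <- function(p = wb_params(), bracket = c(0, 1), tol = 1e-4,
                           discard = 500, probe = 2000, v_init = -62) {
  stopifnot(inherits(p, "wb_params"))
  fires <- function(I) {
    wb_single_spike_count(I, p$C_m, p$g_L, p$E_L, p$g_Na, p$E_Na, p$g_K,
                          p$E_K, p$phi, p$dt, discard, probe, v_init) > 0
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo) || !fires(hi))
    stop_user("bracket does not straddle the firing threshold")
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
    it <- it + 1L
  }
  structure((lo + hi) / 2, iterations = it, bracket = c(lo, hi))
}
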