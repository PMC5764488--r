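#' Steady-state f-I curve of the heterogeneous QIF population
#'
#' The population transfer function
#' \deqn{\Phi(I) = \frac{1}{\pi \tau_m}\sqrt{\frac{I + \sqrt{I^2 +
#'   \Delta^2}}{2}},}
#' i.e. the stationary firing rate of a heterogeneous QIF ensemble whose
#' Lorentzian input-current distribution of half-width `Delta` is centered
#' at `I`.  For `Delta = 0` it reduces to the hard-threshold squashing
#' function `sqrt(max(I, 0)) / (pi * tau_m)` characteristic of Class 1
#' excitability; heterogeneity smooths the threshold.
#'
#' @param I Input current (dimensionless); vectorized.
#' @param Delta Half-width of the current distribution (>= 0).
#' @param tau_m Membrane time constant (ms, > 0).
#' @param units `"Hz"` (default) or `"1/ms"`.
#' @return Firing rate(s), strictly increasing in `I`.
#' @examples
#' fi_curve(4, 0, 10)  # 63.66 Hz, the most likely intrinsic frequency
#' @export
fi_curve <- function(I, Delta = 0, tau_m = 10, units = c("Hz", "1/ms")) {
  units <- match.arg(units)
  if (any(tau_m <= 0)) stop_user("tau_m must be positive")
  if (any(Delta < 0)) stop_user("Delta must be non-negative")
  r <- phi_ms(I, Delta, tau_m)
  if (units == "Hz") 1000 * r else r
}

# Phi in 1/ms (internal unit)
phi_ms <- function(I, Delta, tau_m) {
  sqrt((I + sqrt(I^2 + Delta^2)) / 2) / (pi * tau_m)
}

# dPhi/dI in (1/ms) per unit current; at Delta = 0 only defined for I != 0
phi_prime_ms <- function(I, Delta, tau_m) {
  w <- sqrt(I^2 + Delta^2)
  phi <- phi_ms(I, Delta, tau_m)
  ifelse(phi > 0, (1 + I / w) / (4 * pi^2 * tau_m^2 * phi), 0)
}

#' Right-hand side of the exact QIF firing-rate equations
#'
#' The macroscopic equations for rate `R`, mean membrane potential `V` and
#' synaptic activation `S` of a heterogeneous inhibitory QIF network:
#' \deqn{\tau_m \dot R = \Delta/(\pi \tau_m) + 2 R V}
#' \deqn{\tau_m \dot V = V^2 - (\pi \tau_m R)^2 - J \tau_m S + \Theta}
#' \deqn{\tau_d \dot S = -S + R}
#' The bilinear `R V` term couples the rate to the subthreshold voltage
#' (spike synchrony), and the `-(pi tau_m R)^2` term describes the
#' hyperpolarizing effect of the reset.  When `tau_d = 0` the gating
#' variable is slaved to the rate (`S = R`) and the system reduces to the
#' planar instantaneous-synapse form; supplying a state whose `s` differs
#' from `r` then triggers a warning that the planar form is used.
#'
#' @param state Named numeric vector `c(r, v, s)` with `r`, `s` in 1/ms and
#'   `v` dimensionless (for `tau_d = 0`, `c(r, v)` is accepted).
#' @param p An [fre_params()] object.
#' @param theta Instantaneous external input; defaults to `p$Theta`.
#' @return Named derivative vector `c(r, v, s)` (s-component equals the
#'   r-component in the instantaneous limit).
#' @export
qif_fre_rhs <- function(state, p, theta = p$Theta) {
  r <- state[["r"]]; v <- state[["v"]]
  if (p$tau_d == 0) {
    if ("s" %in% names(state) && abs(state[["s"]] - r) > 1e-12)
      warning("tau_d = 0: planar form used, s is slaved to r")
    dr <- (p$Delta / (pi * p$tau_m) + 2 * r * v) / p$tau_m
    dv <- (v^2 - (pi * p$tau_m * r)^2 - p$J * p$tau_m * r + theta) / p$tau_m
    return(c(r = dr, v = dv, s = dr))
  }
  s <- state[["s"]]
  dr <- (p$Delta / (pi * p$tau_m) + 2 * r * v) / p$tau_m
  dv <- (v^2 - (pi * p$tau_m * r)^2 - p$J * p$tau_m * s + theta) / p$tau_m
  ds <- (-s + r) / p$tau_d
  c(r = dr, v = dv, s = ds)
}

#' Right-hand side of the heuristic (Wilson-Cowan-type) rate equation
#'
#' \deqn{\tau_m \dot R = -R + \Phi(-J \tau_m S + \Theta)}
#' \deqn{\tau_d \dot S = -S + R}
#' with a static f-I curve `phi`.  With `phi` set to the QIF transfer
#' function ([fi_curve()]) the steady state coincides with that of the
#' exact QIF-FRE, but the heuristic model has no voltage channel and its
#' fixed point is always stable: it cannot produce sustained
#' inhibition-based oscillations.
#'
#' @param state Named numeric vector `c(r, s)` (1/ms).
#' @param p An [fre_params()] object with `tau_d > 0`.
#' @param phi Monotone increasing f-I function of the input current,
#'   returning a rate in 1/ms; defaults to the QIF transfer function with
#'   `p`'s `Delta` and `tau_m`.
#' @param theta Instantaneous external input; defaults to `p$Theta`.
#' @return Named derivative vector `c(r, s)`.
#' @export
hfre_rhs <- function(state, p, phi = NULL, theta = p$Theta) {
  if (is.null(phi)) phi <- function(I) phi_ms(I, p$Delta, p$tau_m)
  r <- state[["r"]]; s <- state[["s"]]
  dr <- (-r + phi(-p$J * p$tau_m * s + theta)) / p$tau_m
  if (p$tau_d == 0) stop_user("H-FRE with tau_d = 0 is first order in R; use tau_d > 0")
  ds <- (-s + r) / p$tau_d
  c(r = dr, s = ds)
}

#' Slow-synapse reduction of the QIF-FRE
#'
#' In the limit of slow synaptic kinetics (`tau_d >> tau_m`) and slowly
#' varying drive, the neuronal variables are slaved to the synaptic
#' activation and the QIF-FRE collapse to the scalar flow
#' \deqn{\tau_d \dot S = -S + \Phi(-J \tau_m S + \Theta),}
#' formally identical to the Wilson-Cowan equation for one inhibitory
#' population.  The instantaneous rate readout is
#' `R*(S) = Phi(-J tau_m S + Theta)`.  The reduction breaks down when the
#' external drive fluctuates on the membrane time scale, because fast
#' inputs elicit spike synchrony that the scalar flow cannot represent.
#'
#' @param s Synaptic activation (1/ms).
#' @param p An [fre_params()] object.
#' @param theta Instantaneous external input; defaults to `p$Theta`.
#' @return `slow_reduction_rhs()`: ds/dt (1/ms per ms);
#'   `slow_reduction_rate()`: the rate readout in 1/ms.
#' @export
slow_reduction_rhs <- function(s, p, theta = p$Theta) {
  (-s + phi_ms(-p$J * p$tau_m * s + theta, p$Delta, p$tau_m)) / p$tau_d
}

#' @rdname slow_reduction_rhs
#' @export
slow_reduction_rate <- function(s, p, theta = p$Theta) {
  phi_ms(-p$J * p$tau_m * s + theta, p$Delta, p$tau_m)
}
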