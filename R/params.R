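#' Parameters of the macroscopic firing-rate models
#'
#' Bundles the five parameters shared by the exact QIF firing-rate
#' equations (QIF-FRE), the heuristic rate equation (H-FRE) and the
#' slow-synapse reduction: the membrane and synaptic time constants, the
#' inhibitory coupling strength, and the center and half-width of the
#' Lorentzian distribution of external input currents.
#'
#' Voltages and currents are dimensionless (the QIF voltage is normalized
#' so that positive values are suprathreshold); time constants are in ms.
#' `Delta = 0` describes a network of identical neurons.
#'
#' @param tau_m Membrane time constant (ms, > 0).
#' @param tau_d Synaptic decay time constant (ms, >= 0; 0 selects the
#'   instantaneous-synapse limit in which the gating variable is slaved to
#'   the rate).
#' @param J Inhibitory synaptic strength (dimensionless, >= 0).
#' @param Theta Center of the input-current distribution (dimensionless).
#' @param Delta Half-width of the input-current distribution
#'   (dimensionless, >= 0).
#' @return An object of class `fre_params`.
#' @seealso [nondimensionalize()], [integrate_fre()]
#' @examples
#' fre_params()            # the fast-synapse reference parameter set
#' fre_params(tau_d = 50)  # slow synapses: no sustained oscillation
#' @export
fre_params <- function(tau_m = 10, tau_d = 5, J = 21, Theta = 4, Delta = 0.3) {
  p <- list(tau_m = tau_m, tau_d = tau_d, J = J, Theta = Theta, Delta = Delta)
  validate_fre_params(p)
  structure(p, class = "fre_params")
}

validate_fre_params <- function(p) {
  for (nm in c("tau_m", "tau_d", "J", "Theta", "Delta")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop_user(sprintf("parameter '%s' must be a finite number", nm))
  }
  if (p$tau_m <= 0) stop_user("tau_m must be positive")
  if (p$tau_d < 0) stop_user("tau_d must be non-negative")
  if (p$Delta < 0) stop_user("Delta must be non-negative")
  if (p$J < 0) stop_user("J must be non-negative (inhibitory coupling)")
  invisible(p)
}

#' @export
print.fre_params <- function(x, ...) {
  cat("QIF-FRE parameters:\n")
  cat(sprintf("  tau_m = %g ms, tau_d = %g ms, J = %g, Theta = %g, Delta = %g\n",
              x$tau_m, x$tau_d, x$J, x$Theta, x$Delta))
  if (x$Theta > 0) {
    d <- nondimensionalize(x)
    cat(sprintf("  reduced: j = %g, delta = %g, tau = %g\n", d$j, d$delta, d$tau))
  }
  invisible(x)
}

#' Reduced (nondimensional) parameters
#'
#' The QIF-FRE with `Theta > 0` can be rescaled to a three-parameter form:
#' a reduced coupling `j`, a reduced heterogeneity `delta` (the ratio of
#' the width to the center of the current distribution, comparable to a
#' coefficient of variation), and a reduced synaptic time constant `tau`
#' measuring the synaptic decay relative to the most likely intrinsic
#' period of the neurons.
#'
#' @param j Reduced coupling strength (>= 0).
#' @param delta Reduced heterogeneity (>= 0).
#' @param tau Reduced synaptic time constant (>= 0).
#' @return An object of class `dimless_params`.
#' @export
dimless_params <- function(j, delta, tau) {
  if (delta < 0) stop_user("delta must be non-negative")
  if (tau < 0) stop_user("tau must be non-negative")
  if (j < 0) stop_user("j must be non-negative")
  structure(list(j = j, delta = delta, tau = tau), class = "dimless_params")
}

#' @export
print.dimless_params <- function(x, ...) {
  cat(sprintf("reduced parameters: j = %g, delta = %g, tau = %g\n",
              x$j, x$delta, x$tau))
  invisible(x)
}

#' Map between dimensional and reduced parameter sets
#'
#' The change of variables `r = tau_m R / sqrt(Theta)`,
#' `v = V / sqrt(Theta)`, `s = tau_m S / sqrt(Theta)` with rescaled time
#' `t' = sqrt(Theta) t / tau_m` turns the dimensional QIF-FRE into the
#' reduced system with
#' `j = J / sqrt(Theta)`, `delta = Delta / Theta`,
#' `tau = sqrt(Theta) tau_d / tau_m`.  The reduction is valid for
#' `Theta > 0` only (the majority of neurons intrinsically oscillating).
#' `dimensionalize()` inverts the map for given `tau_m` and `Theta`, so
#' the round trip is the identity.
#'
#' @param p An [fre_params()] object with `Theta > 0`.
#' @return `nondimensionalize()`: a [dimless_params()] object.
#' @examples
#' nondimensionalize(fre_params())            # j = 10.5, delta = 0.075, tau = 1
#' nondimensionalize(fre_params(tau_d = 50))  # tau = 10
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "fre_params"))
  if (p$Theta <= 0)
    stop_user("nondimensionalization requires Theta > 0")
  dimless_params(j = p$J / sqrt(p$Theta),
                 delta = p$Delta / p$Theta,
                 tau = sqrt(p$Theta) * p$tau_d / p$tau_m)
}

#' @rdname nondimensionalize
#' @param d A [dimless_params()] object.
#' @param tau_m,Theta Membrane time constant (ms) and distribution center
#'   fixing the dimensional scale (`Theta > 0`).
#' @return `dimensionalize()`: an [fre_params()] object.
#' @export
dimensionalize <- function(d, tau_m, Theta) {
  stopifnot(inherits(d, "dimless_params"))
  if (Theta <= 0) stop_user("dimensionalize requires Theta > 0")
  fre_params(tau_m = tau_m,
             tau_d = d$tau * tau_m / sqrt(Theta),
             J = d$j * sqrt(Theta),
             Theta = Theta,
             Delta = d$delta * Theta)
}

#' Intrinsic period and frequency of the typical neuron
#'
#' For a QIF neuron with input current `eta > 0` the free-running period in
#' the infinite-threshold limit is `pi * tau_m / sqrt(eta)`.  Evaluated at
#' the center `Theta` of the current distribution this gives the most
#' likely intrinsic period of the network; its inverse is the most likely
#' intrinsic frequency.
#'
#' @param tau_m Membrane time constant (ms).
#' @param Theta Center of the input-current distribution (> 0).
#' @return Period in ms (`intrinsic_period`) or frequency in Hz
#'   (`intrinsic_frequency_hz`).
#' @examples
#' intrinsic_period(10, 4)        # 15.71 ms
#' intrinsic_frequency_hz(10, 4)  # 63.66 Hz
#' @export
intrinsic_period <- function(tau_m = 10, Theta = 4) {
  if (Theta <= 0) stop_user("intrinsic period requires Theta > 0")
  pi * tau_m / sqrt(Theta)
}

#' @rdname intrinsic_period
#' @export
intrinsic_frequency_hz <- function(tau_m = 10, Theta = 4) {
  1000 / intrinsic_period(tau_m, Theta)
}

# internal error helpers: user errors exit 1 from the CLI, numerical errors 2
stop_user <- function(msg) {
  stop(structure(class = c("qiffre_user_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_numeric <- function(msg) {
  stop(structure(class = c("qiffre_numeric_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
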