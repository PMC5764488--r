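#' Integrate a macroscopic rate model
#'
#' Fixed-step classical Runge-Kutta (4th order, via \pkg{deSolve})
#' integration of one of the three rate models: the exact QIF firing-rate
#' equations (`"qif_fre"`), the heuristic Wilson-Cowan-type equation
#' (`"h_fre"`), or the slow-synapse scalar reduction
#' (`"slow_reduction"`).  The default step `tau_m / 100` resolves the
#' membrane time scale; results should be (and in the test suite are)
#' stable under halving of the step.
#'
#' Rates are handled internally in 1/ms and reported in Hz.  The external
#' drive enters the voltage equation (QIF-FRE) or the f-I argument (H-FRE
#' and reduction), and may be time-varying via a [forcing_spec()].
#'
#' @param p An [fre_params()] object.
#' @param model One of `"qif_fre"`, `"h_fre"`, `"slow_reduction"`.
#' @param duration Integration span in ms.
#' @param init Named list with `r_hz`, `v`, `s_hz` (defaults 5 Hz, 0,
#'   5 Hz); unused entries are ignored by models lacking the channel.
#' @param dt Step in ms (default `p$tau_m / 100`).
#' @param forcing Optional [forcing_spec()]; `NULL` means constant drive
#'   `p$Theta`.
#' @param record_dt Output sampling interval (defaults to `dt`; must be a
#'   multiple of `dt`).
#' @return A `qiffre_series` with channels `r_hz`, `v`, `s_hz` (channels a
#'   model lacks are reconstructed where defined: the reduction's rate
#'   readout, the slaved `s = r` in the instantaneous limit) and metadata
#'   recording model, parameters, solver and step.
#' @examples
#' p <- fre_params(tau_d = 50)
#' ts <- integrate_fre(p, "qif_fre", duration = 500)
#' tail(ts$r_hz, 1)  # settles at the fixed-point rate
#' @export
integrate_fre <- function(p, model = c("qif_fre", "h_fre", "slow_reduction"),
                          duration, init = list(r_hz = 5, v = 0, s_hz = 5),
                          dt = p$tau_m / 100, forcing = NULL,
                          record_dt = dt) {
  model <- match.arg(model)
  validate_fre_params(p)
  if (dt <= 0) stop_user("dt must be positive")
  thin <- record_dt / dt
  if (abs(thin - round(thin)) > 1e-8 || thin < 1)
    stop_user("record_dt must be a positive multiple of dt")
  theta_fun <- if (is.null(forcing)) {
    function(t) p$Theta
  } else {
    stopifnot(inherits(forcing, "forcing_spec"))
    function(t) forcing_theta(t, forcing)
  }

  r0 <- (if (is.null(init$r_hz)) 5 else init$r_hz) / 1000
  v0 <- if (is.null(init$v)) 0 else init$v
  s0 <- (if (is.null(init$s_hz)) 5 else init$s_hz) / 1000
  times <- seq(0, duration, by = dt)

  deriv <- switch(model,
    qif_fre = if (p$tau_d == 0) {
      function(t, y, parms)
        list(unname(qif_fre_rhs(c(r = y[1], v = y[2]), p, theta_fun(t))[1:2]))
    } else {
      function(t, y, parms)
        list(unname(qif_fre_rhs(c(r = y[1], v = y[2], s = y[3]), p, theta_fun(t))))
    },
    h_fre = function(t, y, parms)
      list(unname(hfre_rhs(c(r = y[1], s = y[2]), p, theta = theta_fun(t)))),
    slow_reduction = function(t, y, parms)
      list(slow_reduction_rhs(y[1], p, theta_fun(t)))
  )
  y0 <- switch(model,
    qif_fre = if (p$tau_d == 0) c(r0, v0) else c(r0, v0, s0),
    h_fre = c(r0, s0),
    slow_reduction = s0)

  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  bad <- which(rowSums(!is.finite(sol[, -1, drop = FALSE])) > 0)
  if (length(bad))
    stop_numeric(sprintf("non-finite state encountered at t = %g ms",
                         sol[bad[1], 1]))

  keep <- seq(1, nrow(sol), by = as.integer(round(thin)))
  sol <- sol[keep, , drop = FALSE]
  df <- switch(model,
    qif_fre = if (p$tau_d == 0) {
      data.frame(t_ms = sol[, 1], r_hz = 1000 * sol[, 2], v = sol[, 3],
                 s_hz = 1000 * sol[, 2])
    } else {
      data.frame(t_ms = sol[, 1], r_hz = 1000 * sol[, 2], v = sol[, 3],
                 s_hz = 1000 * sol[, 4])
    },
    h_fre = data.frame(t_ms = sol[, 1], r_hz = 1000 * sol[, 2],
                       s_hz = 1000 * sol[, 3]),
    slow_reduction = data.frame(
      t_ms = sol[, 1],
      r_hz = 1000 * slow_reduction_rate(sol[, 2], p, theta_fun(sol[, 1])),
      s_hz = 1000 * sol[, 2]))

  new_series(df, meta = list(
    model = model, params = unclass(p), solver = "rk4", dt = dt,
    record_dt = record_dt, duration = duration,
    init = list(r_hz = 1000 * r0, v = v0, s_hz = 1000 * s0),
    forcing = if (is.null(forcing)) list(type = "constant", base = p$Theta)
              else unclass(forcing)))
}
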