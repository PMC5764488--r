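#' Time-varying external drive
#'
#' Specification of the external input current `Theta(t)` entering the
#' voltage equation of the rate models.  Two forms are supported: a
#' constant drive, and the periodic "sinusoid-cubed" stimulus
#' `Theta(t) = base + (1 + sin(2 pi t / T_theta))^3`, whose cubed
#' nonlinearity produces sharp depolarizing pulses once per period.
#'
#' @param type `"constant"` or `"sinusoid_cubed"`.
#' @param base Constant offset (default 4).
#' @param T_theta Forcing period in ms (required, > 0, for
#'   `"sinusoid_cubed"`).
#' @return An object of class `forcing_spec`.
#' @examples
#' f <- forcing_spec("sinusoid_cubed", T_theta = 100)
#' forcing_theta(c(0, 25, 75), f)  # 5, 12, 4
#' @export
forcing_spec <- function(type = c("constant", "sinusoid_cubed"),
                         base = 4, T_theta = NULL) {
  type <- match.arg(type)
  if (type == "sinusoid_cubed") {
    if (is.null(T_theta) || !is.finite(T_theta) || T_theta <= 0)
      stop_user("sinusoid_cubed forcing requires a period T_theta > 0")
  }
  structure(list(type = type, base = base, T_theta = T_theta),
            class = "forcing_spec")
}

#' @rdname forcing_spec
#' @param t Time(s) in ms.
#' @param spec A `forcing_spec` object.
#' @return `forcing_theta()`: the drive evaluated at `t`.
#' @export
forcing_theta <- function(t, spec) {
  stopifnot(inherits(spec, "forcing_spec"))
  switch(spec$type,
    constant = rep_len(spec$base, length(t)),
    sinusoid_cubed = spec$base + (1 + sin(2 * pi * t / spec$T_theta))^3,
    stop_user(sprintf("unknown forcing type '%s'", spec$type))
  )
}

#' @export
print.forcing_spec <- function(x, ...) {
  if (x$type == "constant") {
    cat(sprintf("constant drive Theta = %g\n", x$base))
  } else {
    cat(sprintf("Theta(t) = %g + (1 + sin(2 pi t / %g ms))^3\n",
                x$base, x$T_theta))
  }
  invisible(x)
}
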