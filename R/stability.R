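#' Fixed point of the nondimensional QIF-FRE
#'
#' The stationary state of the reduced system satisfies
#' `0 = v*^2 - pi^2 r*^2 - j r* + 1` with `v* = -delta / (2 pi r*)` and
#' `s* = r*`.  Substituting `v*` gives a function of `r*` that decreases
#' monotonically from `+Inf` (or 1 for `delta = 0`) to `-Inf` on
#' `r* > 0`, so the positive root is unique; it is located by bracketed
#' root finding and polished by Newton steps to a residual below 1e-12.
#' For `j = 0`, `delta = 0` the rate attains its maximum `1/pi`; strong
#' coupling drives it toward 0.
#'
#' @param j Reduced coupling (>= 0).
#' @param delta Reduced heterogeneity (>= 0).
#' @return An object of class `qif_fixed_point`: a list with `r_star`,
#'   `v_star`, `s_star`, the inputs, and the fixed-point `residual`.
#' @examples
#' qif_fixed_point(0, 0)$r_star  # 1/pi
#' @export
qif_fixed_point <- function(j, delta) {
  if (j < 0 || delta < 0) stop_user("j and delta must be non-negative")
  f <- function(r) delta^2 / (4 * pi^2 * r^2) - pi^2 * r^2 - j * r + 1
  fp <- function(r) -delta^2 / (2 * pi^2 * r^3) - 2 * pi^2 * r - j
  lo <- 1e-12
  hi <- 1 / pi + 1
  while (f(hi) > 0) hi <- hi * 2
  if (delta == 0 && j == 0) {
    r <- 1 / pi
  } else {
    r <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
    for (i in 1:5) r <- r - f(r) / fp(r)  # Newton polish
  }
  v <- if (delta == 0) 0 else -delta / (2 * pi * r)
  structure(list(r_star = r, v_star = v, s_star = r, j = j, delta = delta,
                 residual = abs(v^2 - pi^2 * r^2 - j * r + 1)),
            class = "qif_fixed_point")
}

#' @export
print.qif_fixed_point <- function(x, ...) {
  cat(sprintf("fixed point (j = %g, delta = %g): r* = %.8g, v* = %.8g (residual %.2g)\n",
              x$j, x$delta, x$r_star, x$v_star, x$residual))
  invisible(x)
}

#' Dimensional fixed point of the QIF-FRE
#'
#' Maps the nondimensional fixed point back to a rate (Hz), mean voltage
#' and gating level for a dimensional parameter set; equivalently the
#' self-consistent solution of `R* = Phi(-J tau_m R* + Theta)`.
#'
#' @param p An [fre_params()] object with `Theta > 0`.
#' @return List with `r_hz`, `v`, `s_hz`.
#' @export
qif_fre_fixed_point <- function(p) {
  d <- nondimensionalize(p)
  fp <- qif_fixed_point(d$j, d$delta)
  scale <- sqrt(p$Theta) / p$tau_m  # nondimensional rate -> 1/ms
  list(r_hz = 1000 * fp$r_star * scale, v = fp$v_star * sqrt(p$Theta),
       s_hz = 1000 * fp$s_star * scale)
}

#' Eigenvalues of the heuristic rate equation at its fixed point
#'
#' Linearizing the H-FRE about its steady state gives
#' `lambda = -alpha (1 -+ sqrt(1 - beta))` with
#' `alpha = (tau_m + tau_d) / (2 tau_m tau_d)` and
#' `beta = 4 tau_m tau_d (1 + J tau_m Phi') / (tau_m + tau_d)^2`.
#' Since the f-I curve is increasing (`Phi' > 0`), `beta > 0` and both
#' eigenvalues have negative real part: the heuristic fixed point is
#' always stable (damped oscillations at most, for `beta > 1`).
#'
#' @param p An [fre_params()] object with `tau_d > 0`.
#' @param phi_prime Slope of the f-I curve at the fixed point, in 1/ms per
#'   unit current; computed from the QIF transfer function by default.
#' @return Complex vector of the two eigenvalues (1/ms).
#' @export
hfre_eigenvalues <- function(p, phi_prime = NULL) {
  if (p$tau_d == 0)
    stop_user("tau_d = 0: the H-FRE is first order and has a single real eigenvalue")
  if (is.null(phi_prime)) {
    fp <- qif_fre_fixed_point(p)
    I_star <- -p$J * p$tau_m * fp$r_hz / 1000 + p$Theta
    phi_prime <- phi_prime_ms(I_star, p$Delta, p$tau_m)
  }
  if (phi_prime <= 0) stop_user("phi_prime must be positive")
  alpha <- (p$tau_m + p$tau_d) / (2 * p$tau_m * p$tau_d)
  beta <- 4 * p$tau_m * p$tau_d * (1 + p$J * p$tau_m * phi_prime) /
    (p$tau_m + p$tau_d)^2
  -alpha * (1 + c(1, -1) * sqrt(as.complex(1 - beta)))
}

#' Roots of the characteristic equation of the QIF-FRE
#'
#' Perturbations of the fixed point grow as `exp(lambda t)` where
#' `lambda` solves
#' `-2 j r* = (1 + lambda tau) [(2 pi r*)^2 + (lambda + delta/(pi r*))^2]`
#' (nondimensional units; note `delta/(pi r*) = -2 v*`).  Expanding gives
#' a cubic whose roots are computed from the companion matrix; they
#' coincide with the eigenvalues of the 3x3 Jacobian of the reduced
#' system.  For `tau = 0` the synaptic root disappears and the remaining
#' quadratic has negative discriminant whenever `j > 0`: with
#' instantaneous synapses the fixed point is always a focus (transient
#' spike-synchrony ringing), never unstable.
#'
#' @param j,delta Reduced coupling and heterogeneity.
#' @param tau Reduced synaptic time constant (>= 0).
#' @param fp Optional precomputed [qif_fixed_point()] consistent with
#'   `(j, delta)`.
#' @return Complex vector of the roots (3 for `tau > 0`, 2 for
#'   `tau = 0`), with attribute `residual` giving each root's
#'   characteristic-equation residual.
#' @export
qif_characteristic_roots <- function(j, delta, tau, fp = NULL) {
  if (tau < 0) stop_user("tau must be non-negative")
  if (is.null(fp)) fp <- qif_fixed_point(j, delta)
  r <- fp$r_star
  a <- -2 * fp$v_star          # = delta / (pi r*), >= 0
  cc <- a^2 + (2 * pi * r)^2
  if (tau == 0) {
    coef <- c(cc + 2 * j * r, 2 * a, 1)  # ascending
  } else {
    coef <- c(cc + 2 * j * r, 2 * a + cc * tau, 1 + 2 * a * tau, tau)
  }
  lam <- companion_roots(coef)
  res <- vapply(lam, function(l)
    abs(2 * j * r + (1 + l * tau) * ((2 * pi * r)^2 + (l + a)^2)),
    numeric(1))
  structure(lam, residual = res)
}

# roots of a polynomial (ascending coefficients) via the companion matrix
companion_roots <- function(coef) {
  n <- length(coef) - 1L
  coef <- coef / coef[n + 1L]
  M <- matrix(0, n, n)
  if (n > 1) M[cbind(2:n, 1:(n - 1))] <- 1
  M[, n] <- -coef[1:n]
  eigen(M, only.values = TRUE)$values
}

#' Jacobian eigenvalues of the reduced QIF-FRE
#'
#' Direct numerical eigenvalues of the 3x3 Jacobian of the nondimensional
#' system at its fixed point -- the independent cross-check for
#' [qif_characteristic_roots()].
#'
#' @inheritParams qif_characteristic_roots
#' @return Complex vector of the three eigenvalues (`tau > 0` required).
#' @export
qif_jacobian_eigenvalues <- function(j, delta, tau, fp = NULL) {
  if (tau <= 0) stop_user("the 3-variable Jacobian requires tau > 0")
  if (is.null(fp)) fp <- qif_fixed_point(j, delta)
  r <- fp$r_star; v <- fp$v_star
  Jm <- rbind(c(2 * v, 2 * r, 0),
              c(-2 * pi^2 * r, 2 * v, -j),
              c(1 / tau, 0, -1 / tau))
  eigen(Jm, only.values = TRUE)$values
}

#' Near-critical growth rate for identical neurons
#'
#' For a homogeneous network (`Delta = 0`) the characteristic equation can
#' be expanded about the marginal point `lambda = 2 pi i R*`, giving the
#' leading-order growth rate
#' \deqn{\nu \approx \frac{J \tau_d R_*}{\tau_m (1 + (2\pi\tau_d R_*)^2)}}
#' and oscillation frequency `omega = 2 pi R* + J R* / (tau_m omega_0 X)`
#' terms beyond leading order.  The fixed point is unstable whenever
#' `J tau_d > 0`: any inhibitory coupling with non-instantaneous synapses
#' destabilizes the homogeneous network, and on the `J = 0` boundary the
#' marginal frequency is exactly the intrinsic rate, `omega_c = 2 pi R*`.
#'
#' @param J Synaptic strength (dimensionless).
#' @param tau_d Synaptic decay constant (ms).
#' @param r_star Fixed-point rate in 1/ms.
#' @param tau_m Membrane time constant (ms).
#' @param delta Must be 0 (the expansion assumes identical neurons).
#' @return List with `nu` (growth rate, 1/ms) and `omega` (angular
#'   frequency at marginality, rad/ms).
#' @export
identical_growth_rate <- function(J, tau_d, r_star, tau_m, delta = 0) {
  if (delta != 0)
    stop_user("identical_growth_rate is valid only for delta = 0")
  X <- 1 + (2 * pi * tau_d * r_star)^2
  list(nu = J * tau_d * r_star / (tau_m * X),
       omega = 2 * pi * r_star + J * r_star / (tau_m * 2 * pi * r_star * X))
}

#' Hopf-bifurcation boundary in the (j, tau) plane
#'
#' Setting `lambda = i omega` in the characteristic equation and
#' separating real and imaginary parts yields the marginal frequency
#' `omega^2 = 4 v*^2 + 4 pi^2 r*^2 - 4 v* / tau` and a quadratic in `tau`
#' whose two branches
#' \deqn{\tau_\pm(r_*) = \frac{(1 - \pi^2 r_*^2 - 7 v_*^2) \pm
#'   \sqrt{(\pi^2 r_*^2 - 1)^2 - (14 + 50 \pi^2 r_*^2) v_*^2 - 15
#'   v_*^4}}{-16 v_* (\pi^2 r_*^2 + v_*^2)}}
#' bound the oscillatory region, while the fixed-point relation gives the
#' matching coupling `j(r*) = v*^2/r* + 1/r* - pi^2 r*`.  For
#' `delta = 0` the unstable region is the whole quadrant `j > 0`,
#' `tau > 0`; for `0 < delta < delta_c` the branches close into a finite
#' curve; above the critical heterogeneity ([critical_delta()]) no
#' marginal point exists and the region is empty.
#'
#' @param delta Reduced heterogeneity (>= 0).
#' @param n Number of `r*` samples (log-spaced over `(1e-4, 1/pi - 1e-4)`).
#' @param refine Bisection refinement steps used to locate the ends of the
#'   real-discriminant interval.
#' @return An object of class `hopf_curve`: list with `delta`, `region`
#'   (`"full_quadrant"`, `"closed"` or `"empty"`), `closed` flag and
#'   `boundary`, a data.frame of `(r_star, j, tau_minus, tau_plus)`
#'   samples where the discriminant is non-negative.
#' @examples
#' hopf_curve(0.2)$region   # "empty": heterogeneity destroys oscillations
#' @export
hopf_curve <- function(delta, n = 2000, refine = 40) {
  if (delta < 0) stop_user("delta must be non-negative")
  if (delta == 0) {
    return(structure(list(delta = 0, region = "full_quadrant", closed = FALSE,
                          boundary = data.frame(r_star = numeric(0),
                                                j = numeric(0),
                                                tau_minus = numeric(0),
                                                tau_plus = numeric(0))),
                     class = "hopf_curve"))
  }
  r <- exp(seq(log(1e-4), log(1 / pi - 1e-4), length.out = n))
  disc <- hopf_discriminant(r, delta)
  ok <- disc >= 0
  if (!any(ok)) {
    return(structure(list(delta = delta, region = "empty", closed = FALSE,
                          boundary = data.frame(r_star = numeric(0),
                                                j = numeric(0),
                                                tau_minus = numeric(0),
                                                tau_plus = numeric(0))),
                     class = "hopf_curve"))
  }
  # refine the interval ends where the discriminant changes sign, so the
  # tau+ / tau- branches meet cleanly at the tips of the closed curve
  idx <- which(ok)
  r_sel <- r[idx]
  sharpen <- function(r_out, r_in) {
    for (i in seq_len(refine)) {
      mid <- (r_out + r_in) / 2
      if (hopf_discriminant(mid, delta) >= 0) r_in <- mid else r_out <- mid
    }
    r_in
  }
  if (min(idx) > 1) r_sel <- c(sharpen(r[min(idx) - 1], r[min(idx)]), r_sel)
  if (max(idx) < n) r_sel <- c(r_sel, sharpen(r[max(idx) + 1], r[max(idx)]))

  v <- -delta / (2 * pi * r_sel)
  q <- pi^2 * r_sel^2
  disc <- pmax(hopf_discriminant(r_sel, delta), 0)
  denom <- -16 * v * (q + v^2)
  tau_minus <- ((1 - q - 7 * v^2) - sqrt(disc)) / denom
  tau_plus <- ((1 - q - 7 * v^2) + sqrt(disc)) / denom
  j <- v^2 / r_sel + 1 / r_sel - pi^2 * r_sel
  keep <- tau_minus > 0 & j >= 0
  boundary <- data.frame(r_star = r_sel, j = j, tau_minus = tau_minus,
                         tau_plus = tau_plus)[keep, ]
  structure(list(delta = delta, region = "closed", closed = TRUE,
                 boundary = boundary),
            class = "hopf_curve")
}

hopf_discriminant <- function(r_star, delta) {
  v2 <- (delta / (2 * pi * r_star))^2
  q <- pi^2 * r_star^2
  (q - 1)^2 - (14 + 50 * q) * v2 - 15 * v2^2
}

#' @export
print.hopf_curve <- function(x, ...) {
  cat(sprintf("Hopf boundary at delta = %g: %s region", x$delta, x$region))
  if (nrow(x$boundary))
    cat(sprintf(" (%d boundary samples, j in [%.3g, %.3g])",
                nrow(x$boundary), min(x$boundary$j), max(x$boundary$j)))
  cat("\n")
  invisible(x)
}

#' Is a point of the (j, tau) plane inside the oscillatory region?
#'
#' Decided from the sign of the largest real part among the
#' characteristic-equation roots at `(j, delta, tau)` -- the normative
#' stability criterion, independent of the parametric boundary curve.
#'
#' @param delta,j,tau Reduced parameters of the query point.
#' @param tol Margin below which the point is treated as marginal
#'   (returns `NA`).
#' @return `TRUE` (unstable fixed point: sustained oscillation), `FALSE`,
#'   or `NA` if within `tol` of marginality.
#' @export
hopf_region_contains <- function(delta, j, tau, tol = 1e-9) {
  mx <- max(Re(qif_characteristic_roots(j, delta, tau)))
  if (abs(mx) < tol) return(NA)
  mx > 0
}

#' Heterogeneity at which the Hopf branches merge, and its maximum
#'
#' For fixed `r*` the two branches `tau_+/-` exist while the discriminant
#' of the marginal-stability quadratic is non-negative; `delta_star(r*)`
#' is the heterogeneity at which it vanishes -- the largest `delta` for
#' which the boundary still passes through that `r*`.  Writing
#' `q = pi^2 r*^2`, the vanishing discriminant gives
#' `delta* = 2 pi r* sqrt((8 sqrt(1 + 5q + 10q^2) - 7 - 25q) / 15)`,
#' with zeros at `r* = 0` (the `j -> Inf` limit) and `r* = 1/pi` (the
#' uncoupled rate maximum) and a single interior maximum.
#' `critical_delta()` locates that maximum: the heterogeneity above which
#' collective oscillations are impossible at any coupling and synaptic
#' speed.  The default route maximizes `delta_star` directly; the
#' `"region"` route instead bisects on the disappearance of the
#' [hopf_curve()] region as `delta` grows, as a cross-check.
#'
#' @param r_star Fixed-point rate(s) in `(0, 1/pi)`.
#' @return `delta_star()`: numeric vector of merge heterogeneities.
#' @export
delta_star <- function(r_star) {
  if (any(r_star <= 0 | r_star >= 1 / pi))
    stop_user("r_star must lie in (0, 1/pi)")
  q <- pi^2 * r_star^2
  u <- (8 * sqrt(1 + 5 * q + 10 * q^2) - 7 - 25 * q) / 15
  2 * pi * r_star * sqrt(pmax(u, 0))
}

#' @rdname delta_star
#' @param method `"discriminant"` (maximize `delta_star`) or `"region"`
#'   (bisect on emptiness of the Hopf region).
#' @param tol Numerical tolerance of the optimization/bisection.
#' @return `critical_delta()`: list with `delta_c` and `r_star_c`.
#' @examples
#' critical_delta()  # delta_c = 0.1453, r*_c = 0.1505
#' @export
critical_delta <- function(method = c("discriminant", "region"), tol = 1e-10) {
  method <- match.arg(method)
  if (method == "discriminant") {
    opt <- optimize(delta_star, c(1e-9, 1 / pi - 1e-9), maximum = TRUE,
                    tol = tol)
    return(list(delta_c = opt$objective, r_star_c = opt$maximum))
  }
  lo <- 0.05; hi <- 0.3
  while (hi - lo > max(tol, 1e-9)) {
    mid <- (lo + hi) / 2
    if (hopf_curve(mid, n = 20000)$region == "empty") hi <- mid else lo <- mid
  }
  hc <- hopf_curve(lo, n = 20000)
  r_c <- hc$boundary$r_star[which.max(hopf_discriminant(hc$boundary$r_star, lo))]
  list(delta_c = (lo + hi) / 2, r_star_c = r_c)
}
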