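test_that("f-I curve reproduces the intrinsic frequency and threshold behavior", {
  expect_equal(fi_curve(4, 0, 10), 63.66, tolerance = 1e-4)
  expect_equal(fi_curve(-1, 0, 10), 0)
  expect_equal(fi_curve(-1, 0, 25), 0)
  # identical neurons: exact hard-threshold squashing function
  I <- seq(-3, 6, by = 0.25)
  expect_equal(fi_curve(I, 0, 10, units = "1/ms"),
               sqrt(pmax(I, 0)) / (pi * 10))
  expect_error(fi_curve(1, Delta = -0.1), "Delta")
  expect_error(fi_curve(1, tau_m = 0), "tau_m")
})

test_that("f-I curve is increasing in I, and in Delta below threshold", {
  I <- seq(-5, 10, by = 0.1)
  for (Delta in c(0, 0.3, 1, 3)) {
    expect_true(all(diff(fi_curve(I, Delta, 10)) > -1e-12))
  }
  # heterogeneity smooths the threshold: larger Delta raises subthreshold rates
  for (Ineg in c(-2, -0.5)) {
    expect_true(all(diff(fi_curve(Ineg, c(0.1, 0.5, 1, 2), 10)) > 0))
  }
})

test_that("f-I value matches the long-time rate of the uncoupled rate equations", {
  # oracle: integrate the full model with J = 0, Theta = 0, Delta = 0.3 to
  # steady state; the stationary rate must equal Phi(0)
  p <- fre_params(tau_m = 10, tau_d = 5, J = 0, Theta = 0, Delta = 0.3)
  ts <- integrate_fre(p, "qif_fre", 2000)
  expect_equal(tail(ts$r_hz, 1), fi_curve(0, 0.3, 10), tolerance = 1e-6)
})

test_that("QIF-FRE derivative vanishes at the fixed point and keeps r = 0 invariant at Delta = 0", {
  p <- slow_params()
  fp <- qif_fre_fixed_point(p)
  st <- c(r = fp$r_hz / 1000, v = fp$v, s = fp$s_hz / 1000)
  expect_equal(unname(qif_fre_rhs(st, p)), c(0, 0, 0), tolerance = 1e-12)
  # rate channel cannot leave zero for identical neurons
  p0 <- fre_params(Delta = 0, Theta = -1)
  d <- qif_fre_rhs(c(r = 0, v = -0.5, s = 0), p0, theta = -1)
  expect_equal(d[["r"]], 0)
})

test_that("instantaneous-synapse limit uses the planar system and warns about s", {
  p <- fre_params(tau_d = 0)
  expect_warning(qif_fre_rhs(c(r = 0.01, v = 0, s = 0.5), p), "planar")
  d <- qif_fre_rhs(c(r = 0.01, v = 0), p)
  expect_equal(d[["s"]], d[["r"]])
  # voltage equation must use the instantaneous coupling -J tau_m R
  expect_equal(d[["v"]],
               (0 - (pi * 10 * 0.01)^2 - 21 * 10 * 0.01 + 4) / 10)
})

test_that("QIF-FRE oscillates for fast synapses and decays for slow ones", {
  ts5 <- integrate_fre(fast_params(), "qif_fre", 1000)
  ts50 <- integrate_fre(slow_params(), "qif_fre", 2000)
  expect_gt(late_range(ts5, "r_hz"), 50)        # sustained swings
  expect_lt(late_range(ts50, "r_hz"), 0.5)      # settled
  fp <- qif_fre_fixed_point(slow_params())
  expect_equal(tail(ts50$r_hz, 1), fp$r_hz, tolerance = 1e-3)
})

test_that("H-FRE shares the QIF-FRE steady state but never sustains oscillations", {
  for (p in list(fast_params(), slow_params())) {
    ts <- integrate_fre(p, "h_fre", 2000)
    fp <- qif_fre_fixed_point(p)
    expect_lt(late_range(ts, "r_hz"), 0.2)
    expect_equal(tail(ts$r_hz, 1), fp$r_hz, tolerance = 1e-3)
  }
  st <- local({
    fp <- qif_fre_fixed_point(fast_params())
    c(r = fp$r_hz / 1000, s = fp$s_hz / 1000)
  })
  expect_equal(unname(hfre_rhs(st, fast_params())), c(0, 0), tolerance = 1e-12)
})

test_that("slow-synapse reduction is stationary at the shared fixed point", {
  p <- slow_params()
  fp <- qif_fre_fixed_point(p)
  expect_equal(slow_reduction_rhs(fp$s_hz / 1000, p), 0, tolerance = 1e-12)
  expect_equal(1000 * slow_reduction_rate(fp$s_hz / 1000, p), fp$r_hz,
               tolerance = 1e-9)
})

test_that("steady-state agreement across the three model routes", {
  p <- slow_params()
  fp_hz <- qif_fre_fixed_point(p)$r_hz
  qif <- tail(integrate_fre(p, "qif_fre", 3000)$r_hz, 1)
  hfre <- tail(integrate_fre(p, "h_fre", 3000)$r_hz, 1)
  red <- tail(integrate_fre(p, "slow_reduction", 3000)$r_hz, 1)
  expect_equal(qif, fp_hz, tolerance = 1e-4)
  expect_equal(hfre, fp_hz, tolerance = 1e-4)
  expect_equal(red, fp_hz, tolerance = 1e-4)
})

test_that("fixed-point identity v* r* = -Delta/(2 pi tau_m) holds exactly", {
  for (p in list(fast_params(), fre_params(Delta = 0.8, J = 5))) {
    fp <- qif_fre_fixed_point(p)
    expect_equal((fp$r_hz / 1000) * fp$v, -p$Delta / (2 * pi * p$tau_m),
                 tolerance = 1e-12)
  }
})

test_that("sinusoid-cubed forcing hits its cardinal values", {
  f <- forcing_spec("sinusoid_cubed", T_theta = 100)
  expect_equal(forcing_theta(0, f), 5)
  expect_equal(forcing_theta(25, f), 12)
  expect_equal(forcing_theta(75, f), 4)
  expect_equal(forcing_theta(c(0, 50), forcing_spec("constant")), c(4, 4))
  expect_error(forcing_spec("sinusoid_cubed"), "T_theta")
  expect_error(forcing_spec("ramp"), "arg")
})

test_that("integration from a stationary state yields a constant series", {
  p <- slow_params()
  fp <- qif_fre_fixed_point(p)
  ts <- integrate_fre(p, "qif_fre", 100,
                      init = list(r_hz = fp$r_hz, v = fp$v, s_hz = fp$s_hz))
  expect_lt(diff(range(ts$r_hz)), 1e-8)
  expect_lt(diff(range(ts$v)), 1e-8)
  m <- series_meta(ts)
  expect_equal(m$solver, "rk4")
  expect_equal(m$dt, p$tau_m / 100)
})

test_that("oscillation frequency is in the gamma band and stable under dt halving", {
  p <- fast_params()
  f1 <- oscillation_frequency(integrate_fre(p, "qif_fre", 1000), transient = 200)
  f2 <- oscillation_frequency(integrate_fre(p, "qif_fre", 1000, dt = p$tau_m / 200),
                              transient = 200)
  expect_gt(f1, 30); expect_lt(f1, 100)
  expect_equal(f1, f2, tolerance = 0.01)
})
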