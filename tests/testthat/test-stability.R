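test_that("fixed point: limits, uniqueness and residual", {
  fp <- qif_fixed_point(0, 0)
  expect_equal(fp$r_star, 1 / pi)
  expect_equal(fp$v_star, 0)
  # strong coupling drives the rate to zero
  rs <- vapply(c(1, 10, 100, 1000), function(j) qif_fixed_point(j, 0)$r_star,
               numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_lt(rs[4], 1e-3)
  set.seed(3)
  for (i in 1:25) {
    fp <- qif_fixed_point(runif(1, 0, 30), runif(1, 0, 0.5))
    expect_lt(fp$residual, 1e-12)
    expect_equal(fp$s_star, fp$r_star)
    expect_equal(fp$v_star * fp$r_star, -fp$delta / (2 * pi), tolerance = 1e-12)
  }
})

test_that("fixed point matches the long-time reduced-system integration", {
  # oracle: the reduced system is the dimensional one at tau_m = Theta = 1
  red <- fre_params(tau_m = 1, tau_d = 10, J = 10.5, Theta = 1, Delta = 0.075)
  ts <- integrate_fre(red, "qif_fre", 300)
  expect_equal(tail(ts$r_hz, 1) / 1000, qif_fixed_point(10.5, 0.075)$r_star,
               tolerance = 1e-5)
})

test_that("H-FRE eigenvalues: closed-form cases and unconditional stability", {
  # tau_m = tau_d and J = 0 gives beta = 1: a double eigenvalue at -alpha
  p <- fre_params(tau_m = 10, tau_d = 10, J = 0, Delta = 0.3)
  lam <- hfre_eigenvalues(p)
  alpha <- (10 + 10) / (2 * 10 * 10)
  expect_equal(lam, as.complex(c(-alpha, -alpha)), tolerance = 1e-12)
  # beta = 2 gives the damped-focus pair -alpha (1 -+ i)
  p2 <- fre_params(tau_m = 10, tau_d = 10, J = 21)
  lam2 <- hfre_eigenvalues(p2, phi_prime = 1 / (21 * 10))
  expect_equal(sort(Im(lam2)), c(-alpha, alpha), tolerance = 1e-12)
  expect_equal(Re(lam2), c(-alpha, -alpha), tolerance = 1e-12)
  expect_error(hfre_eigenvalues(fre_params(tau_d = 0)), "first order")
})

test_that("H-FRE is stable across a (J, tau_d) grid at the reference Theta, Delta", {
  for (J in seq(1, 40, length.out = 20)) {
    for (tau_d in seq(1, 100, length.out = 20)) {
      lam <- hfre_eigenvalues(fre_params(tau_d = tau_d, J = J))
      expect_lt(max(Re(lam)), 0)
    }
  }
})

test_that("characteristic roots equal Jacobian eigenvalues (200 random triples)", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    j <- runif(1, 0, 25)
    delta <- runif(1, 0, 0.25)
    tau <- 10^runif(1, -2, 1.5)
    fp <- qif_fixed_point(j, delta)
    r1 <- qif_characteristic_roots(j, delta, tau, fp)
    r2 <- qif_jacobian_eigenvalues(j, delta, tau, fp)
    expect_lt(max(attr(r1, "residual")), 1e-10)
    o1 <- r1[order(Re(r1), Im(r1))]
    o2 <- r2[order(Re(r2), Im(r2))]
    worst <- max(worst, max(Mod(o1 - o2)))
  }
  expect_lt(worst, 1e-8)
})

test_that("instantaneous synapses give a focus: complex pair for any j > 0", {
  for (j in c(0.1, 1, 10, 25)) {
    for (delta in c(0, 0.075, 0.2)) {
      lam <- qif_characteristic_roots(j, delta, 0)
      expect_length(lam, 2)
      expect_true(all(abs(Im(lam)) > 0))
      if (delta == 0) {
        expect_equal(max(Re(lam)), 0)  # undamped focus for identical neurons
      } else {
        expect_lt(max(Re(lam)), 0)     # heterogeneity damps the ringing
      }
    }
  }
})

test_that("uncoupled network factorizes: intrinsic pair plus synaptic root", {
  fp <- qif_fixed_point(0, 0)
  lam <- qif_characteristic_roots(0, 0, 2)
  expect_equal(sort(Im(lam)), c(-2 * pi * fp$r_star, 0, 2 * pi * fp$r_star),
               tolerance = 1e-12)
  expect_equal(min(Re(lam)), -1 / 2, tolerance = 1e-12)
})

test_that("identical-neuron growth rate: sign, boundary frequency, expansion", {
  fp <- qif_fixed_point(0.5, 0)
  g0 <- identical_growth_rate(0, 3, fp$r_star, 1)
  expect_equal(g0$nu, 0)
  expect_equal(g0$omega, 2 * pi * fp$r_star)
  expect_error(identical_growth_rate(1, 1, 0.2, 1, delta = 0.1), "delta = 0")
  # nu > 0 whenever J tau > 0, and matches the root finder to first order
  for (jt in list(c(0.1, 0.01), c(0.05, 0.2), c(1, 0.001))) {
    fp <- qif_fixed_point(jt[1], 0)
    nu <- identical_growth_rate(jt[1], jt[2], fp$r_star, 1)$nu
    nu_root <- max(Re(qif_characteristic_roots(jt[1], 0, jt[2], fp)))
    expect_gt(nu, 0)
    expect_equal(nu, nu_root, tolerance = 0.01)
  }
})

test_that("Hopf region geometry matches the reference phase diagrams", {
  # delta = 0: instability throughout the quadrant
  hc0 <- hopf_curve(0)
  expect_equal(hc0$region, "full_quadrant")
  for (j in c(0.1, 1, 10)) for (tau in c(0.05, 1, 20)) {
    expect_true(hopf_region_contains(0, j, tau))
  }
  # delta = 0.075: closed curve separating the two reference regimes
  hc <- hopf_curve(0.075)
  expect_equal(hc$region, "closed")
  expect_true(all(hc$boundary$tau_plus >= hc$boundary$tau_minus))
  expect_true(hopf_region_contains(0.075, 10.5, 1))
  expect_false(hopf_region_contains(0.075, 10.5, 10))
  # above the critical heterogeneity: no oscillatory region at all
  hc2 <- hopf_curve(0.2)
  expect_equal(hc2$region, "empty")
  for (j in c(1, 10, 25)) for (tau in c(0.1, 1, 10)) {
    expect_false(hopf_region_contains(0.2, j, tau))
  }
})

test_that("points on the Hopf boundary are marginal under the root finder", {
  hc <- hopf_curve(0.075)
  b <- hc$boundary[round(seq(1, nrow(hc$boundary), length.out = 15)), ]
  for (i in seq_len(nrow(b))) {
    for (tau in c(b$tau_minus[i], b$tau_plus[i])) {
      mx <- max(Re(qif_characteristic_roots(b$j[i], 0.075, tau)))
      expect_lt(abs(mx), 1e-6)
    }
  }
})

test_that("delta* vanishes at both rate extremes and peaks in between", {
  expect_lt(delta_star(1e-8), 1e-6)
  expect_lt(delta_star(1 / pi - 1e-8), 1e-3)
  expect_error(delta_star(0), "r_star")
  expect_error(delta_star(1 / pi), "r_star")
  r <- seq(0.01, 1 / pi - 0.01, length.out = 200)
  d <- delta_star(r)
  peak <- which.max(d)
  expect_true(peak > 1 && peak < length(r))
  expect_true(all(diff(d[1:peak]) > 0))
  expect_true(all(diff(d[peak:length(d)]) < 0))
})

test_that("critical heterogeneity agrees between discriminant and region routes", {
  cd1 <- critical_delta()
  cd2 <- critical_delta(method = "region", tol = 1e-8)
  expect_equal(cd1$delta_c, cd2$delta_c, tolerance = 1e-6)
  expect_equal(cd1$r_star_c, cd2$r_star_c, tolerance = 1e-3)
})
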