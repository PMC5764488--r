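test_that("Lorentzian grid: closed forms, symmetry, and CDF convergence", {
  expect_equal(lorentzian_grid(3, 0, 1), c(-1, 0, 1), tolerance = 1e-12)
  g <- lorentzian_grid(11, 4, 0.3)
  expect_equal(g[6], 4)                       # odd middle index at the center
  expect_equal(g + rev(g), rep(8, 11))        # symmetric about the center
  expect_true(all(diff(g) > 0))
  expect_true(all(is.finite(lorentzian_grid(1e4, 4, 0.3))))
  # empirical CDF within Kolmogorov distance 2/N of the arctan CDF
  N <- 1e4
  x <- lorentzian_grid(N, 4, 0.3)
  Fx <- 0.5 + atan((x - 4) / 0.3) / pi
  ks <- max(pmax(abs(seq_len(N) / N - Fx), abs((seq_len(N) - 1) / N - Fx)))
  expect_lt(ks, 2 / N)
})

test_that("single QIF period: closed form, limits, and simulation oracle", {
  expect_equal(single_qif_period(4, 10), 15.71, tolerance = 1e-3)
  expect_equal(single_qif_period(1, 1), pi)
  expect_equal(single_qif_period(4, 10, 100), single_qif_period(4, 10),
               tolerance = 1e-4)
  expect_error(single_qif_period(-1, 10), "positive")
  # oracle: simulate one uncoupled neuron and measure its ISI
  p <- qif_net_params(N = 1, J = 0, Delta = 0, Theta = 4)
  sim <- simulate_qif_network(p, 200, r0_hz = 0, v0 = -100)
  isi <- diff(sim$raster$t_ms)
  expect_gt(length(isi), 5)
  expect_equal(mean(isi), single_qif_period(4, 10, 100), tolerance = 0.01)
})

test_that("excitable regime: below-threshold network stays silent", {
  p <- qif_net_params(N = 50, J = 0, Delta = 0, Theta = -1)
  sim <- simulate_qif_network(p, 500, r0_hz = 0, v0 = -5)
  expect_equal(nrow(sim$raster), 0)
  # voltages approach the resting potential -sqrt(|Theta|)
  expect_equal(unname(sim$final$v), rep(-1, 50), tolerance = 1e-3)
})

test_that("rate estimator: empty raster, single spike, homogeneous rate", {
  empty <- spike_raster(integer(0), numeric(0), N = 100, duration = 10)
  expect_equal(estimate_rate(empty, 0.1, seq(0, 10, 0.5)), rep(0, 21))
  one <- spike_raster(1L, 5.05, N = 100, duration = 10)
  expect_equal(estimate_rate(one, 0.1, 5.1), 1 / (100 * 0.1) * 1000)  # 100 Hz
  expect_equal(estimate_rate(one, 0.1, 7), 0)
  # synthetic homogeneous raster at per-neuron rate rho
  rho <- 0.04  # 1/ms = 40 Hz
  N <- 200
  set.seed(5)
  spikes <- lapply(seq_len(N), function(i) {
    t <- cumsum(stats::rexp(100, rho))
    t[t < 500]
  })
  ras <- spike_raster(rep(seq_len(N), lengths(spikes)), unlist(spikes),
                      N = N, duration = 500)
  est <- estimate_rate(ras, 1, seq(100, 400, 1), units = "1/ms")
  se <- sqrt(rho / (N * 1)) / sqrt(length(est))  # averaged binomial error
  expect_equal(mean(est), rho, tolerance = 5 * se / rho)
})

test_that("raster respects the refractory invariant", {
  p <- qif_net_params(N = 200, tau_m = 10, J = 21, Theta = 4, Delta = 0.3,
                      tau_d = 5)
  sim <- simulate_qif_network(p, 300)
  ras <- sim$raster
  expect_gt(nrow(ras), 100)
  isi_min <- min(vapply(split(ras$t_ms, ras$neuron), function(t)
    if (length(t) > 1) min(diff(t)) else Inf, numeric(1)))
  expect_gte(isi_min, 2 * p$tau_m / p$V_theta - 1e-9)
  expect_true(all(ras$t_ms >= 0 & ras$t_ms <= 300))
})

test_that("network mean rate converges to the mean-field fixed point with N", {
  fp <- qif_fre_fixed_point(slow_params())$r_hz
  err <- vapply(c(500, 5000), function(N) {
    p <- qif_net_params(N = N, tau_d = 50)
    sim <- simulate_qif_network(p, 400, raster = FALSE)
    sel <- sim$series$t_ms > 200
    abs(mean(sim$series$r_hz[sel]) - fp)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2] / fp, 0.05)
})

test_that("network gating channel tracks the mean-field s channel in both regimes", {
  for (td in c(5, 50)) {
    p <- fre_params(tau_d = td)
    fre <- integrate_fre(p, "qif_fre", 250, dt = 0.1)
    np <- qif_net_params(N = 2000, tau_d = td)
    sim <- simulate_qif_network(np, 250, raster = FALSE, smoothing = "wide")
    sel <- sim$series$t_ms > 100
    d <- rel_l2(sim$series$s_hz[sel], fre$s_hz[-1][sel])
    expect_lt(d, if (td == 5) 0.15 else 0.05)
  }
})
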