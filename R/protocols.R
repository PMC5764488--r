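#' Oscillation amplitude of a macroscopic observable
#'
#' Measures the mean peak-to-peak excursion of a channel after a
#' transient: the series is cut into `n_windows` consecutive windows of
#' `window` ms and the per-window `max - min` values are averaged.  The
#' windowed average makes the measure robust to slow drift and to
#' finite-size jitter in network observables.
#'
#' @param series A `qiffre_series` (or a numeric vector, in which case
#'   `t_ms` must be supplied).
#' @param channel Channel name (default `"v_mean"`, the observable least
#'   affected by finite-size fluctuations).
#' @param transient Discarded initial span (ms).
#' @param window Window length (ms).
#' @param n_windows Number of windows averaged.
#' @param t_ms Sample times when `series` is a plain vector.
#' @return Mean peak-to-peak amplitude (channel units).
#' @export
oscillation_amplitude <- function(series, channel = "v_mean",
                                  transient = 1000, window = 200,
                                  n_windows = 5, t_ms = NULL) {
  if (inherits(series, "qiffre_series")) {
    t_ms <- series$t_ms
    x <- series[[channel]]
    if (is.null(x)) stop_user(sprintf("no channel '%s' in series", channel))
  } else {
    x <- series
    if (is.null(t_ms)) stop_user("t_ms must be supplied for a plain vector")
  }
  need <- transient + n_windows * window
  if (max(t_ms) < need - 1e-9)
    stop_user(sprintf("series too short: %g ms needed, %g available",
                      need, max(t_ms)))
  amp <- vapply(seq_len(n_windows), function(w) {
    sel <- t_ms > transient + (w - 1) * window & t_ms <= transient + w * window
    diff(range(x[sel]))
  }, numeric(1))
  mean(amp)
}

#' Dominant oscillation frequency of a channel
#'
#' Frequency from mean inter-peak intervals in the post-transient
#' segment.  Local maxima count as peaks only if they rise above the
#' neighboring minima by at least `prominence` times the post-transient
#' range of the signal, which rejects finite-size ripple in network rate
#' traces.  Returns 0 when fewer than two qualifying peaks exist (e.g. a
#' constant or monotonically relaxing channel).
#'
#' @inheritParams oscillation_amplitude
#' @param channel Channel name (default `"r_hz"`).
#' @param transient Discarded initial span (ms).
#' @param prominence Prominence floor as a fraction of the channel range.
#' @return Frequency in Hz (0 if not oscillating).
#' @export
oscillation_frequency <- function(series, channel = "r_hz", transient = 0,
                                  prominence = 0.05, t_ms = NULL) {
  if (inherits(series, "qiffre_series")) {
    t_ms <- series$t_ms
    x <- series[[channel]]
    if (is.null(x)) stop_user(sprintf("no channel '%s' in series", channel))
  } else {
    x <- series
    if (is.null(t_ms)) stop_user("t_ms must be supplied for a plain vector")
  }
  sel <- t_ms > transient
  x <- x[sel]; tt <- t_ms[sel]
  rng <- diff(range(x))
  if (rng <= 0) return(0)
  pk <- find_peaks(x, prominence * rng)
  if (length(pk) < 2) return(0)
  1000 / mean(diff(tt[pk]))
}

# indices of local maxima with prominence >= floor (prominence measured
# against the higher of the two flanking minima)
find_peaks <- function(x, floor) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- logical(length(cand))
  mins <- c(which(diff(sign(diff(x))) > 0) + 1L)
  bounds <- c(1L, mins, n)
  for (k in seq_along(cand)) {
    i <- cand[k]
    left <- max(bounds[bounds < i])
    right <- min(bounds[bounds > i])
    base <- max(min(x[left:i]), min(x[i:right]))
    keep[k] <- (x[i] - base) >= floor
  }
  cand[keep]
}

#' Compare the macroscopic models (and optionally the QIF network)
#'
#' Runs the requested models from a common initial state under a common
#' drive, aligns the rate and gating channels on a shared comparison
#' grid, and reports pairwise relative L2 distances over the
#' post-transient span:
#' `||x - y||_2 / ||y||_2` with `y` the second model of the pair.
#' Channels are window-averaged onto the comparison grid (default 1 ms)
#' before differencing, so that network traces are compared within their
#' finite-size fluctuation band rather than at raw estimator resolution.
#'
#' @param p An [fre_params()] object shared by all models.
#' @param models Subset of `"qif_fre"`, `"h_fre"`, `"slow_reduction"`,
#'   `"qif_net"`.
#' @param forcing Optional [forcing_spec()].
#' @param duration Simulated span (ms).
#' @param transient Span excluded from the distance (ms).
#' @param compare_dt Comparison grid step (ms).
#' @param N Network size when `"qif_net"` is included.
#' @param init Common initial macroscopic state, as in [integrate_fre()].
#' @param dt Integration step for the rate models (ms).
#' @return An object of class `model_comparison`: list with the aligned
#'   `series` (one `qiffre_series` per model on the comparison grid), and
#'   `distance`, a named list of pairwise-distance matrices for the `r`
#'   and `s` channels.
#' @export
compare_models <- function(p, models = c("qif_fre", "h_fre", "slow_reduction"),
                           forcing = NULL, duration = 1000, transient = 100,
                           compare_dt = 1, N = 5000,
                           init = list(r_hz = 5, v = 0, s_hz = 5),
                           dt = p$tau_m / 100) {
  models <- match.arg(models, c("qif_fre", "h_fre", "slow_reduction",
                                "qif_net"), several.ok = TRUE)
  record_dt <- p$tau_m / 100
  runs <- list()
  for (m in models) {
    if (m == "qif_net") {
      np <- qif_net_params(N = N, tau_m = p$tau_m, J = p$J, Theta = p$Theta,
                           Delta = p$Delta, tau_d = p$tau_d)
      if (!is.null(forcing))
        stop_user("time-varying drive is not supported by the network comparison")
      sim <- simulate_qif_network(np, duration, r0_hz = init$r_hz,
                                  v0 = init$v, s0_hz = init$s_hz,
                                  record_dt = record_dt,
                                  smoothing = "wide", raster = FALSE)
      runs[[m]] <- sim$series
    } else {
      runs[[m]] <- integrate_fre(p, m, duration, init = init, dt = dt,
                                 forcing = forcing, record_dt = record_dt)
    }
  }
  # window-average all channels onto the common comparison grid and keep
  # only bins present in every model (series may or may not include t = 0)
  aligned <- lapply(runs, bin_series, compare_dt = compare_dt)
  common <- Reduce(intersect, lapply(aligned, function(x) x$t_ms))
  aligned <- lapply(aligned, function(x) {
    new_series(as.data.frame(x)[match(common, x$t_ms), , drop = FALSE],
               attr(x, "meta"))
  })
  sel <- aligned[[1]]$t_ms > transient
  rel_l2 <- function(x, y) sqrt(mean((x - y)^2)) / sqrt(mean(y^2))
  dist_for <- function(ch) {
    D <- matrix(NA_real_, length(models), length(models),
                dimnames = list(models, models))
    for (i in seq_along(models)) for (k in seq_along(models)) {
      if (i == k) { D[i, k] <- 0; next }
      D[i, k] <- rel_l2(aligned[[i]][[ch]][sel], aligned[[k]][[ch]][sel])
    }
    D
  }
  structure(list(series = aligned, transient = transient,
                 distance = list(r = dist_for("r_hz"), s = dist_for("s_hz"))),
            class = "model_comparison")
}

bin_series <- function(x, compare_dt) {
  # average samples into absolute windows ((b-1)*dt, b*dt]; the bin label
  # is the window's right edge, so identically sampled models align even
  # when one series includes t = 0 and another starts at its first step
  bin <- ceiling(round(x$t_ms / compare_dt, 9))
  full <- tabulate(bin + 1L)
  keep_bins <- which(full == max(full)) - 1L  # drop partial windows
  sel <- bin %in% keep_bins
  df <- data.frame(t_ms = keep_bins * compare_dt)
  for (ch in setdiff(names(x), "t_ms"))
    df[[ch]] <- as.numeric(tapply(x[[ch]][sel], bin[sel], mean)[
                           as.character(keep_bins)])
  new_series(df, attr(x, "meta"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (relative L2, post-transient):\n")
  cat("r channel:\n"); print(round(x$distance$r, 4))
  cat("s channel:\n"); print(round(x$distance$s, 4))
  invisible(x)
}

#' Oscillation-amplitude phase diagram over (tau_d, k)
#'
#' Reproduces the sweep protocol used to map oscillatory regions of the
#' Wang-Buzsaki network: for each synaptic time constant in `tau_d_grid`
#' the coupling `k` is stepped in the requested direction, each run
#' seeded with the final state of the previous one (continuation), and
#' the mean-membrane-potential oscillation amplitude is measured per
#' cell.  The QIF network can be swept with the same protocol (grids then
#' mean `J` values instead of `k`).
#'
#' @param p A [wb_params()] or [qif_net_params()] template; `tau_d` and
#'   the coupling field are overridden per cell.
#' @param tau_d_grid,k_grid Strictly increasing grids of the synaptic
#'   constant (ms) and coupling strength.
#' @param direction `"increasing"` or `"decreasing"` coupling sweep.
#' @param transient Discard before measuring (ms); later cells of a row
#'   inherit the previous cell's state, so this can be much shorter than
#'   a cold-start transient.
#' @param window,n_windows Amplitude-measurement windows (ms, count).
#' @param channel Channel measured (default `"v_mean"`).
#' @return An object of class `phase_diagram`: list with the grids, the
#'   amplitude matrix (rows = `tau_d`, cols = `k`), `delta` (relative
#'   heterogeneity of the template), and the sweep direction.
#' @export
phase_diagram_sweep <- function(p, tau_d_grid, k_grid,
                                direction = c("increasing", "decreasing"),
                                transient = 300, window = 200, n_windows = 3,
                                channel = "v_mean") {
  direction <- match.arg(direction)
  if (!length(tau_d_grid) || !length(k_grid))
    stop_user("grids must be nonempty")
  if (any(diff(tau_d_grid) <= 0) || any(diff(k_grid) <= 0))
    stop_user("grid axes must be strictly increasing")
  is_wb <- inherits(p, "wb_params")
  if (!is_wb && !inherits(p, "qif_net_params"))
    stop_user("p must be wb_params or qif_net_params")
  ks <- if (direction == "increasing") k_grid else rev(k_grid)
  dur <- transient + n_windows * window
  A <- matrix(NA_real_, length(tau_d_grid), length(k_grid),
              dimnames = list(tau_d = tau_d_grid, k = k_grid))
  for (i in seq_along(tau_d_grid)) {
    state <- NULL
    for (kk in seq_along(ks)) {
      ci <- if (direction == "increasing") kk else length(ks) - kk + 1
      res <- tryCatch({
        if (is_wb) {
          pp <- p
          pp$tau_d <- tau_d_grid[i]
          pp$k <- ks[kk]
          sim <- simulate_wb_network(
            pp, dur,
            init_v = if (is.null(state)) "grid" else state$v,
            init_h = state$h, init_n = state$n,
            s0 = if (is.null(state)) 0 else state$s,
            raster = FALSE, record_dt = 0.5)
          state <- sim$final
        } else {
          pp <- p
          pp$tau_d <- tau_d_grid[i]
          pp$J <- ks[kk]
          sim <- simulate_qif_network(
            pp, dur,
            init = if (is.null(state)) "grid" else state$v,
            s0_hz = if (is.null(state)) 5 else state$s_hz,
            raster = FALSE, record_dt = 0.5)
          state <- sim$final
        }
        oscillation_amplitude(sim$series, channel, transient = transient,
                              window = window, n_windows = n_windows)
      }, error = function(e) {
        stop_numeric(sprintf("sweep cell (tau_d = %g, k = %g) failed: %s",
                             tau_d_grid[i], ks[kk], conditionMessage(e)))
      })
      A[i, ci] <- res
    }
  }
  delta <- if (is_wb) {
    if (p$I_bar != 0) p$sigma / p$I_bar else NA_real_
  } else {
    if (p$Theta != 0) p$Delta / p$Theta else NA_real_
  }
  structure(list(tau_d = tau_d_grid, k = k_grid, amplitude = A,
                 delta = delta, direction = direction, channel = channel),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram (%s sweep, delta = %g): amplitude of %s\n",
              x$direction, x$delta, x$channel))
  print(round(x$amplitude, 2))
  invisible(x)
}
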