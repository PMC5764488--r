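# shared fixtures and small numeric helpers

fast_params <- function() fre_params(tau_m = 10, tau_d = 5, J = 21,
                                     Theta = 4, Delta = 0.3)
slow_params <- function() fre_params(tau_m = 10, tau_d = 50, J = 21,
                                     Theta = 4, Delta = 0.3)

rel_l2 <- function(x, y) sqrt(mean((x - y)^2)) / sqrt(mean(y^2))

# late-time peak-to-peak excursion of a channel
late_range <- function(series, channel, frac = 0.2) {
  n <- nrow(series)
  sel <- seq(floor((1 - frac) * n), n)
  diff(range(series[[channel]][sel]))
}

small_wb <- function(N = 100, ...) wb_params(N = N, ...)
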