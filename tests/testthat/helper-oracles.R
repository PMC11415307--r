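# Independent oracles used across the suite. These never call package code.

# Fixed-step classical 4th-order Runge-Kutta for dC/dt = deriv(t, C),
# returning C at each requested time (times[1] is the initial time).
rk4_oracle <- function(deriv, c0, times, h) {
  out <- matrix(NA_real_, nrow = length(times), ncol = length(c0))
  out[1, ] <- c0
  state <- c0
  t <- times[1]
  for (k in 2:length(times)) {
    while (t < times[k] - 1e-12) {
      step <- min(h, times[k] - t)
      k1 <- deriv(t, state)
      k2 <- deriv(t + step / 2, state + step / 2 * k1)
      k3 <- deriv(t + step / 2, state + step / 2 * k2)
      k4 <- deriv(t + step, state + step * k3)
      state <- state + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[k, ] <- state
  }
  out
}

# Exact ordinary-least-squares slope of y on t (closed form, no lm()).
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled ranks to the first sample (tie-free data only).
ranksum_exact_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Shared scenario used in several transfer tests: donor effectively at
# plateau from the first sample (loading tau << sampling interval).
equilibrated_transfer <- function(rate, noise_cv = 0, seed = 1,
                                  duration_s = 900) {
  transfer_scenario(rate = rate,
                    calibration = fluorescence_calibration(5, 50),
                    tau_load_s = 1e-3, plateau_um = 2000,
                    duration_s = duration_s,
                    noise_cv = noise_cv, seed = seed)
}
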