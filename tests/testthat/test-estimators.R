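cal55 <- fluorescence_calibration(f = 5, f0 = 50)

test_that("select_linear_window returns the full extent of an exact line", {
  tr <- fluorescence_trace(seq(0, 600, by = 10), 500 - 0.3 * seq(0, 600, by = 10))
  w <- select_linear_window(tr)
  expect_equal(unname(w), c(0, 600))
})

test_that("select_linear_window locates a plateau-to-decay changepoint", {
  # short plateau (13 samples) before solution exchange, then exponential
  # decay with measurement noise; the decay phase is the longest
  # lack-of-fit-consistent stretch, so the selected window must start close
  # to the changepoint and cover the decay, never swallowing the plateau
  times <- seq(0, 420, by = 10)
  cp <- 120
  for (seed in 1:4) {
    set.seed(seed)
    vals <- ifelse(times <= cp, 500, 500 * exp(-(times - cp) / 600)) +
      rnorm(length(times), 0, 3)
    w <- select_linear_window(fluorescence_trace(times, vals))
    expect_lte(abs(w[["t_start"]] - cp), 50)  # within 5 samples
    expect_gte(w[["t_end"]], cp + 200)        # covers the decay phase
  }
})

test_that("select_linear_window accepts a noisy flat trace in full", {
  set.seed(11)
  times <- seq(0, 1790, by = 10)
  tr <- fluorescence_trace(times, 300 + rnorm(length(times), 0, 3))
  w <- select_linear_window(tr)
  expect_equal(unname(w), c(0, 1790))
  fit <- fit_efflux_slope(tr, w)
  ci <- fit$slope_k + c(-1, 1) * stats::qt(0.975, fit$n - 2) * fit$slope_se
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("select_linear_window masks excluded (blocker) intervals", {
  times <- seq(0, 900, by = 10)
  vals <- 500 - 0.3 * times
  vals[times >= 300 & times <= 500] <- 350  # blocked: flux suspended
  tr <- fluorescence_trace(times, vals)
  w <- select_linear_window(tr, exclude = list(c(300, 500)))
  expect_true(w[["t_end"]] < 300 || w[["t_start"]] > 500)
})

test_that("fit_efflux_slope is exact on a straight line", {
  times <- seq(0, 300, by = 10)
  tr <- fluorescence_trace(times, 500 - 0.4 * times)
  fit <- fit_efflux_slope(tr, c(0, 300))
  expect_equal(fit$slope_k, -0.4)
  expect_equal(fit$intercept_c, 500)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_efflux_slope(tr, c(100, 100.5)), "3 samples")
})

test_that("efflux slope over the Taylor window matches the closed-form OLS value", {
  # P/Vol = 1e-3 /s, alpha = 0, f = 5, C0 = 100: the tangent slope at t0 is
  # -0.5 a.u./s; the OLS slope over the first 0.05*Vol/P = 50 s of the exact
  # exponential is slightly shallower because a finite-window OLS slope
  # tracks the derivative near the window centre
  p <- efflux_params(vol_in = 1, perm = 0.001, c_in_0 = 100)
  tr <- generate_efflux_trace(efflux_scenario(p, cal55, noise_cv = 0))
  fit <- fit_efflux_slope(tr, c(0, 50))
  tt <- seq(0, 50, by = 10)
  expected <- ols_slope_oracle(tt, 5 * 100 * exp(-0.001 * tt) + 50)
  expect_equal(fit$slope_k, expected, tolerance = 1e-10)
  expect_equal(fit$slope_k, -0.5, tolerance = 0.03)
})

test_that("slope CI covers zero for a noisy constant trace", {
  set.seed(21)
  times <- seq(0, 1790, by = 10)  # n = 180
  tr <- fluorescence_trace(times, 400 + rnorm(180, 0, 5))
  fit <- fit_efflux_slope(tr, c(0, 1790))
  ci <- fit$slope_k + c(-1, 1) * stats::qt(0.975, fit$n - 2) * fit$slope_se
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("donor steady-state detection brackets the loading time constant", {
  times <- seq(0, 900, by = 30)
  donor <- fluorescence_trace(times, 1000 * (1 - exp(-times / 80)))
  t_ss <- detect_donor_steady_state(donor)
  expect_gte(t_ss, 300)
  expect_lte(t_ss, 450)

  flat <- fluorescence_trace(times, rep(800, length(times)))
  expect_equal(detect_donor_steady_state(flat), 0)

  ramp <- fluorescence_trace(times, 100 + 2 * times)
  expect_true(is.na(detect_donor_steady_state(ramp)))

  short <- fluorescence_trace(seq(0, 200, by = 10), rep(1, 21))
  expect_error(detect_donor_steady_state(short), "5 minutes")
})

test_that("recipient exponential fit recovers a known rate to 0.1% on ideal data", {
  # donor at plateau, recipient generated directly from the closed form
  times <- seq(0, 900, by = 30)
  c2 <- recipient_solution(c1 = 400, c2_t0 = 40, rate = 0.0011, t0 = 0,
                           t = times)
  donor <- fluorescence_trace(times, rep(5 * 400 + 50, length(times)),
                              background = 50)
  recipient <- fluorescence_trace(times, 5 * c2 + 50, background = 50)
  est <- fit_recipient_exponential(donor, recipient, t_ss = 0)
  expect_equal(est$method, "exponential_fit")
  expect_equal(est$rate, 0.0011, tolerance = 0.001)
  expect_equal(est$diagnostics$amplitude_ratio, 10, tolerance = 0.01)
})

test_that("recipient exponential fit fails cleanly on degenerate inputs", {
  times <- seq(0, 900, by = 30)
  donor <- fluorescence_trace(times, rep(2050, length(times)), background = 50)
  # recipient already equilibrated with the donor: rate unidentifiable
  same <- fluorescence_trace(times, rep(2050, length(times)), background = 50)
  expect_error(fit_recipient_exponential(donor, same, t_ss = 0),
               "unidentifiable")
  # recipient at background: the ratio form is undefined
  at_bg <- fluorescence_trace(times, rep(50, length(times)), background = 50)
  expect_error(fit_recipient_exponential(donor, at_bg, t_ss = 0),
               "background")
})

test_that("discretized estimator matches truth and the exponential fit on noiseless data", {
  pair <- generate_transfer_traces(equilibrated_transfer(rate = 0.0011))
  disc <- estimate_rate_discretized(pair$donor, pair$recipient)
  expect_equal(disc$method, "discretized")
  expect_equal(disc$rate, 0.0011, tolerance = 0.02)
  expo <- fit_recipient_exponential(pair$donor, pair$recipient)
  expect_equal(disc$rate, expo$rate, tolerance = 0.05)
  # per-step estimates retained for all steps past t_min
  expect_true(all(c("t_s", "estimate", "used") %in%
                    names(disc$diagnostics$steps)))
  expect_gt(disc$diagnostics$n_used, 10)
})

test_that("discretized estimator handles zero-gradient and zero-flux cases", {
  times <- seq(0, 900, by = 30)
  f <- fluorescence_trace(times, rep(500, length(times)), background = 50)
  expect_error(estimate_rate_discretized(f, f), "zero donor-recipient")

  donor <- fluorescence_trace(times, rep(2000, length(times)), background = 50)
  flat_rec <- fluorescence_trace(times, rep(300, length(times)), background = 50)
  est <- estimate_rate_discretized(donor, flat_rec)
  expect_equal(est$rate, 0)
})

test_that("estimates are invariant to background offset and calibration scale", {
  pair <- generate_transfer_traces(equilibrated_transfer(rate = 0.002,
                                                         noise_cv = 0.02,
                                                         seed = 5))
  shift <- function(tr, d) {
    fluorescence_trace(tr$times, tr$values + d, background = tr$background + d)
  }
  scale_tr <- function(tr, s) {
    fluorescence_trace(tr$times, (tr$values - tr$background) * s +
                         tr$background, background = tr$background)
  }
  base_e <- fit_recipient_exponential(pair$donor, pair$recipient)$rate
  base_d <- estimate_rate_discretized(pair$donor, pair$recipient)$rate
  off_e <- fit_recipient_exponential(shift(pair$donor, 137),
                                     shift(pair$recipient, 137))$rate
  off_d <- estimate_rate_discretized(shift(pair$donor, 137),
                                     shift(pair$recipient, 137))$rate
  expect_equal(off_e, base_e, tolerance = 1e-8)
  expect_equal(off_d, base_d, tolerance = 1e-12)
  sc_e <- fit_recipient_exponential(scale_tr(pair$donor, 3.7),
                                    scale_tr(pair$recipient, 3.7))$rate
  sc_d <- estimate_rate_discretized(scale_tr(pair$donor, 3.7),
                                    scale_tr(pair$recipient, 3.7))$rate
  expect_equal(sc_e, base_e, tolerance = 1e-8)
  expect_equal(sc_d, base_d, tolerance = 1e-12)

  # the raw efflux slope scales linearly with f, and is offset-invariant
  p <- efflux_params(vol_in = 1, perm = 0.001, c_in_0 = 100)
  tr1 <- generate_efflux_trace(efflux_scenario(p, fluorescence_calibration(5, 50),
                                               noise_cv = 0.02, seed = 9))
  tr2 <- scale_tr(tr1, 2)  # doubled f: signal doubles about the background
  k1 <- fit_efflux_slope(tr1, c(0, 300))$slope_k
  k2 <- fit_efflux_slope(tr2, c(0, 300))$slope_k
  expect_equal(k2 / k1, 2, tolerance = 1e-9)
  tr3 <- shift(tr1, 400)
  expect_equal(fit_efflux_slope(tr3, c(0, 300))$slope_k, k1)
})

test_that("expected |k| grows with the generating permeability", {
  slopes <- vapply(c(2e-4, 1e-3, 5e-3), function(perm) {
    ks <- vapply(1:8, function(r) {
      p <- efflux_params(vol_in = 1, perm = perm, c_in_0 = 100)
      tr <- generate_efflux_trace(efflux_scenario(p, cal55, noise_cv = 0.02,
                                                  seed = 100 + r))
      fit_efflux_slope(tr, c(0, 300))$slope_k
    }, numeric(1))
    mean(abs(ks))
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("blocker intervals are masked out of transfer fits", {
  sc <- equilibrated_transfer(rate = 0.002)
  sc$blockers <- list(c(300, 600))
  pair <- generate_transfer_traces(sc)
  est <- estimate_rate_discretized(pair$donor, pair$recipient,
                                   exclude = list(c(300, 600)))
  # steps inside the blocked interval never enter the average
  used_t <- est$diagnostics$steps$t_s[est$diagnostics$steps$used]
  expect_false(any(used_t >= 330 & used_t <= 600))
  expect_equal(est$rate, 0.002, tolerance = 0.05)
})

test_that("hemichannel and GJ normalization arithmetic", {
  pop <- channel_population(g_ns = 3.4, gamma_ps = 340)
  expect_equal(pop$n_po, 10)
  fit <- structure(list(slope_k = -0.5), class = "linear_fit")
  norm <- normalize_hemichannel(fit, pop)
  expect_equal(norm$value, -0.05)
  expect_equal(normalize_hemichannel(0, pop)$value, 0)
  expect_error(normalize_hemichannel(fit, 0), "positive")

  rate <- structure(list(rate = 0.0011), class = "rate_estimate")
  gj <- normalize_gj(rate, gj_ns = 1.15, gamma_j_ps = 115)  # 10 channels
  expect_equal(gj$value, 1.1e-4)
  expect_equal(normalize_gj(0, 2, 100)$value, 0)
  expect_error(normalize_gj(rate, -1, 115), "positive")

  # per-channel value is invariant to channel count at fixed per-channel rate
  vals <- vapply(c(5, 20, 80), function(n) {
    normalize_gj(1e-5 * n, gj_ns = n * 115 / 1000, gamma_j_ps = 115)$value
  }, numeric(1))
  expect_equal(vals, rep(1e-5, 3), tolerance = 1e-10)
})
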