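test_that("two-compartment model: zero-permeability and no-gradient identities", {
  p0 <- two_compartment_params(vol1 = 2, vol2 = 5, perm = 0,
                               c1_0 = 100, c2_0 = 0)
  sim <- simulate_two_compartment(p0, seq(0, 1000, by = 50))
  expect_equal(sim$c1_um, rep(100, nrow(sim)))
  expect_equal(sim$c2_um, rep(0, nrow(sim)))

  peq <- two_compartment_params(vol1 = 1, vol2 = 3, perm = 0.02,
                                c1_0 = 50, c2_0 = 50)
  sim <- simulate_two_compartment(peq, seq(0, 1000, by = 100))
  expect_equal(sim$c1_um, rep(50, nrow(sim)))
  expect_equal(sim$c2_um, rep(50, nrow(sim)))
})

test_that("two-compartment solution matches the RK4 oracle and conserves mass", {
  p <- two_compartment_params(vol1 = 1, vol2 = 1, perm = 0.01,
                              c1_0 = 100, c2_0 = 0)
  times <- c(0, 100)
  sim <- simulate_two_compartment(p, times)
  oracle <- rk4_oracle(function(t, s) {
    c(p$perm * (s[2] - s[1]) / p$vol1, p$perm * (s[1] - s[2]) / p$vol2)
  }, c(p$c1_0, p$c2_0), times, h = 0.01)
  expect_equal(sim$c1_um[2], oracle[2, 1], tolerance = 1e-6)
  expect_equal(sim$c2_um[2], oracle[2, 2], tolerance = 1e-6)

  # mass conservation across a parameter sweep
  for (perm in c(1e-4, 1e-3, 1e-2, 1e-1)) {
    pp <- two_compartment_params(vol1 = 0.7, vol2 = 2.3, perm = perm,
                                 c1_0 = 80, c2_0 = 5)
    sim <- simulate_two_compartment(pp, seq(0, 2000, by = 20))
    amount <- pp$vol1 * sim$c1_um + pp$vol2 * sim$c2_um
    const <- pp$vol1 * pp$c1_0 + pp$vol2 * pp$c2_0
    expect_lt(max(abs(amount - const)) / const, 1e-9)
  }
})

test_that("two-compartment simulation rejects non-monotone time vectors", {
  p <- two_compartment_params(1, 1, 0.01, 100, 0)
  expect_error(simulate_two_compartment(p, c(0, 10, 5)), "increasing")
  expect_error(simulate_two_compartment(p, c(5, 10, 20)), "start at 0")
})

test_that("efflux solution: initial condition, RK4 agreement, fixed point", {
  p <- efflux_params(vol_in = 1, perm = 0.01, c_in_0 = 100, alpha = 0)
  expect_identical(efflux_solution(p, 0), 100)

  oracle <- rk4_oracle(function(t, c) (p$alpha - p$perm * c) / p$vol_in,
                       p$c_in_0, c(0, 100), h = 0.01)
  expect_equal(efflux_solution(p, 100), oracle[2, 1], tolerance = 1e-6)

  # with production, the long-time limit is the ODE's fixed point alpha/P
  pa <- efflux_params(vol_in = 2, perm = 0.005, c_in_0 = 100, alpha = 0.1)
  expect_equal(efflux_solution(pa, 1e7), pa$alpha / pa$perm, tolerance = 1e-8)

  # zero-permeability limit form: linear production
  pz <- efflux_params(vol_in = 2, perm = 0, c_in_0 = 10, alpha = 0.1)
  expect_equal(efflux_solution(pz, c(0, 100)), c(10, 10 + 0.1 / 2 * 100))
})

test_that("efflux and recipient closed forms track RK4 over a rate grid", {
  for (rate in 10^seq(-4, -1, by = 1)) {
    p <- efflux_params(vol_in = 1, perm = rate, c_in_0 = 100, alpha = 0.02)
    times <- seq(0, 2000, by = 250)
    oracle <- rk4_oracle(function(t, c) (p$alpha - p$perm * c) / p$vol_in,
                         p$c_in_0, times, h = 0.5)
    expect_equal(efflux_solution(p, times), oracle[, 1], tolerance = 1e-6)

    oracle2 <- rk4_oracle(function(t, c) rate * (100 - c), 10, times, h = 0.5)
    expect_equal(recipient_solution(100, 10, rate, 0, times), oracle2[, 1],
                 tolerance = 1e-6)
  }
})

test_that("linearized efflux: balance point, slope sign, tangency", {
  cal <- fluorescence_calibration(f = 5, f0 = 20)
  # alpha exactly balancing efflux at t0 gives a flat line
  pb <- efflux_params(vol_in = 1, perm = 0.01, c_in_0 = 50, alpha = 0.5)
  expect_equal(efflux_linear_approx(pb, cal, 0, c(0, 100, 500)),
               rep(5 * 50 + 20, 3))
  # alpha = 0: strictly negative slope -f*C(t0)*P/Vol
  p <- efflux_params(vol_in = 2, perm = 0.004, c_in_0 = 100, alpha = 0)
  fl <- efflux_linear_approx(p, cal, 0, c(0, 10))
  expect_equal(diff(fl) / 10, -5 * 100 * 0.004 / 2)
  expect_lt(diff(fl), 0)

  # the linear coefficient is f times the numerical derivative of the
  # exact solution at the expansion point (central difference at t0 = 10 s)
  for (perm in c(1e-3, 1e-2, 5e-2)) {
    pp <- efflux_params(vol_in = 1.5, perm = perm, c_in_0 = 80, alpha = 0.01)
    eps <- 1e-3
    dnum <- (efflux_solution(pp, 10 + eps) - efflux_solution(pp, 10 - eps)) /
      (2 * eps)
    pt0 <- efflux_params(vol_in = pp$vol_in, perm = pp$perm,
                         c_in_0 = efflux_solution(pp, 10), alpha = pp$alpha)
    slope <- (efflux_linear_approx(pt0, cal, 10, 11) -
                efflux_linear_approx(pt0, cal, 10, 10)) / 1
    expect_equal(slope, cal$f * dnum, tolerance = 1e-8)
  }
})

test_that("linearized efflux stays within 1% of the exact solution early on", {
  cal <- fluorescence_calibration(f = 5, f0 = 0)
  for (rate in c(1e-3, 1e-2, 5e-2)) {
    p <- efflux_params(vol_in = 1, perm = rate, c_in_0 = 100, alpha = 0.05)
    t_max <- 0.1 / rate  # 0.1 * Vol/P
    tt <- seq(0, t_max, length.out = 20)
    exact <- cal$f * efflux_solution(p, tt) + cal$f0
    approx_f <- efflux_linear_approx(p, cal, 0, tt)
    expect_lt(max(abs(approx_f - exact) / exact), 0.01)
  }
})

test_that("recipient solution: identities, RK4 check, monotone approach", {
  expect_equal(recipient_solution(100, 10, 0, 0, c(0, 500, 5000)),
               rep(10, 3))
  expect_equal(recipient_solution(100, 100, 0.01, 0, c(0, 100)), rep(100, 2))

  oracle <- rk4_oracle(function(t, c) 0.0011 * (100 - c), 10, c(0, 600),
                       h = 0.01)
  expect_equal(recipient_solution(100, 10, 0.0011, 0, 600), oracle[2, 1],
               tolerance = 1e-6)

  up <- recipient_solution(100, 10, 0.002, 0, seq(0, 3000, by = 30))
  expect_true(all(diff(up) >= 0))
  expect_true(all(up <= 100))
  down <- recipient_solution(10, 100, 0.002, 0, seq(0, 3000, by = 30))
  expect_true(all(diff(down) <= 0))

  expect_error(relative_fluorescence(100, 0, 0.001, 0, 10), "undefined")
  expect_equal(relative_fluorescence(100, 10, 0.0011, 0, 600),
               recipient_solution(100, 10, 0.0011, 0, 600) / 10)
})

test_that("parameter constructors enforce invariants", {
  expect_error(two_compartment_params(0, 1, 0.01, 10, 0))
  expect_error(efflux_params(1, -0.1, 10))
  expect_error(fluorescence_calibration(0))
  expect_error(fluorescence_calibration(5, -1))
})
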