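test_that("synchronization factor follows Q0*z1/2 and vanishes without drive", {
  expect_equal(synchronization_factor(pacemaker_perturbation(0, 2 * pi * 8),
                                      phase_response_curve(0.3, 1)), 0)
  expect_equal(synchronization_factor(pacemaker_perturbation(2, 2 * pi * 8),
                                      phase_response_curve(0, 1)), 1)
  expect_equal(synchronization_factor(pacemaker_perturbation(3, 10),
                                      phase_response_curve(-1, 0)), 0)
})

test_that("averaged Adler model converges to the full PRC model as drive weakens", {
  omega_theta <- 2 * pi * 8
  prc <- phase_response_curve(z0 = 0.4, z1 = 1)
  T <- 10 / 8  # ten pacemaker cycles
  errs <- sapply(c(2, 1, 0.5, 0.25), function(Q0) {
    pert <- pacemaker_perturbation(Q0, omega_theta)
    A <- synchronization_factor(pert, prc)
    omega <- omega_theta + 1.6 * A  # fixed detuning/A ratio
    full <- integrate_prc_model(omega, prc, pert, phi0 = 0.3, T = T)
    avg <- integrate_adler(phase_reduction_params(omega - omega_theta, A),
                           phi0 = 0.3, T = T)
    max(abs(full$phase_diff - avg$phase_diff))
  })
  expect_true(all(diff(errs) < 0))  # three halvings, monotone decrease
})

test_that("regime classification distinguishes locking, pulling and the boundary", {
  expect_identical(classify_regime(phase_reduction_params(0, 1)), "locking")
  expect_identical(classify_regime(phase_reduction_params(2, 1)), "pulling")
  expect_identical(classify_regime(phase_reduction_params(1, 1)), "boundary")
  expect_identical(classify_regime(phase_reduction_params(-0.5, 1)), "locking")
  expect_identical(classify_regime(phase_reduction_params(1 + 1e-12, 1)),
                   "boundary")
})

test_that("locking phase is arcsin(detuning/A) and spans exactly 180 degrees", {
  expect_equal(locking_phase(phase_reduction_params(0, 1)), 0)
  expect_equal(locking_phase(phase_reduction_params(0.5, 1)), pi / 6)
  # numeric oracle: Adler integration converges to the same phase
  p <- phase_reduction_params(0.5, 1)
  tr <- integrate_adler(p, phi0 = -2, T = 30)
  expect_equal(tr$phase_diff[length(tr$phase_diff)], pi / 6, tolerance = 1e-6)
  # full span over admissible detunings (eps kept clear of the boundary
  # classification tolerance)
  eps <- 1e-8
  span <- locking_phase(phase_reduction_params(1 - eps, 1)) -
    locking_phase(phase_reduction_params(-(1 - eps), 1))
  expect_equal(span, pi, tolerance = 1e-3)
  expect_error(locking_phase(phase_reduction_params(2, 1)), "invalid-regime")
  expect_error(locking_phase(phase_reduction_params(1, 1)), "invalid-regime")
})

test_that("locking attractor: trajectories from phases spanning the circle converge", {
  p <- phase_reduction_params(0.6, 1)
  lock <- locking_phase(p)
  unstable <- pi - lock
  phis <- seq(0, 2 * pi, length.out = 17)[-17]
  phis <- phis[abs(wrap_pi(phis - unstable)) > 0.05]
  for (phi0 in phis) {
    tr <- integrate_adler(p, phi0 = phi0, T = 40, dt = 5e-4)
    expect_equal(wrap_pi(tr$phase_diff[length(tr$phase_diff)]), lock,
                 tolerance = 1e-4)
  }
})

test_that("precession frequency is sqrt(dw^2 - A^2)/2pi with the drift sign reported", {
  f <- precession_frequency(phase_reduction_params(2 * pi, 0))
  expect_equal(as.numeric(f), 1)
  expect_equal(attr(f, "drift"), 1)
  f2 <- precession_frequency(phase_reduction_params(2 * pi * 1.25, 2 * pi * 0.75))
  expect_equal(as.numeric(f2), 1)
  f3 <- precession_frequency(phase_reduction_params(-2 * pi * 1.25, 2 * pi * 0.75))
  expect_equal(attr(f3, "drift"), -1)
  expect_error(precession_frequency(phase_reduction_params(0.5, 1)),
               "invalid-regime")
})

test_that("pulling-regime rotation rate matches the closed-form frequency", {
  for (ratio in c(1.05, 1.5, 3, 10)) {
    p <- phase_reduction_params(ratio * 2, 2)
    f <- as.numeric(precession_frequency(p))
    T <- 25 / f  # at least 20 cycles
    dt <- min(1e-4 / f, 1e-4)
    tr <- integrate_adler(p, phi0 = 0, T = T, dt = dt)
    n_cyc <- (tr$phase_diff[length(tr$phase_diff)] - tr$phase_diff[1]) / (2 * pi)
    rate <- n_cyc / T
    expect_equal(rate, f, tolerance = 0.005)
  }
})

test_that("closed-form Adler solution matches RK4 pointwise in both regimes", {
  grid <- list(c(2, 1), c(-3, 1), c(0.5, 1), c(-0.9, 1), c(1.05, 1),
               c(10, 1), c(0, 1), c(0.2, 2))
  for (g in grid) {
    p <- phase_reduction_params(g[1], g[2])
    T <- if (abs(g[1]) > g[2]) 10 * 2 * pi / sqrt(g[1]^2 - g[2]^2) else 10
    T <- min(T, 60)
    for (phi0 in c(0.3, -3, 3)) {
      tr <- integrate_adler(p, phi0 = phi0, T = T, dt = 1e-4)
      cf <- adler_solution(p, tr$times, phi0 = phi0)
      expect_lt(max(abs(tr$phase_diff - cf$phase_diff)), 1e-6)
    }
  }
})

test_that("closed form degenerates and saturates correctly", {
  # A = 0: pure linear drift
  p0 <- phase_reduction_params(1.3, 0)
  tr <- adler_solution(p0, c(0, 1, 2), phi0 = 0.5)
  expect_equal(tr$phase_diff, 0.5 + 1.3 * c(0, 1, 2))
  # locking regime: t -> infinity limit equals the locking phase
  p <- phase_reduction_params(0.7, 1)
  expect_equal(adler_solution(p, 60, phi0 = -2)$phase_diff,
               locking_phase(p), tolerance = 1e-9)
  # pulling regime: advance of exactly one cycle per period
  pp <- phase_reduction_params(3, 1)
  f <- as.numeric(precession_frequency(pp))
  tr2 <- adler_solution(pp, c(0.2, 0.2 + 1 / f), phi0 = 1)
  expect_equal(diff(tr2$phase_diff), 2 * pi, tolerance = 1e-9)
  expect_error(adler_solution(phase_reduction_params(0, 0), 1, phi0 = 0),
               "degenerate-parameters")
})

test_that("closed form satisfies the Adler ODE by finite differencing", {
  p <- phase_reduction_params(1.8, 1.1)
  t <- seq(0.1, 2, by = 1e-4)
  tr <- adler_solution(p, t, phi0 = 0.4)
  dphi_num <- diff(tr$phase_diff) / 1e-4
  mid <- (tr$phase_diff[-1] + tr$phase_diff[-length(t)]) / 2
  expect_lt(max(abs(dphi_num - (p$delta_omega - p$A * sin(mid)))), 1e-4)
})

test_that("Adler integrator respects fixed points and rejects coarse steps", {
  p <- phase_reduction_params(0, 1)
  tr <- integrate_adler(p, phi0 = 0, T = 1)
  expect_true(all(tr$phase_diff == 0))
  tr2 <- integrate_adler(p, phi0 = pi - 1e-6, T = 40)
  expect_equal(tr2$phase_diff[length(tr2$phase_diff)], 0, tolerance = 1e-6)
  expect_error(integrate_adler(phase_reduction_params(2000, 1), 0, 1, dt = 1e-3),
               "step-too-large")
})

test_that("PRC model without drive is a bare rotator; z0-only drive has no mean shift", {
  pert0 <- pacemaker_perturbation(0, 2 * pi * 8)
  prc <- phase_response_curve(0.5, 1)
  tr <- integrate_prc_model(2 * pi * 7, prc, pert0, phi0 = 0.2, T = 0.5)
  expect_equal(tr$phase, 0.2 + 2 * pi * 7 * tr$times, tolerance = 1e-10)
  # z1 = 0: over whole pacemaker cycles the cosine drive averages out
  prc0 <- phase_response_curve(0.5, 0)
  pert <- pacemaker_perturbation(1, 2 * pi * 8)
  tr2 <- integrate_prc_model(2 * pi * 7, prc0, pert, phi0 = 0, T = 1)
  expect_equal(tr2$phase[length(tr2$phase)], 2 * pi * 7, tolerance = 1e-6)
})

test_that("speed-constraint detuning enforces f = v/(2R)", {
  expect_equal(speed_constraint_detuning(0, 0.5, 1.2), 1.2)
  dw <- speed_constraint_detuning(0.4, 0.6, 0)
  expect_equal(dw, pi * 0.4 / 0.6)
  f <- as.numeric(precession_frequency(phase_reduction_params(dw, 0)))
  expect_equal(f, 0.4 / (2 * 0.6), tolerance = 1e-12)
  # round trip at the stated example
  dw2 <- speed_constraint_detuning(0.4, 0.6, 1)
  f2 <- as.numeric(precession_frequency(phase_reduction_params(dw2, 1)))
  expect_equal(f2, 1 / 3, tolerance = 1e-12)
  # property: identity holds for random admissible inputs
  set.seed(42)
  for (k in 1:25) {
    v <- runif(1, 0.05, 1.5); R <- runif(1, 0.1, 5); A <- runif(1, 0, 3)
    dwk <- speed_constraint_detuning(v, R, A)
    expect_gte(dwk, A)
    fk <- as.numeric(precession_frequency(phase_reduction_params(dwk, A)))
    expect_equal(fk, v / (2 * R), tolerance = 1e-12)
  }
})
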