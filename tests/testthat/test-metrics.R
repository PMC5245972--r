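test_that("spike phases wrap correctly and honor pacemaker resets", {
  f <- 8
  expect_equal(spike_phases(c(0, 1 / f, 2 / f), f), c(0, 0, 0))
  expect_equal(spike_phases(1.5 / f, f), pi)
  expect_equal(spike_phases(c(0.9, 1.0, 1.21), f, reset_times_s = 1),
               c(wrap_2pi(2 * pi * f * 0.9), 0, wrap_2pi(2 * pi * f * 0.21)))
})

test_that("single-cell metric is -1 for perfect precession and near 0 for noise", {
  x <- seq(0, 1, length.out = 60)
  phi <- (-4.5 * x + 5) %% (2 * pi)  # no wrap inside the data range
  r <- single_cell_precession(x, phi)
  expect_equal(r$rho, -1, tolerance = 1e-9)
  set.seed(1)
  r0 <- single_cell_precession(runif(1000), runif(1000, 0, 2 * pi))
  expect_lt(abs(r0$rho), 0.1)
  expect_error(single_cell_precession(c(1, 2), c(0, 1)), "3 spikes")
  expect_error(single_cell_precession(rep(1, 5), runif(5)), "variance")
})

test_that("offset search agrees with a fine-grid oracle and is rotation invariant", {
  set.seed(7)
  x <- runif(80)
  phi <- wrap_2pi(-5 * x + 1 + rnorm(80, 0, 0.4))
  prod_r <- single_cell_precession(x, phi)
  oracle <- fine_grid_min_cor(x, phi)
  expect_lt(abs(prod_r$rho - oracle$rho), 0.01)
  for (rot in c(0.7, 2.1, 4.4)) {
    r_rot <- single_cell_precession(x, wrap_2pi(phi + rot))
    expect_lt(abs(r_rot$rho - prod_r$rho), 0.01)
  }
  # the optimized rho is never weaker than the zero-offset correlation
  expect_lte(prod_r$rho, cor(x, phi) + 1e-12)
})

test_that("population metric reduces to the single-cell metric and dies under mispairing", {
  set.seed(3)
  x <- runif(60, 0, 1)
  phi <- wrap_2pi(-5 * x + 2 + rnorm(60, 0, 0.3))
  single <- single_cell_precession(x, phi)
  pop <- population_precession(x - 0.5, phi)  # distance from one shared center
  expect_equal(pop$rho, single$rho, tolerance = 1e-9)
  # two clean non-overlapping cells with consistent offsets pool coherently
  x2 <- c(x, x + 2)
  centers <- rep(c(0.5, 2.5), each = 60)
  pop2 <- population_precession(x2 - centers, c(phi, phi))
  expect_lt(pop2$rho, -0.8)
  # randomized cell-center pairing destroys the pooled correlation
  set.seed(4)
  centers_shuffled <- sample(centers)
  pop3 <- population_precession(x2 - centers_shuffled, c(phi, phi))
  expect_gt(pop3$rho, -0.35)
})

test_that("theta-sequence score is +1 for ideal sequences, -1 reversed, ~0 shuffled", {
  d <- make_compressed_sequences(jitter_s = 0)
  s <- theta_sequence_score(d$time_s, d$center_m, d$cell_id, f_theta = 8)
  expect_equal(s$mean_rho, 1, tolerance = 1e-9)
  expect_true(all(s$per_cycle$rho > 0.999))
  dr <- make_compressed_sequences(jitter_s = 0, reversed = TRUE)
  sr <- theta_sequence_score(dr$time_s, dr$center_m, dr$cell_id, f_theta = 8)
  expect_equal(sr$mean_rho, -1, tolerance = 1e-9)
  set.seed(5)
  dsh <- make_compressed_sequences(n_cycles = 200, jitter_s = 0)
  dsh$center_m <- ave(dsh$center_m, floor(dsh$time_s * 8),
                      FUN = function(z) sample(z))
  ssh <- theta_sequence_score(dsh$time_s, dsh$center_m, dsh$cell_id, 8)
  expect_lt(abs(ssh$mean_rho), 0.1)
})

test_that("sequence score degrades monotonically along a jitter ladder", {
  jit <- c(0, 0.004, 0.008, 0.016, 0.032)
  scores <- sapply(jit, function(j) {
    d <- make_compressed_sequences(n_cycles = 120, jitter_s = j, seed = 11)
    theta_sequence_score(d$time_s, d$center_m, d$cell_id, 8)$mean_rho
  })
  expect_true(all(diff(scores) < 0))
})

test_that("sequence windows skip non-qualifying cycles", {
  # one cell only: no cycle qualifies
  d <- make_compressed_sequences(n_cells = 1, n_cycles = 10)
  expect_error(theta_sequence_score(d$time_s, d$center_m, d$cell_id, 8),
               "no qualifying")
  # cycles with fewer than 3 spikes are skipped, not zero-filled
  d2 <- make_compressed_sequences(n_cells = 8, n_cycles = 5)
  keep <- !(floor(d2$time_s * 8) == 2 & d2$cell_id > 2)  # thin cycle 2
  s <- theta_sequence_score(d2$time_s[keep], d2$center_m[keep],
                            d2$cell_id[keep], 8)
  expect_false(2 %in% s$per_cycle$cycle)
})

test_that("cycles precessed equals the winding number of synthetic ramps", {
  expect_equal(cycles_precessed(rep(1.2, 10)), 0L)
  for (k in 0:3) {
    # downward phase ramp: spikes arrive at progressively earlier pacemaker
    # phases, winding k full cycles over 40 spikes
    ph <- wrap_2pi(2 - (0:39) * (k * 2 * pi / 39))
    expect_equal(cycles_precessed(ph), k)
  }
  # regression (upward drift) counts negative
  ph_up <- wrap_2pi(1 + (0:39) * (2 * pi / 39))
  expect_equal(cycles_precessed(ph_up), -1L)
  expect_error(cycles_precessed(1), "2 spikes")
})

test_that("instantaneous frequency recovers stationary sinusoids and chirps", {
  fs <- 1000
  t <- seq(0, 12, by = 1 / fs)
  for (f0 in c(8, 9)) {
    ft <- instantaneous_theta_frequency(sin(2 * pi * f0 * t), fs)
    expect_lt(max(abs(ft$freq_hz - f0)), 0.01)
  }
  # unbiased across the band
  for (f0 in c(6.5, 7.5, 8.5, 9.5)) {
    ft <- instantaneous_theta_frequency(sin(2 * pi * f0 * t), fs)
    expect_lt(abs(mean(ft$freq_hz) - f0), 0.02)
  }
  # linear chirp 7 -> 10 Hz over 10 s
  tc <- seq(0, 10, by = 1 / fs)
  finst <- 7 + 0.3 * tc
  chirp <- sin(2 * pi * (7 * tc + 0.15 * tc^2))
  ft <- instantaneous_theta_frequency(chirp, fs)
  mid <- ft$time_s > 2 & ft$time_s < 8
  expect_lt(max(abs(ft$freq_hz[mid] - (7 + 0.3 * ft$time_s[mid]))), 0.1)
  expect_gt(cor(ft$time_s[mid], ft$freq_hz[mid]), 0.99)
  expect_error(instantaneous_theta_frequency(sin(2 * pi * 8 * t[1:500]), fs),
               "transient")
})

test_that("per-lap frequency averaging applies the variability exclusion rule", {
  mk_lap <- function(freqs) data.frame(time_s = seq_along(freqs) / 1000,
                                       freq_hz = freqs,
                                       x_m = seq(-0.3, 0.3,
                                                 length.out = length(freqs)))
  clean <- replicate(5, mk_lap(rep(8.5, 600) + rnorm(600, 0, 0.05)),
                     simplify = FALSE)
  lp <- lap_precession_frequency(clean, xc_m = 0)
  expect_false(any(lp$excluded))
  expect_equal(lp$mean_freq_hz, rep(8.5, 5), tolerance = 0.05)
  # inject one high-variance lap
  set.seed(2)
  noisy <- c(clean, list(mk_lap(rep(8.5, 600) + rnorm(600, 0, 1.5))))
  lp2 <- lap_precession_frequency(noisy, xc_m = 0)
  expect_true(lp2$excluded[6])
  expect_false(any(lp2$excluded[1:5]))
  off <- list(mk_lap(rep(8, 100)))
  off[[1]]$x_m <- off[[1]]$x_m + 10
  expect_error(lap_precession_frequency(off, xc_m = 0), "empty window")
})

test_that("binned circular phase comparison recovers known shifts", {
  set.seed(6)
  x <- runif(400, 0, 1)
  phi <- wrap_2pi(-4 * x + 1 + rnorm(400, 0, 0.3))
  same <- binned_phase_shift(x, phi, x, phi, field_extent = c(0, 1))
  expect_equal(same$shift, rep(0, 5))
  shifted <- binned_phase_shift(x, phi, x, wrap_2pi(phi + pi / 6),
                                field_extent = c(0, 1))
  expect_equal(shifted$shift, rep(pi / 6, 5), tolerance = 1e-9)
  # missing bins are flagged, not fabricated
  xm <- x[x < 0.55]
  miss <- binned_phase_shift(x, phi, xm, phi[x < 0.55],
                             field_extent = c(0, 1))
  expect_true(any(is.na(miss$mean_perturbed)))
  expect_equal(miss$n_perturbed[5], 0L)
})

test_that("circular means from von Mises samples fall within 2 SE of truth", {
  set.seed(9)
  hits <- replicate(200, {
    mu <- runif(1, 0, 2 * pi)
    smp <- rvonmises(60, mu, kappa = 4)
    abs(wrap_pi(circ_mean(smp) - mu)) <= 2 * circ_se(smp)
  })
  expect_gte(mean(hits), 0.95 - 0.03)  # binomial slack at 200 repeats
})
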