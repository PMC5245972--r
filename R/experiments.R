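# Experiment drivers: reproduce the study's simulation protocols at desk
# scale, wiring the simulator to the analysis metrics.  Every experiment is
# deterministic given its seed (per-lap seeds are base_seed + lap index).

.experiment_result <- function(name, config, tables) {
  structure(list(experiment = name, config = config, tables = tables),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s>\n  tables: %s\n", x$experiment,
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

# Build the standard minimal pair (one place cell, one interneuron) at a
# given running speed; the lap spans +/- halfwin_sigma place-field widths
# around the field center at x = 0.
.pair_setup <- function(v_cms, IE_pA = NULL, sigma_cm = 40, halfwin_sigma = 3,
                        lateral_cm = 0, wE_nS = 0.5,
                        I0I_pA = NULL, Itheta_pA = NULL, sigma_nE_mV = NULL,
                        sigma_nI_mV = 0) {
  sp <- speed_params(v_cms)
  if (is.null(IE_pA)) IE_pA <- sp$IE_pA
  if (is.null(I0I_pA)) I0I_pA <- sp$I0I_pA
  if (is.null(Itheta_pA)) Itheta_pA <- sp$Itheta_pA
  if (is.null(sigma_nE_mV)) sigma_nE_mV <- sp$sigma_nE_mV
  halfwin <- halfwin_sigma * sigma_cm
  list(net = network_config(1, 1, wE_nS = wE_nS),
       lif_pyr = default_lif_params("pyramidal", sigma_n_mV = sigma_nE_mV),
       lif_int = default_lif_params("interneuron", sigma_n_mV = sigma_nI_mV),
       drives = drive_set(I0I_pA, Itheta_pA, IE_pA = IE_pA, xc_cm = 0,
                          sigma_cm = sigma_cm, x0_cm = -halfwin, v_cms = v_cms,
                          lateral_cm = lateral_cm),
       T = 2 * halfwin / v_cms)
}

#' Interneuron phase advance across the place field
#'
#' Unwraps the interneuron's spike phases relative to the pacemaker between
#' the first and last pyramidal spike of a lap and reports the total
#' advance (positive for precession) and its rounding to whole cycles.
#'
#' @param sim A `sim_result` from a pair (or larger) simulation.
#' @param int_id Interneuron index.
#' @param window Optional `c(t0, t1)` window (s); default first-to-last
#'   pooled pyramidal spike.
#' @return List with `advance_deg`, `cycles`, `n_spikes`, `window`.
#' @export
field_phase_advance <- function(sim, int_id = 1L, window = NULL) {
  f_theta <- sim$drives$f_theta
  resets <- if (is.finite(sim$reset_time)) sim$reset_time else numeric(0)
  if (is.null(window)) {
    pyr <- sim$spikes$spike_time_s[sim$spikes$cell_type == "pyramidal"]
    if (length(pyr) < 2)
      return(list(advance_deg = NA_real_, cycles = NA_integer_,
                  n_spikes = length(pyr), window = c(NA_real_, NA_real_)))
    window <- range(pyr)
  }
  st <- spike_times(sim, "interneuron", int_id)
  st <- st[st >= window[1] & st <= window[2]]
  if (length(st) < 2)
    return(list(advance_deg = NA_real_, cycles = NA_integer_,
                n_spikes = length(st), window = window))
  ph <- spike_phases(st, f_theta, resets)
  adv <- -sum(wrap_pi(diff(ph)))
  list(advance_deg = adv * 180 / pi, cycles = cycles_precessed(ph),
       n_spikes = length(st), window = window)
}

#' Minimal pair experiment
#'
#' Simulates the two-cell circuit (place cell + interneuron) over seeded
#' laps at one running speed. Reports per lap: the pyramidal spike count,
#' the maximum number of pyramidal spikes in one theta cycle, and the
#' interneuron's phase advance across the field; plus the interneuron's
#' out-of-field entrainment (rate and circular spike-phase statistics
#' before field entry).
#'
#' @param v_cms Running speed (cm/s), default 40.
#' @param n_laps Number of laps, default 20.
#' @param seed Base seed; lap i uses `seed + i`.
#' @param ... Overrides passed to the pair setup (`IE_pA`, `sigma_cm`,
#'   `halfwin_sigma`, `lateral_cm`, ...).
#' @return An `experiment_result` with tables `laps` and `entrainment`.
#' @export
run_minimal_pair <- function(v_cms = 40, n_laps = 20, seed = 1L, ...) {
  cfg <- .pair_setup(v_cms, ...)
  f_theta <- cfg$drives$f_theta
  pre_end <- (abs(cfg$drives$x0) / 1e-2 - 2 * cfg$drives$sigma / 1e-2) /
    v_cms  # time at which x reaches -2 sigma
  laps <- list(); ent <- list()
  for (i in seq_len(n_laps)) {
    sim <- simulate(cfg$net, cfg$lif_pyr, cfg$lif_int, cfg$drives,
                    T = cfg$T, seed = seed + i, record_every = 100000L)
    adv <- field_phase_advance(sim)
    pyr <- spike_times(sim, "pyramidal")
    max_per_cycle <- if (length(pyr)) max(tabulate(floor(pyr * f_theta) + 1))
                     else 0L
    laps[[i]] <- data.frame(lap = i, pyr_spikes = length(pyr),
                            max_spikes_per_cycle = max_per_cycle,
                            advance_deg = adv$advance_deg,
                            cycles = adv$cycles)
    ist <- spike_times(sim, "interneuron")
    ist <- ist[ist > 0.3 & ist < pre_end]
    ph <- spike_phases(ist, f_theta)
    ent[[i]] <- data.frame(lap = i, rate_hz = length(ist) / (pre_end - 0.3),
                           phase_mean_deg = circ_mean(ph) * 180 / pi,
                           phase_sd_deg = circ_sd(ph) * 180 / pi)
  }
  laps <- do.call(rbind, laps)
  tab <- table(factor(laps$cycles, levels = 0:5))
  .experiment_result("minimal_pair",
    list(v_cms = v_cms, n_laps = n_laps, seed = seed),
    list(laps = laps, entrainment = do.call(rbind, ent),
         summary = data.frame(
           modal_cycles = as.integer(names(which.max(tab))),
           mean_advance_deg = mean(laps$advance_deg, na.rm = TRUE),
           mean_pyr_spikes = mean(laps$pyr_spikes))))
}

#' Interneuron firing rate with the place cell inactive
#'
#' Simulates the interneuron under the tonic + pacemaker drive alone
#' (place-field drive disabled) and reports the mean firing rate after a
#' transient, i.e. the out-of-field steady state.
#'
#' @param v_cms Running speed determining the drives (cm/s).
#' @param T_measure_s Measurement duration after the transient (s).
#' @param transient_s Discarded initial transient (s).
#' @param seed RNG seed (the interneuron is noiseless by default, so this
#'   only matters if noise is added).
#' @return List with `rate_hz`, `phase_mean_deg`, `phase_sd_deg`.
#' @export
run_interneuron_baseline <- function(v_cms = 40, T_measure_s = 10,
                                     transient_s = 2, seed = 1L) {
  sp <- speed_params(v_cms)
  net <- network_config(1, 1)
  dr <- drive_set(sp$I0I_pA, sp$Itheta_pA, IE_pA = 0, xc_cm = 0)
  sim <- simulate(net, default_lif_params("pyramidal"),
                  default_lif_params("interneuron"), dr,
                  T = transient_s + T_measure_s, seed = seed,
                  record_every = 100000L)
  st <- spike_times(sim, "interneuron")
  st <- st[st > transient_s]
  ph <- spike_phases(st, dr$f_theta)
  list(rate_hz = length(st) / T_measure_s,
       phase_mean_deg = circ_mean(ph) * 180 / pi,
       phase_sd_deg = circ_sd(ph) * 180 / pi)
}

#' Locking phase across a tonic-current sweep
#'
#' The dorsoventral-gradient protocol: interneurons driven by the same
#' pacemaker but different tonic currents; each simulation reports the
#' steady-state mean spike phase, the rate, and whether the cell is locked
#' 1:1 to the pacemaker.
#'
#' @param I0I_grid_pA Tonic currents to sweep (pA).
#' @param Itheta_pA Pacemaker amplitude (pA).
#' @param T_s Simulation length (s); the last `measure_s` seconds are
#'   analyzed.
#' @param measure_s Measurement window (s).
#' @param seed RNG seed.
#' @return Data frame `I0I_pA`, `rate_hz`, `phase_deg`, `resultant`,
#'   `locked`.
#' @export
locking_phase_sweep <- function(I0I_grid_pA, Itheta_pA, T_s = 60,
                                measure_s = 10, seed = 1L) {
  net <- network_config(1, 1)
  lifE <- default_lif_params("pyramidal")
  lifI <- default_lif_params("interneuron")
  rows <- lapply(I0I_grid_pA, function(I0I) {
    dr <- drive_set(I0I, Itheta_pA, IE_pA = 0, xc_cm = 0)
    sim <- simulate(net, lifE, lifI, dr, T = T_s, seed = seed,
                    record_every = 10000000L)
    st <- spike_times(sim, "interneuron")
    st <- st[st > T_s - measure_s]
    ph <- spike_phases(st, dr$f_theta)
    rate <- length(st) / measure_s
    R <- circ_r(ph)
    data.frame(I0I_pA = I0I, rate_hz = rate,
               phase_deg = circ_mean(ph) * 180 / pi, resultant = R,
               locked = R > 0.9999 & abs(rate - dr$f_theta) < 0.005)
  })
  do.call(rbind, rows)
}

#' Angular span of stable locking phases of the LIF interneuron
#'
#' Locates the two saddle-node edges of the locking region by bisection on
#' the tonic current (long simulations are used near the edges, where
#' critical slowing makes settling slow) and returns the circular span
#' between the edge locking phases.
#'
#' @param Itheta_pA Pacemaker amplitude (pA).
#' @param bracket_pA `c(lo, hi)` currents bracketing the locking region
#'   (lo and hi must be outside it).
#' @param T_s Simulation length per probe (s).
#' @param tol_pA Bisection tolerance (pA).
#' @param seed RNG seed.
#' @return List with `edges_pA`, `edge_phases_deg`, `span_deg`.
#' @export
locking_span <- function(Itheta_pA, bracket_pA = c(77.5, 82), T_s = 150,
                         tol_pA = 2e-3, seed = 1L) {
  probe <- function(I0I) {
    r <- locking_phase_sweep(I0I, Itheta_pA, T_s = T_s, measure_s = 20,
                             seed = seed)
    list(locked = r$locked, phase = r$phase_deg)
  }
  mid0 <- mean(bracket_pA)
  stopifnot(probe(mid0)$locked)
  bisect <- function(inside, outside) {
    for (k in 1:40) {
      if (abs(inside - outside) < tol_pA) break
      mid <- (inside + outside) / 2
      if (probe(mid)$locked) inside <- mid else outside <- mid
    }
    inside
  }
  lo <- bisect(mid0, bracket_pA[1])
  hi <- bisect(mid0, bracket_pA[2])
  p_lo <- probe(lo)$phase
  p_hi <- probe(hi)$phase
  # phase decreases monotonically with current; travel from p_lo to p_hi
  # going downward through the wrap
  span <- (p_lo - p_hi) %% 360
  list(edges_pA = c(lo, hi), edge_phases_deg = c(p_lo, p_hi),
       span_deg = span)
}

#' Dorsoventral experiment
#'
#' (a) Locking phase as a function of tonic current with the place cell
#' silent; (b) dorsal- and ventral-pole pair simulations: out-of-field
#' locking phases (and their circular separation) and the phase advance
#' over each pole's place field.
#'
#' @param seed Base seed.
#' @param n_laps Laps per pole for the advance measurement.
#' @param sweep_grid_pA Currents for the locking sweep (pA).
#' @param refine_span Also run the bisection-based [locking_span()]
#'   (slower, precise).
#' @return An `experiment_result` with tables `sweep`, `poles`,
#'   `pole_laps` and optionally `span`.
#' @export
run_dorsoventral <- function(seed = 1L, n_laps = 5,
                             sweep_grid_pA = seq(78.6, 80.6, by = 0.2),
                             refine_span = FALSE) {
  dv <- lapply(c(dorsal = "dorsal", ventral = "ventral"), dorsoventral_params)
  sweep <- locking_phase_sweep(sweep_grid_pA, Itheta_pA = dv$dorsal$Itheta_pA,
                               seed = seed)
  poles <- list(); pole_laps <- list()
  for (pole in names(dv)) {
    p <- dv[[pole]]
    # out-of-field locking phase
    base <- locking_phase_sweep(p$I0I_pA, p$Itheta_pA, T_s = 120,
                                measure_s = 20, seed = seed)
    poles[[pole]] <- data.frame(pole = pole, I0I_pA = p$I0I_pA,
                                Itheta_pA = p$Itheta_pA,
                                phase_deg = base$phase_deg,
                                rate_hz = base$rate_hz, locked = base$locked)
    cfg <- .pair_setup(p$v_cms, sigma_cm = p$sigma_cm, wE_nS = p$wE_nS,
                       I0I_pA = p$I0I_pA, Itheta_pA = p$Itheta_pA,
                       sigma_nE_mV = p$sigma_nE_mV)
    for (i in seq_len(n_laps)) {
      sim <- simulate(cfg$net, cfg$lif_pyr, cfg$lif_int, cfg$drives,
                      T = cfg$T, seed = seed + i, record_every = 100000L)
      adv <- field_phase_advance(sim)
      pyr <- spike_times(sim, "pyramidal")
      ext <- if (length(pyr) >= 2) diff(range(pyr)) * p$v_cms / 100 else NA
      pole_laps[[paste(pole, i)]] <- data.frame(
        pole = pole, lap = i, pyr_spikes = length(pyr),
        advance_deg = adv$advance_deg, cycles = adv$cycles,
        field_extent_m = ext)
    }
  }
  poles <- do.call(rbind, poles)
  sep <- abs(poles$phase_deg[1] - poles$phase_deg[2]) %% 360
  sep <- min(sep, 360 - sep)
  tables <- list(sweep = sweep, poles = poles,
                 pole_laps = do.call(rbind, pole_laps),
                 separation_deg = sep)
  if (refine_span)
    tables$span <- locking_span(dv$dorsal$Itheta_pA, seed = seed)
  .experiment_result("dorsoventral", list(seed = seed, n_laps = n_laps),
                     tables)
}

#' Envelope-amplitude sweep
#'
#' Sweeps the place-field drive amplitude; for each amplitude, seeded laps
#' give the distribution of interneuron cycles-precessed and the place-cell
#' spike count, plus the re-binning of cycle probabilities by spike count.
#'
#' @param IE_grid_pA Envelope amplitudes (pA).
#' @param n_trials Laps per amplitude.
#' @param v_cms Running speed (cm/s).
#' @param lateral_cm Lateral offset of the pass (14 for the edge-pass
#'   protocol).
#' @param seed Base seed.
#' @return An `experiment_result` with tables `trials`, `by_amplitude`,
#'   `by_spike_count`.
#' @export
run_envelope_sweep <- function(IE_grid_pA = seq(110, 250, by = 10),
                               n_trials = 100, v_cms = 40, lateral_cm = 0,
                               seed = 1L) {
  trials <- list()
  for (a in seq_along(IE_grid_pA)) {
    cfg <- .pair_setup(v_cms, IE_pA = IE_grid_pA[a], lateral_cm = lateral_cm)
    for (i in seq_len(n_trials)) {
      sim <- simulate(cfg$net, cfg$lif_pyr, cfg$lif_int, cfg$drives,
                      T = cfg$T, seed = seed + (a - 1) * n_trials + i,
                      record_every = 1000000L)
      adv <- field_phase_advance(sim)
      trials[[length(trials) + 1]] <- data.frame(
        IE_pA = IE_grid_pA[a], trial = i,
        pyr_spikes = sum(sim$spikes$cell_type == "pyramidal"),
        advance_deg = adv$advance_deg,
        cycles = ifelse(is.na(adv$cycles), 0L, adv$cycles))
    }
  }
  trials <- do.call(rbind, trials)
  summarize_cycles <- function(d) {
    tab <- table(factor(pmax(pmin(d$cycles, 3), 0), levels = 0:3))
    data.frame(n = nrow(d), mean_spikes = mean(d$pyr_spikes),
               sd_spikes = stats::sd(d$pyr_spikes),
               p0 = as.numeric(tab[1] / nrow(d)),
               p1 = as.numeric(tab[2] / nrow(d)),
               p2 = as.numeric(tab[3] / nrow(d)),
               p3 = as.numeric(tab[4] / nrow(d)),
               modal_cycles = as.integer(names(which.max(tab))))
  }
  by_amp <- do.call(rbind, lapply(split(trials, trials$IE_pA), function(d)
    cbind(data.frame(IE_pA = d$IE_pA[1]), summarize_cycles(d))))
  sc_bins <- seq(0, max(trials$pyr_spikes) + 5, by = 5)
  trials$spike_bin <- cut(trials$pyr_spikes, sc_bins, include.lowest = TRUE)
  by_sc <- do.call(rbind, lapply(split(trials, trials$spike_bin), function(d)
    if (nrow(d)) cbind(data.frame(spike_bin = as.character(d$spike_bin[1])),
                       summarize_cycles(d))))
  .experiment_result("envelope_sweep",
    list(IE_grid_pA = IE_grid_pA, n_trials = n_trials, v_cms = v_cms,
         lateral_cm = lateral_cm, seed = seed),
    list(trials = trials, by_amplitude = by_amp, by_spike_count = by_sc))
}

#' Two place cells sharing one interneuron
#'
#' Two pyramidal cells with temporally separated fields couple to the same
#' interneuron; the interneuron should precess about one cycle in each
#' field, and each inactive cell's membrane theta oscillation should speed
#' up (subthreshold precession) while its partner drives the interneuron.
#'
#' @param v_cms Running speed (cm/s).
#' @param sep_cm Separation between the two field centers (cm).
#' @param seed RNG seed.
#' @param overlapping If `TRUE`, both fields share one center (the
#'   disruption scenario).
#' @return An `experiment_result` with tables `fields` (per-field advance)
#'   and `membrane` (per-cell in-field / out-field membrane theta
#'   frequency).
#' @export
run_two_cells <- function(v_cms = 40, sep_cm = 160, seed = 1L,
                          overlapping = FALSE) {
  sp <- speed_params(v_cms)
  sigma_cm <- 40
  xc <- if (overlapping) c(0, 0) else c(0, sep_cm)
  halfwin <- 3 * sigma_cm
  x0 <- -halfwin
  T <- (max(xc) + halfwin - x0) / v_cms
  net <- network_config(2, 1)
  dr <- drive_set(sp$I0I_pA, sp$Itheta_pA, IE_pA = sp$IE_pA, xc_cm = xc,
                  sigma_cm = sigma_cm, x0_cm = x0, v_cms = v_cms)
  sim <- simulate(net, default_lif_params("pyramidal", sp$sigma_nE_mV),
                  default_lif_params("interneuron"), dr, T = T,
                  seed = seed, record_pyr = 1:2, record_int = 1L,
                  record_every = 10L)
  fs <- 1 / (sim$dt * sim$record_every)
  f_theta <- dr$f_theta
  fields <- lapply(1:2, function(k) {
    st <- spike_times(sim, "pyramidal", k)
    if (length(st) < 2) return(data.frame(cell = k, advance_deg = NA,
                                          cycles = NA, n_spikes = length(st)))
    adv <- field_phase_advance(sim, window = range(st))
    data.frame(cell = k, advance_deg = adv$advance_deg, cycles = adv$cycles,
               n_spikes = length(st))
  })
  # membrane theta frequency of each cell inside its own vs its partner's field
  Vth <- default_lif_params("pyramidal")$V_theta
  mem <- lapply(1:2, function(k) {
    ft <- instantaneous_theta_frequency(sim$v_pyr[, k], fs, clip = Vth)
    x_cm <- (dr$x0 + dr$v * ft$time_s) / 1e-2
    in_own <- abs(x_cm - xc[k]) < sigma_cm
    in_partner <- abs(x_cm - xc[3 - k]) < sigma_cm
    out <- !(abs(x_cm - xc[1]) < 2 * sigma_cm |
             abs(x_cm - xc[2]) < 2 * sigma_cm)
    data.frame(cell = k,
               freq_own_field = mean(ft$freq_hz[in_own]),
               freq_partner_field = mean(ft$freq_hz[in_partner]),
               freq_out_field = mean(ft$freq_hz[out]))
  })
  .experiment_result("two_cells",
    list(v_cms = v_cms, sep_cm = sep_cm, seed = seed,
         overlapping = overlapping),
    list(fields = do.call(rbind, fields), membrane = do.call(rbind, mem)))
}

#' Speed sweep of the precession frequency
#'
#' For each running speed, simulates seeded laps of the minimal pair,
#' estimates the place cell's instantaneous membrane theta frequency, and
#' averages it within 15 cm of the field center per lap, applying the
#' variability-based exclusion rule per speed. A linear trend of included
#' per-lap frequencies against speed is reported.
#'
#' @param speeds_cms Running speeds (cm/s).
#' @param n_laps Laps per speed.
#' @param seed Base seed.
#' @return An `experiment_result` with tables `laps` (per-lap estimates
#'   with exclusion flags) and `trend` (slope, intercept).
#' @export
run_speed_sweep <- function(speeds_cms = c(15, 25, 35, 45, 55, 65),
                            n_laps = 20, seed = 1L) {
  Vth <- default_lif_params("pyramidal")$V_theta
  all_rows <- list()
  for (si in seq_along(speeds_cms)) {
    v <- speeds_cms[si]
    cfg <- .pair_setup(v)
    lap_traces <- list()
    for (i in seq_len(n_laps)) {
      sim <- simulate(cfg$net, cfg$lif_pyr, cfg$lif_int, cfg$drives,
                      T = cfg$T, seed = seed + (si - 1) * n_laps + i,
                      record_pyr = 1L, record_int = integer(0),
                      record_every = 10L)
      fs <- 1 / (sim$dt * sim$record_every)
      ft <- instantaneous_theta_frequency(sim$v_pyr[, 1], fs, clip = Vth)
      lap_traces[[i]] <- data.frame(
        time_s = ft$time_s, freq_hz = ft$freq_hz,
        x_m = cfg$drives$x0 + cfg$drives$v * ft$time_s)
    }
    lp <- lap_precession_frequency(lap_traces, xc_m = 0)
    lp$v_cms <- v
    all_rows[[si]] <- lp
  }
  laps <- do.call(rbind, all_rows)
  inc <- laps[!laps$excluded, ]
  fit <- stats::lm(mean_freq_hz ~ v_cms, data = inc)
  .experiment_result("speed_sweep",
    list(speeds_cms = speeds_cms, n_laps = n_laps, seed = seed),
    list(laps = laps,
         trend = data.frame(slope_hz_per_cms = stats::coef(fit)[2],
                            intercept_hz = stats::coef(fit)[1],
                            n_included = nrow(inc),
                            n_excluded = sum(laps$excluded))))
}

# ---- network-scale experiments ----------------------------------------

# Simulate one lap of a mapped network along a linear track and compute the
# three metrics.  Returns a one-row data frame.
.network_lap <- function(map, v_cms, seed, wE_nS = 0.5, wI_nS = 25,
                         sigma_cm = 40, sigma_nI_mV = 0,
                         sigma_nE_mV = NULL, min_spikes_cell = 5) {
  sp <- speed_params(v_cms)
  if (is.null(sigma_nE_mV)) sigma_nE_mV <- sp$sigma_nE_mV
  n_pyr <- length(map$bins)
  n_int <- max(map$interneuron)
  xc_cm <- map_centers_m(map) / 1e-2
  halfwin <- 3 * sigma_cm
  x0 <- -halfwin
  L_cm <- map$track$L / 1e-2
  T <- (L_cm + halfwin - x0) / v_cms
  net <- network_config(n_pyr, n_int, wE_nS = wE_nS, wI_nS = wI_nS,
                        pyr2int = map$interneuron)
  dr <- drive_set(sp$I0I_pA, sp$Itheta_pA, IE_pA = sp$IE_pA, xc_cm = xc_cm,
                  sigma_cm = sigma_cm, x0_cm = x0, v_cms = v_cms)
  sim <- simulate(net, default_lif_params("pyramidal", sigma_nE_mV),
                  default_lif_params("interneuron", sigma_nI_mV), dr,
                  T = T, seed = seed, record_pyr = integer(0),
                  record_int = integer(0), record_every = 1000000L)
  sp_df <- sim$spikes[sim$spikes$cell_type == "pyramidal", ]
  if (nrow(sp_df) < 10)
    return(data.frame(pop_rho = NA, pop_offset = NA, seq_rho = NA,
                      n_cycles = 0, single_rho = NA, n_cells_used = 0,
                      n_spikes = nrow(sp_df)))
  phi <- spike_phases(sp_df$spike_time_s, dr$f_theta)
  x_m <- (x0 + v_cms * sp_df$spike_time_s) * 1e-2
  centers <- map_centers_m(map)[sp_df$cell_id]
  dist <- x_m - centers
  pop <- population_precession(dist, phi)
  seq_sc <- tryCatch(
    theta_sequence_score(sp_df$spike_time_s, centers, sp_df$cell_id,
                         dr$f_theta, offset_pop = pop$offset),
    error = function(e) NULL)
  per_cell <- vapply(split(seq_len(nrow(sp_df)), sp_df$cell_id),
    function(idx) {
      if (length(idx) < min_spikes_cell) return(NA_real_)
      if (stats::sd(x_m[idx]) == 0) return(NA_real_)
      single_cell_precession(x_m[idx], phi[idx])$rho
    }, numeric(1))
  data.frame(pop_rho = pop$rho, pop_offset = pop$offset,
             seq_rho = if (is.null(seq_sc)) NA else seq_sc$mean_rho,
             n_cycles = if (is.null(seq_sc)) 0 else nrow(seq_sc$per_cycle),
             single_rho = mean(per_cell, na.rm = TRUE),
             n_cells_used = sum(!is.na(per_cell)), n_spikes = nrow(sp_df))
}

#' Network density experiment
#'
#' Simulates mapped networks with a fixed number of pyramidal cells and a
#' varying number of active place cells per interneuron, for random and/or
#' optimal place-field maps, and reports the single-cycle theta-sequence
#' metric, the population phase-precession metric and the per-lap
#' single-cell metric at each density.
#'
#' @param n_pyr Number of pyramidal cells (all active), default 1000.
#' @param densities Active cells per interneuron (each must divide
#'   `n_pyr`).
#' @param map_types Subset of `c("random", "optimal")`.
#' @param n_repeats Fresh map instances (one lap each) per condition.
#' @param v_cms Running speed (cm/s).
#' @param L_m,x_res_m Track length and map resolution (m).
#' @param seed Base seed.
#' @return An `experiment_result` with tables `laps` and `by_density`.
#' @export
run_network_density <- function(n_pyr = 1000, densities = c(1, 2, 4, 8),
                                map_types = c("random", "optimal"),
                                n_repeats = 3, v_cms = 50, L_m = 5,
                                x_res_m = 0.1, seed = 1L) {
  track <- track_discretization(L_m, x_res_m)
  rows <- list()
  k <- 0
  for (dens in densities) {
    stopifnot(n_pyr %% dens == 0)
    n_int <- n_pyr / dens
    for (mt in map_types) {
      for (r in seq_len(n_repeats)) {
        k <- k + 1
        map <- if (mt == "random")
          random_map(n_pyr, n_int, track, seed = seed + 1000 + k)
        else optimal_map(n_pyr, n_int, track)
        res <- .network_lap(map, v_cms, seed = seed + k)
        rows[[k]] <- cbind(data.frame(density = dens, map_type = mt,
                                      repeat_i = r), res)
      }
    }
  }
  laps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(laps, interaction(laps$density, laps$map_type, drop = TRUE)),
    function(d) data.frame(
      density = d$density[1], map_type = d$map_type[1], n = nrow(d),
      mean_seq_rho = mean(d$seq_rho, na.rm = TRUE),
      sd_seq_rho = stats::sd(d$seq_rho),
      mean_pop_rho = mean(d$pop_rho, na.rm = TRUE),
      sd_pop_rho = stats::sd(d$pop_rho),
      mean_single_rho = mean(d$single_rho, na.rm = TRUE),
      sd_single_rho = stats::sd(d$single_rho))))
  .experiment_result("network_density",
    list(n_pyr = n_pyr, densities = densities, map_types = map_types,
         n_repeats = n_repeats, v_cms = v_cms, L_m = L_m, seed = seed),
    list(laps = laps, by_density = agg[order(agg$map_type, agg$density), ]))
}

#' Extraneous-noise sweep
#'
#' Varies the membrane noise amplitude of one population at a time in a
#' small mapped network and reports the three sequence/precession metrics
#' at each noise level.
#'
#' @param population `"pyramidal"` or `"interneuron"`.
#' @param sigma_grid_mV Noise amplitudes (mV; stationary SD).
#' @param n_pyr,n_int Network size (optimal map, density `n_pyr/n_int`).
#' @param n_laps Laps per level.
#' @param v_cms Running speed.
#' @param L_m Track length (m).
#' @param seed Base seed.
#' @return An `experiment_result` with tables `laps` and `by_level`.
#' @export
run_noise_sweep <- function(population = c("pyramidal", "interneuron"),
                            sigma_grid_mV = c(0, 0.5, 2, 4, 8), n_pyr = 32,
                            n_int = 32, n_laps = 5, v_cms = 50, L_m = 5,
                            seed = 1L) {
  population <- match.arg(population)
  track <- track_discretization(L_m, 0.1)
  map <- optimal_map(n_pyr, n_int, track)
  rows <- list()
  for (li in seq_along(sigma_grid_mV)) {
    s <- sigma_grid_mV[li]
    for (i in seq_len(n_laps)) {
      res <- .network_lap(
        map, v_cms, seed = seed + (li - 1) * n_laps + i,
        sigma_nE_mV = if (population == "pyramidal") s else NULL,
        sigma_nI_mV = if (population == "interneuron") s else 0)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(sigma_mV = s, lap = i, population = population), res)
    }
  }
  laps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(laps, laps$sigma_mV), function(d)
    data.frame(sigma_mV = d$sigma_mV[1], n = nrow(d),
               mean_seq_rho = mean(d$seq_rho, na.rm = TRUE),
               mean_pop_rho = mean(d$pop_rho, na.rm = TRUE),
               mean_single_rho = mean(d$single_rho, na.rm = TRUE))))
  .experiment_result("noise_sweep",
    list(population = population, sigma_grid_mV = sigma_grid_mV,
         n_pyr = n_pyr, n_int = n_int, n_laps = n_laps, v_cms = v_cms,
         seed = seed),
    list(laps = laps, by_level = agg[order(agg$sigma_mV), ]))
}

#' Perturbation experiments
#'
#' `"theta_reset"`: transient silencing of both cells (-50 pA to the place
#' cell, -20 pA to the interneuron, 200 ms centered on the field-input
#' peak) with a simultaneous pacemaker phase reset; phase precession should
#' resume after the perturbation. `"interneuron_silencing"`: a -10 pA, 1 s
#' current into the interneuron centered on the field (or on a random
#' location within a jitter window of the center, per lap); spike phases
#' are compared against unperturbed control laps in five spatial bins.
#'
#' @param protocol `"theta_reset"` or `"interneuron_silencing"`.
#' @param n_laps Laps (per condition for silencing).
#' @param v_cms Running speed.
#' @param jitter_cm Half-width of the uniform silencing-center jitter (cm);
#'   0 centers every lap on the field.
#' @param seed Base seed.
#' @return An `experiment_result`; tables depend on the protocol.
#' @export
run_perturbations <- function(protocol = c("theta_reset",
                                           "interneuron_silencing"),
                              n_laps = 20, v_cms = 40, jitter_cm = 0,
                              seed = 1L) {
  protocol <- match.arg(protocol)
  cfg <- .pair_setup(v_cms)
  t_center <- abs(cfg$drives$x0 / 1e-2) / v_cms  # crossing time of x = 0
  f_theta <- cfg$drives$f_theta
  if (protocol == "theta_reset") {
    rows <- list()
    for (i in seq_len(n_laps)) {
      pert <- perturbation_protocol(amp_pyr_pA = -50, amp_int_pA = -20,
                                    onset_s = t_center - 0.1,
                                    duration_s = 0.2, pacemaker_reset = TRUE)
      sim <- simulate(cfg$net, cfg$lif_pyr, cfg$lif_int, cfg$drives,
                      perturb = pert, T = cfg$T, seed = seed + i,
                      record_every = 1000000L)
      all_sp <- sim$spikes$spike_time_s
      w <- c(pert$onset, pert$onset + pert$duration)
      silenced <- sum(all_sp >= w[1] & all_sp < w[2]) == 0
      post <- field_phase_advance(sim, window = c(w[2], cfg$T))
      pyr_post <- spike_times(sim, "pyramidal")
      pyr_post <- pyr_post[pyr_post > w[2]]
      rows[[i]] <- data.frame(lap = i, silenced_in_window = silenced,
                              pyr_spikes_post = length(pyr_post),
                              post_advance_deg = post$advance_deg)
    }
    return(.experiment_result("theta_reset",
      list(n_laps = n_laps, v_cms = v_cms, seed = seed),
      list(laps = do.call(rbind, rows))))
  }
  # interneuron silencing: paired control / silenced laps with shared seeds
  collect <- function(perturbed, i) {
    pert <- NULL
    if (perturbed) {
      jit_s <- if (jitter_cm > 0) {
        set.seed(seed + 700000 + i)
        stats::runif(1, -jitter_cm, jitter_cm) / v_cms
      } else 0
      pert <- perturbation_protocol(amp_int_pA = -10,
                                    onset_s = t_center - 0.5 + jit_s,
                                    duration_s = 1)
    }
    sim <- simulate(cfg$net, cfg$lif_pyr, cfg$lif_int, cfg$drives,
                    perturb = pert, T = cfg$T, seed = seed + i,
                    record_every = 1000000L)
    st <- spike_times(sim, "pyramidal")
    data.frame(lap = i, x_m = (cfg$drives$x0 + cfg$drives$v * st) ,
               phase = spike_phases(st, f_theta))
  }
  ctl <- do.call(rbind, lapply(seq_len(n_laps), function(i) collect(FALSE, i)))
  prt <- do.call(rbind, lapply(seq_len(n_laps), function(i) collect(TRUE, i)))
  extent <- range(ctl$x_m)
  bins <- binned_phase_shift(ctl$x_m, ctl$phase, prt$x_m, prt$phase,
                             field_extent = extent, n_bins = 5)
  .experiment_result("interneuron_silencing",
    list(n_laps = n_laps, v_cms = v_cms, jitter_cm = jitter_cm, seed = seed),
    list(control = ctl, perturbed = prt, bins = bins))
}

#' Pooled single-cell precession distributions
#'
#' For each mapping density, simulates repeated laps of a random-map
#' network and measures each cell's phase-position correlation from its
#' spikes pooled over all laps, giving the distribution of single-cell
#' precession strengths.
#'
#' @param n_pyr Number of pyramidal cells, default 200.
#' @param densities Active cells per interneuron.
#' @param n_laps Laps pooled per cell, default 30.
#' @param v_cms Running speed.
#' @param L_m Track length (m), default 5.
#' @param seed Base seed.
#' @return An `experiment_result` with tables `cells` (per cell, per
#'   density) and `by_density`.
#' @export
run_pooled_distribution <- function(n_pyr = 200, densities = c(1, 2, 5),
                                    n_laps = 30, v_cms = 50, L_m = 5,
                                    seed = 1L) {
  track <- track_discretization(L_m, 0.1)
  sigma_cm <- 40
  rows <- list(); cells_rows <- list()
  for (di in seq_along(densities)) {
    dens <- densities[di]
    stopifnot(n_pyr %% dens == 0)
    n_int <- n_pyr / dens
    map <- random_map(n_pyr, n_int, track, seed = seed + 5000 + di)
    sp_all <- list()
    for (i in seq_len(n_laps)) {
      spl <- .pooled_lap_spikes(map, v_cms, sigma_cm,
                                seed = seed + (di - 1) * n_laps + i)
      spl$lap <- i
      sp_all[[i]] <- spl
    }
    sp_all <- do.call(rbind, sp_all)
    per_cell <- vapply(seq_len(n_pyr), function(cid) {
      d <- sp_all[sp_all$cell_id == cid, ]
      if (nrow(d) < 5 || stats::sd(d$x_m) == 0) return(NA_real_)
      single_cell_precession(d$x_m, d$phase)$rho
    }, numeric(1))
    cells_rows[[di]] <- data.frame(density = dens, cell = seq_len(n_pyr),
                                   rho = per_cell)
    rows[[di]] <- data.frame(
      density = dens, n_cells = sum(!is.na(per_cell)),
      mean_rho = mean(per_cell, na.rm = TRUE),
      sd_rho = stats::sd(per_cell[!is.na(per_cell)]),
      frac_strong = mean(per_cell < -0.3, na.rm = TRUE))
  }
  .experiment_result("pooled_distribution",
    list(n_pyr = n_pyr, densities = densities, n_laps = n_laps,
         v_cms = v_cms, seed = seed),
    list(cells = do.call(rbind, cells_rows),
         by_density = do.call(rbind, rows)))
}

# one lap of a mapped network returning pooled pyramidal spikes
.pooled_lap_spikes <- function(map, v_cms, sigma_cm, seed) {
  sp <- speed_params(v_cms)
  n_pyr <- length(map$bins)
  n_int <- max(map$interneuron)
  xc_cm <- map_centers_m(map) / 1e-2
  halfwin <- 3 * sigma_cm
  x0 <- -halfwin
  T <- (map$track$L / 1e-2 + halfwin - x0) / v_cms
  net <- network_config(n_pyr, n_int, pyr2int = map$interneuron)
  dr <- drive_set(sp$I0I_pA, sp$Itheta_pA, IE_pA = sp$IE_pA, xc_cm = xc_cm,
                  sigma_cm = sigma_cm, x0_cm = x0, v_cms = v_cms)
  sim <- simulate(net, default_lif_params("pyramidal", sp$sigma_nE_mV),
                  default_lif_params("interneuron"), dr, T = T, seed = seed,
                  record_pyr = integer(0), record_int = integer(0),
                  record_every = 1000000L)
  d <- sim$spikes[sim$spikes$cell_type == "pyramidal", ]
  data.frame(cell_id = d$cell_id,
             x_m = (x0 + v_cms * d$spike_time_s) * 1e-2,
             phase = spike_phases(d$spike_time_s, dr$f_theta))
}
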