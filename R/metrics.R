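# Circular summary helpers (no circular-statistics package is installed;
# these are the standard resultant-based formulas).

#' Circular mean
#' @param x Angles (rad).
#' @return Mean direction in (-pi, pi].
#' @export
circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

#' Mean resultant length
#' @param x Angles (rad).
#' @return R-bar in [0, 1].
#' @export
circ_r <- function(x) sqrt(mean(sin(x))^2 + mean(cos(x))^2)

#' Circular standard deviation
#' @param x Angles (rad).
#' @return `sqrt(-2*log(Rbar))` (rad).
#' @export
circ_sd <- function(x) sqrt(-2 * log(pmax(circ_r(x), .Machine$double.eps)))

#' Circular standard error of the mean direction
#' @param x Angles (rad).
#' @return `circ_sd(x)/sqrt(n)` (rad).
#' @export
circ_se <- function(x) circ_sd(x) / sqrt(length(x))

#' Pacemaker phase at spike times
#'
#' Assigns each spike the phase of the pacemaker oscillation,
#' `2*pi*f_theta*(t - last_reset) mod 2*pi`, honoring any pacemaker resets
#' from perturbation protocols (phase zero at each reset and at t = 0).
#'
#' @param spike_times_s Spike times (s).
#' @param f_theta Pacemaker frequency (Hz).
#' @param reset_times_s Times at which the pacemaker phase was reset to 0.
#' @return Phases in `[0, 2*pi)`.
#' @export
spike_phases <- function(spike_times_s, f_theta, reset_times_s = numeric(0)) {
  if (!length(spike_times_s)) return(numeric(0))
  last_reset <- vapply(spike_times_s, function(t) {
    r <- reset_times_s[reset_times_s <= t]
    if (length(r)) max(r) else 0
  }, numeric(1))
  wrap_2pi(2 * pi * f_theta * (spike_times_s - last_reset))
}

# offset-minimized Pearson correlation between a linear covariate and
# wrapped phases; the shared core of the single-cell and population metrics
.offset_min_cor <- function(x, phi, grid_deg) {
  offsets <- seq(0, 2 * pi, by = grid_deg * pi / 180)
  offsets <- offsets[offsets < 2 * pi]
  phimat <- wrap_2pi(outer(phi, offsets, `+`))
  rhos <- as.numeric(stats::cor(x, phimat))
  i <- which.min(rhos)
  list(rho = rhos[i], offset = offsets[i])
}

#' Single-cell phase-precession metric
#'
#' Pearson correlation between spike positions and spike phases after
#' adding the phase offset that minimizes the correlation (i.e. yields the
#' most negative, strongest, phase-position relationship). The offset is
#' found by exhaustive grid search (default 1 degree steps); the phases are
#' wrapped to `[0, 2*pi)` after rotation and then treated as linear values.
#' Negative values near -1 indicate robust phase precession.
#'
#' @param x Spike positions (m), one per spike.
#' @param phi Spike phases (rad).
#' @param grid_deg Offset search resolution (degrees).
#' @return List with `rho` (minimized correlation) and `offset` (rad).
#' @export
single_cell_precession <- function(x, phi, grid_deg = 1) {
  stopifnot(length(x) == length(phi))
  if (length(x) < 3) stop("need at least 3 spikes")
  if (stats::sd(x) == 0) stop("zero variance in spike positions")
  .offset_min_cor(x, phi, grid_deg)
}

#' Population phase-precession metric
#'
#' The single-lap population metric: spikes of all cells are pooled, each
#' spike's covariate is the distance of the animal from the place-field
#' center of the cell that fired it, and the offset-minimized correlation
#' is computed exactly as in [single_cell_precession()].
#'
#' @param dist Signed distance of the animal from the firing cell's field
#'   center at each pooled spike (m).
#' @param phi Pooled spike phases (rad).
#' @param grid_deg Offset search resolution (degrees).
#' @return List with `rho` and `offset` (rad).
#' @export
population_precession <- function(dist, phi, grid_deg = 1) {
  stopifnot(length(dist) == length(phi))
  if (length(dist) < 3) stop("need at least 3 pooled spikes")
  if (stats::sd(dist) == 0) stop("zero variance in distances")
  .offset_min_cor(dist, phi, grid_deg)
}

#' Single-cycle theta-sequence metric
#'
#' Partitions a lap into windows one pacemaker period wide, offset by the
#' population phase offset, and within each qualifying cycle (at least
#' `min_spikes` spikes from at least `min_cells` distinct cells) computes
#' the Pearson correlation between spike times and the firing cells' place
#' field centers. Strong positive per-cycle correlations indicate theta
#' sequences that recapitulate the slow behavioral sequence.
#'
#' @param spike_times_s Pooled spike times (s).
#' @param centers_m Field center (m) of the cell firing each spike.
#' @param cell_id Cell identity of each spike.
#' @param f_theta Pacemaker frequency (Hz).
#' @param offset_pop Population phase offset (rad), from
#'   [population_precession()]; theta-window boundaries sit at
#'   `(k + offset_pop/2pi)/f_theta`.
#' @param min_spikes,min_cells Qualification thresholds per cycle.
#' @return List with `per_cycle` (data frame `cycle`, `n_spikes`, `n_cells`,
#'   `rho`) and `mean_rho`. Non-qualifying cycles are skipped, not
#'   zero-filled.
#' @export
theta_sequence_score <- function(spike_times_s, centers_m, cell_id, f_theta,
                                 offset_pop = 0, min_spikes = 3,
                                 min_cells = 2) {
  stopifnot(length(spike_times_s) == length(centers_m),
            length(spike_times_s) == length(cell_id))
  T_theta <- 1 / f_theta
  shift <- offset_pop / (2 * pi) * T_theta
  cyc <- floor((spike_times_s - shift) / T_theta)  # half-open windows
  rows <- lapply(split(seq_along(cyc), cyc), function(idx) {
    nc <- length(unique(cell_id[idx]))
    if (length(idx) < min_spikes || nc < min_cells) return(NULL)
    if (stats::sd(centers_m[idx]) == 0 || stats::sd(spike_times_s[idx]) == 0)
      return(NULL)
    data.frame(cycle = cyc[idx[1]], n_spikes = length(idx), n_cells = nc,
               rho = stats::cor(spike_times_s[idx], centers_m[idx]))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) stop("no qualifying theta cycles")
  list(per_cycle = rows, mean_rho = mean(rows$rho))
}

#' Integer cycles precessed over a field crossing
#'
#' Counts the winding number of a neuron's spiking relative to the
#' pacemaker across a window (conventionally the first-to-last place-cell
#' spike of the lap). Spike phases are unwrapped assuming less than half a
#' cycle of drift between consecutive spikes; precession (spikes moving to
#' progressively earlier pacemaker phases) counts positive.
#'
#' @param phases Pacemaker phases at the neuron's spikes within the window
#'   (rad, wrapped), at least 2 spikes.
#' @return `round(total phase advance / 2*pi)` (integer; negative for
#'   phase regression).
#' @export
cycles_precessed <- function(phases) {
  if (length(phases) < 2) stop("need at least 2 spikes in the window")
  advance <- -sum(wrap_pi(diff(phases)))
  as.integer(round(advance / (2 * pi)))
}

#' Binned circular spike-phase comparison between two conditions
#'
#' Splits the place field into `n_bins` equal spatial bins and reports the
#' circular mean spike phase (with circular standard error) per bin for a
#' control and a perturbed condition, plus the per-bin circular phase shift
#' (perturbed minus control, wrapped to `(-pi, pi]`). Bins lacking spikes in
#' a condition are reported as `NA`.
#'
#' @param x_control,phi_control Spike positions (m) and phases (rad),
#'   control condition.
#' @param x_perturbed,phi_perturbed Same for the perturbed condition.
#' @param field_extent Numeric `c(lo, hi)` (m) spanned by the bins.
#' @param n_bins Number of bins, default 5.
#' @return Data frame with one row per bin: `bin`, `x_lo`, `x_hi`,
#'   `mean_control`, `se_control`, `n_control`, `mean_perturbed`,
#'   `se_perturbed`, `n_perturbed`, `shift` (all angles in rad).
#' @export
binned_phase_shift <- function(x_control, phi_control, x_perturbed,
                               phi_perturbed, field_extent, n_bins = 5) {
  stopifnot(length(field_extent) == 2, field_extent[2] > field_extent[1])
  br <- seq(field_extent[1], field_extent[2], length.out = n_bins + 1)
  summarize <- function(x, phi) {
    b <- cut(x, br, include.lowest = TRUE, labels = FALSE)
    lapply(seq_len(n_bins), function(k) {
      p <- phi[!is.na(b) & b == k]
      if (!length(p)) list(mean = NA_real_, se = NA_real_, n = 0L)
      else list(mean = circ_mean(p), se = circ_se(p), n = length(p))
    })
  }
  ctl <- summarize(x_control, phi_control)
  prt <- summarize(x_perturbed, phi_perturbed)
  out <- data.frame(
    bin = seq_len(n_bins), x_lo = br[-(n_bins + 1)], x_hi = br[-1],
    mean_control = vapply(ctl, `[[`, numeric(1), "mean"),
    se_control = vapply(ctl, `[[`, numeric(1), "se"),
    n_control = vapply(ctl, `[[`, integer(1), "n"),
    mean_perturbed = vapply(prt, `[[`, numeric(1), "mean"),
    se_perturbed = vapply(prt, `[[`, numeric(1), "se"),
    n_perturbed = vapply(prt, `[[`, integer(1), "n")
  )
  out$shift <- wrap_pi(out$mean_perturbed - out$mean_control)
  out
}
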