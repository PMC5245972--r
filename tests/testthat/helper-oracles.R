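# Shared fixtures and independent oracles, all built in code.

# fine-grid (0.1 degree) offset-minimized correlation, deliberately written
# as a plain loop, independent of the production implementation
fine_grid_min_cor <- function(x, phi, step_deg = 0.1) {
  offs <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  best <- Inf; best_o <- NA
  for (o in offs) {
    r <- cor(x, (phi + o) %% (2 * pi))
    if (r < best) { best <- r; best_o <- o }
  }
  list(rho = best, offset = best_o)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# idealized compressed theta sequences: every cycle, each cell fires once,
# ordered by field center with uniform within-cycle lags plus timing jitter
make_compressed_sequences <- function(n_cells = 8, n_cycles = 30,
                                      f_theta = 8, jitter_s = 0,
                                      reversed = FALSE, seed = 1) {
  set.seed(seed)
  Tth <- 1 / f_theta
  centers <- seq_len(n_cells) * 0.5
  lag <- (seq_len(n_cells) - 0.5) / n_cells * 0.8 * Tth
  if (reversed) lag <- rev(lag)
  times <- as.vector(outer(lag, (seq_len(n_cycles) - 1) * Tth, `+`)) +
    rnorm(n_cells * n_cycles, 0, jitter_s)
  data.frame(time_s = times,
             cell_id = rep(seq_len(n_cells), n_cycles),
             center_m = rep(centers, n_cycles))
}

# standard pair configuration at one running speed (small helper mirroring
# the experiment drivers, for direct simulate() tests)
pair_sim <- function(v_cms = 40, IE_pA = NULL, seed = 1, T = NULL, ...) {
  sp <- speed_params(v_cms)
  if (is.null(IE_pA)) IE_pA <- sp$IE_pA
  halfwin <- 120
  dr <- drive_set(sp$I0I_pA, sp$Itheta_pA, IE_pA = IE_pA, xc_cm = 0,
                  sigma_cm = 40, x0_cm = -halfwin, v_cms = v_cms)
  if (is.null(T)) T <- 2 * halfwin / v_cms
  simulate(network_config(1, 1), default_lif_params("pyramidal", sp$sigma_nE_mV),
           default_lif_params("interneuron"), dr, T = T, seed = seed,
           record_every = 100000L, ...)
}
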