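# Unit conversions: user-facing arguments use the conventional units of the
# experimental literature (pA, mV, ms, cm, nS, pF); everything is stored and
# simulated in SI.
.pA <- 1e-12; .mV <- 1e-3; .ms <- 1e-3; .cm <- 1e-2; .nS <- 1e-9; .pF <- 1e-12

#' Leaky integrate-and-fire parameters
#'
#' Membrane and synaptic parameters of a conductance-based LIF neuron.
#' Arguments are in conventional units (ms, pF, mV); the returned object
#' stores SI values.
#'
#' @param tau_m_ms Membrane time constant (ms).
#' @param C_m_pF Membrane capacitance (pF).
#' @param E0_mV Resting potential (mV).
#' @param V_theta_mV Spike threshold (mV).
#' @param V_r_mV Reset potential (mV).
#' @param sigma_n_mV Membrane noise amplitude (mV). Under the default
#'   variance-preserving discretization this is the stationary standard
#'   deviation of the subthreshold voltage noise (per-step increment
#'   `sigma_n*sqrt(2*dt/tau_m)*eta`, standard-normal `eta`); the optional
#'   timestep-bound mode instead adds `(sigma_n/tau_m)*eta*dt`, tying the
#'   effective noise to the timestep.
#' @param E_E_mV,E_I_mV Excitatory / inhibitory reversal potentials (mV).
#' @param tau_E_ms,tau_I_ms Excitatory / inhibitory synaptic decay time
#'   constants (ms).
#' @return An object of class `lif_params` (SI fields).
#' @export
lif_params <- function(tau_m_ms, C_m_pF, E0_mV = -65, V_theta_mV = -50,
                       V_r_mV = -70, sigma_n_mV = 0, E_E_mV = 0, E_I_mV = -70,
                       tau_E_ms = 2, tau_I_ms = 10) {
  stopifnot(tau_m_ms > 0, C_m_pF > 0, tau_E_ms > 0, tau_I_ms > 0,
            sigma_n_mV >= 0, V_r_mV < V_theta_mV)
  structure(list(
    tau_m = tau_m_ms * .ms, C_m = C_m_pF * .pF, E0 = E0_mV * .mV,
    V_theta = V_theta_mV * .mV, V_r = V_r_mV * .mV, sigma_n = sigma_n_mV * .mV,
    E_E = E_E_mV * .mV, E_I = E_I_mV * .mV,
    tau_E = tau_E_ms * .ms, tau_I = tau_I_ms * .ms
  ), class = "lif_params")
}

#' Default neuron parameters for the two cell types
#'
#' Fixed, running-speed-independent parameters: interneurons have
#' tau_m = 40 ms and C_m = 200 pF; pyramidal cells tau_m = 20 ms and
#' C_m = 155 pF; both share V_theta = -50 mV, V_r = -70 mV, E0 = -65 mV,
#' tau_I = 10 ms, tau_E = 2 ms, E_I = -70 mV, E_E = 0 mV.
#'
#' @param type `"interneuron"` or `"pyramidal"`.
#' @param sigma_n_mV Noise amplitude (mV); defaults to 0 (place-cell noise
#'   is set by the speed law, interneuron noise is a protocol parameter).
#' @return An `lif_params` object.
#' @export
default_lif_params <- function(type = c("interneuron", "pyramidal"),
                               sigma_n_mV = 0) {
  type <- match.arg(type)
  if (type == "interneuron")
    lif_params(tau_m_ms = 40, C_m_pF = 200, sigma_n_mV = sigma_n_mV)
  else
    lif_params(tau_m_ms = 20, C_m_pF = 155, sigma_n_mV = sigma_n_mV)
}

#' Bipartite pyramidal-interneuron connectivity
#'
#' Assigns each pyramidal cell to exactly one interneuron such that every
#' interneuron receives the same number (`n_pyr/n_int`) of pyramidal cells;
#' the inhibitory connectivity is the transpose, so interneurons project
#' back to the same cells they receive from. The default assignment is by
#' contiguous blocks; `shuffle = TRUE` permutes cell identities using `seed`
#' (column sums are unchanged).
#'
#' @param n_pyr,n_int Population sizes; `n_int` must divide `n_pyr`.
#' @param seed RNG seed used only when `shuffle = TRUE`.
#' @param shuffle Randomly permute the cell-to-interneuron assignment.
#' @return Integer vector `pyr2int` of length `n_pyr` (1-based interneuron
#'   index per pyramidal cell).
#' @export
build_connectivity <- function(n_pyr, n_int, seed = 1L, shuffle = FALSE) {
  stopifnot(n_pyr >= 1, n_int >= 1)
  if (n_pyr %% n_int != 0)
    stop("n_int must divide n_pyr (equal in-degree per interneuron)")
  pyr2int <- rep(seq_len(n_int), each = n_pyr / n_int)
  if (shuffle) {
    set.seed(seed)
    pyr2int <- sample(pyr2int)
  }
  pyr2int
}

#' Binary excitatory connectivity matrix
#'
#' Expands the per-cell assignment into the `n_pyr x n_int` binary incidence
#' matrix (row sums 1, column sums `n_pyr/n_int`); the inhibitory matrix is
#' its transpose.
#'
#' @param net A [network_config()].
#' @return Binary matrix of dimension `n_pyr x n_int`.
#' @export
connectivity_matrix <- function(net) {
  C <- matrix(0L, net$n_pyr, net$n_int)
  C[cbind(seq_len(net$n_pyr), net$pyr2int)] <- 1L
  C
}

#' Network configuration
#'
#' @param n_pyr,n_int Numbers of pyramidal cells and interneurons
#'   (`n_int` divides `n_pyr`).
#' @param wE_nS Pyramidal-to-interneuron synaptic weight (nS), default 0.5.
#' @param wI_nS Interneuron-to-pyramidal synaptic weight (nS), default 25.
#' @param pyr2int Optional explicit assignment from [build_connectivity()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_pyr, n_int, wE_nS = 0.5, wI_nS = 25,
                           pyr2int = NULL) {
  if (is.null(pyr2int)) pyr2int <- build_connectivity(n_pyr, n_int)
  stopifnot(length(pyr2int) == n_pyr, all(pyr2int >= 1), all(pyr2int <= n_int))
  tab <- tabulate(pyr2int, nbins = n_int)
  if (any(tab != n_pyr / n_int))
    stop("each interneuron must receive n_pyr/n_int pyramidal connections")
  structure(list(n_pyr = n_pyr, n_int = n_int, wE = wE_nS * .nS,
                 wI = wI_nS * .nS, pyr2int = as.integer(pyr2int)),
            class = "network_config")
}

#' Drive set: pacemaker, place-field and trajectory inputs
#'
#' External inputs of one simulation: the interneuron current
#' `I0I - Itheta*cos(2*pi*f_theta*t)` and per-place-cell Gaussian envelope
#' currents `IE*exp(-|x(t)-xc|^2/(2*sigma^2))` along the linear trajectory
#' `x(t) = x0 + v*t` (optionally offset laterally, as in edge-of-field
#' passes).
#'
#' @param I0I_pA Tonic depolarizing current to interneurons (pA).
#' @param Itheta_pA Pacemaker amplitude (pA).
#' @param f_theta_Hz Pacemaker frequency (Hz), default 8.
#' @param IE_pA Per-place-cell peak envelope current (pA), recycled to the
#'   number of cells.
#' @param xc_cm Per-place-cell field centers (cm).
#' @param sigma_cm Place-field width parameter (cm), default 40.
#' @param x0_cm Trajectory start (cm).
#' @param v_cms Running speed (cm/s).
#' @param lateral_cm Perpendicular offset of the trajectory from the field
#'   centers (cm); 14 cm reproduces the edge-pass protocol.
#' @return An object of class `drive_set` (SI fields).
#' @export
drive_set <- function(I0I_pA, Itheta_pA = 0, f_theta_Hz = 8,
                      IE_pA = numeric(0), xc_cm = numeric(0), sigma_cm = 40,
                      x0_cm = 0, v_cms = 0, lateral_cm = 0) {
  stopifnot(f_theta_Hz > 0, sigma_cm > 0, all(is.finite(IE_pA)),
            all(is.finite(xc_cm)))
  n <- length(xc_cm)
  IE_pA <- rep_len(IE_pA, n)
  structure(list(I0I = I0I_pA * .pA, Itheta = Itheta_pA * .pA,
                 f_theta = f_theta_Hz, IE = IE_pA * .pA, xc = xc_cm * .cm,
                 sigma = sigma_cm * .cm, x0 = x0_cm * .cm, v = v_cms * .cm,
                 lateral = lateral_cm * .cm), class = "drive_set")
}

#' Perturbation protocol
#'
#' A transient current injection into one or both populations, optionally
#' resetting the pacemaker phase to its t = 0 value at window onset.
#' Negative amplitudes silence. The theta-reset protocol uses -50 pA to the
#' pyramidal cell and -20 pA to the interneuron for 200 ms with a pacemaker
#' reset; the interneuron-silencing protocol uses -10 pA to the interneuron
#' for 1 s, centered either on the field or on a random location within a
#' jitter window of the field center.
#'
#' @param amp_pyr_pA,amp_int_pA Injected current amplitudes (pA; negative
#'   for silencing).
#' @param onset_s Window onset (s).
#' @param duration_s Window duration (s), positive.
#' @param pacemaker_reset Reset the pacemaker phase at window onset.
#' @param center_jitter_cm Half-width (cm) of the uniform per-lap jitter of
#'   the silencing center around the place-field center (0 = exact center).
#' @return An object of class `perturbation_protocol`.
#' @export
perturbation_protocol <- function(amp_pyr_pA = 0, amp_int_pA = 0, onset_s,
                                  duration_s, pacemaker_reset = FALSE,
                                  center_jitter_cm = 0) {
  stopifnot(duration_s > 0, center_jitter_cm >= 0)
  structure(list(amp_pyr = amp_pyr_pA * .pA, amp_int = amp_int_pA * .pA,
                 onset = onset_s, duration = duration_s,
                 pacemaker_reset = isTRUE(pacemaker_reset),
                 center_jitter = center_jitter_cm * .cm),
            class = "perturbation_protocol")
}

#' Simulate the network
#'
#' Forward-Euler integration (default dt = 0.1 ms) of the conductance-based
#' LIF network under the supplied drives. Deterministic given `seed`:
#' identical configuration and seed reproduce the result bit for bit.
#'
#' @param net A [network_config()].
#' @param lif_pyr,lif_int [lif_params()] for the two populations.
#' @param drives A [drive_set()].
#' @param perturb Optional [perturbation_protocol()]; its window must lie
#'   within `[0, T]`.
#' @param T Duration (s).
#' @param dt Timestep (s), default 1e-4 (0.1 ms).
#' @param seed Integer RNG seed.
#' @param record_pyr,record_int Indices of cells whose membrane traces are
#'   recorded (default: all pyramidal cells and the first interneuron for
#'   small networks; none for networks above 20 cells unless given).
#' @param record_every Record every k-th step (default 10, i.e. 1 kHz at the
#'   default dt).
#' @param noise_mode `"variance_preserving"` (default; `sigma_n` is the
#'   stationary voltage-noise SD regardless of dt) or `"timestep_bound"`
#'   (per-step increment `(sigma_n/tau_m)*eta*dt`; effective noise then
#'   depends on the timestep and membrane time constant).
#' @return An object of class `sim_result` with elements `spikes` (data
#'   frame `cell_id`, `cell_type`, `spike_time_s`), `times`, `v_pyr`,
#'   `v_int` (recorded traces, V), `theta` (pacemaker phase, rad), `x`
#'   (position, m), `reset_time`, `dt`, `seed` and the echoed configuration.
#' @export
simulate <- function(net, lif_pyr, lif_int, drives, perturb = NULL, T,
                     dt = 1e-4, seed = 1L, record_pyr = NULL,
                     record_int = NULL, record_every = 10L,
                     noise_mode = c("variance_preserving", "timestep_bound")) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(net, "network_config"), inherits(lif_pyr, "lif_params"),
            inherits(lif_int, "lif_params"), inherits(drives, "drive_set"),
            T > 0, dt > 0)
  if (length(drives$xc) != net$n_pyr)
    stop("drive_set must provide one field center per pyramidal cell")
  if (is.null(record_pyr))
    record_pyr <- if (net$n_pyr + net$n_int <= 20) seq_len(net$n_pyr) else integer(0)
  if (is.null(record_int))
    record_int <- if (net$n_pyr + net$n_int <= 20) seq_len(net$n_int) else integer(0)
  p <- if (is.null(perturb)) {
    list(amp_pyr = 0, amp_int = 0, onset = 0, off = 0, reset = FALSE)
  } else {
    stopifnot(inherits(perturb, "perturbation_protocol"))
    if (perturb$onset < 0 || perturb$onset + perturb$duration > T)
      stop("perturbation window outside simulation")
    list(amp_pyr = perturb$amp_pyr, amp_int = perturb$amp_int,
         onset = perturb$onset, off = perturb$onset + perturb$duration,
         reset = perturb$pacemaker_reset)
  }
  set.seed(as.integer(seed))
  raw <- simulate_lif_cpp(
    net$n_pyr, net$n_int, net$pyr2int - 1L, net$wE, net$wI,
    lif_pyr$tau_m, lif_pyr$C_m, lif_pyr$E0, lif_pyr$V_theta, lif_pyr$V_r,
    lif_pyr$sigma_n,
    lif_int$tau_m, lif_int$C_m, lif_int$E0, lif_int$V_theta, lif_int$V_r,
    lif_int$sigma_n,
    lif_pyr$E_E, lif_pyr$E_I, lif_pyr$tau_E, lif_pyr$tau_I,
    drives$I0I, drives$Itheta, drives$f_theta,
    drives$IE, drives$xc, drives$sigma, drives$x0, drives$v, drives$lateral,
    p$amp_pyr, p$amp_int, p$onset, p$off, p$reset,
    T, dt, as.integer(record_pyr) - 1L, as.integer(record_int) - 1L,
    as.integer(record_every), noise_mode == "variance_preserving")
  if (length(raw$v_pyr) && any(!is.finite(raw$v_pyr)) ||
      length(raw$v_int) && any(!is.finite(raw$v_int)))
    stop("numerical instability: non-finite membrane trace")
  sp <- c(raw$spikes_pyr, raw$spikes_int)
  ns <- lengths(sp)
  spikes <- data.frame(
    cell_id = rep(c(seq_len(net$n_pyr), seq_len(net$n_int)), ns),
    cell_type = rep(rep(c("pyramidal", "interneuron"),
                        c(net$n_pyr, net$n_int)), ns),
    spike_time_s = unlist(sp, use.names = FALSE)
  )
  structure(list(
    spikes = spikes, times = raw$times,
    v_pyr = `colnames<-`(raw$v_pyr, as.character(record_pyr)),
    v_int = `colnames<-`(raw$v_int, as.character(record_int)),
    theta = raw$theta, x = raw$x, reset_time = raw$reset_time,
    dt = dt, record_every = record_every, seed = as.integer(seed),
    net = net, drives = drives, lif_pyr = lif_pyr, lif_int = lif_int,
    perturb = perturb
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d pyr + %d int, T=%.3g s, dt=%.1e s, seed=%d; %d spikes\n",
              x$net$n_pyr, x$net$n_int, x$times[length(x$times)], x$dt,
              x$seed, nrow(x$spikes)))
  invisible(x)
}

#' Spike times of one cell
#'
#' @param sim A `sim_result`.
#' @param cell_type `"pyramidal"` or `"interneuron"`.
#' @param cell_id Cell index within its population.
#' @return Numeric vector of spike times (s).
#' @export
spike_times <- function(sim, cell_type = c("pyramidal", "interneuron"),
                        cell_id = 1L) {
  cell_type <- match.arg(cell_type)
  s <- sim$spikes
  s$spike_time_s[s$cell_type == cell_type & s$cell_id == cell_id]
}

#' Write spikes to CSV
#'
#' @param sim A `sim_result`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_spikes_csv <- function(sim, path) {
  utils::write.csv(sim$spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Closed-form LIF inter-spike interval under constant current
#'
#' For a noise-free LIF neuron driven by constant current `I`, the
#' steady-state voltage is `V_inf = E0 + I*tau_m/C_m` and, when
#' `V_inf > V_theta`, the inter-spike interval is
#' `tau_m * log((V_inf - V_r)/(V_inf - V_theta))`. Used as the analytic
#' oracle for the Euler integrator.
#'
#' @param lif An [lif_params()].
#' @param I_pA Constant current (pA).
#' @return ISI in seconds (`Inf` if the neuron never reaches threshold).
#' @export
lif_isi <- function(lif, I_pA) {
  V_inf <- lif$E0 + I_pA * .pA * lif$tau_m / lif$C_m
  if (V_inf <= lif$V_theta) return(Inf)
  lif$tau_m * log((V_inf - lif$V_r) / (V_inf - lif$V_theta))
}
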