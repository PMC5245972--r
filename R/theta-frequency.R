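# FFT-based analytic signal (no Hilbert transform is available in the
# installed signal-processing packages).  Standard construction: double the
# positive frequencies, zero the negative ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous theta-band frequency of a membrane trace
#'
#' The membrane-frequency estimator: the trace is clipped at the spike
#' threshold (capping spike/reset discontinuities), band-pass filtered in
#' the theta band (zero-phase 2nd-order Butterworth, 6.25-10 Hz), the
#' instantaneous phase is extracted from the analytic signal, unwrapped,
#' smoothed with a 250 ms moving average, and differentiated to give
#' frequency in Hz. Samples within the filter's edge transient are trimmed.
#'
#' @param v Membrane trace (V or mV; only shape matters).
#' @param fs Sampling rate (Hz), at least 1 kHz.
#' @param band Pass band (Hz), default `c(6.25, 10)`.
#' @param smooth_s Moving-average width (s), default 0.25.
#' @param clip Optional ceiling applied to `v` before filtering (same units
#'   as `v`), typically the spike threshold; `NULL` to skip.
#' @param trim_s Edge transient trimmed from each end (s); default six
#'   periods of the low band edge, which covers the ring-down of the
#'   narrow-band filter plus the smoothing window.
#' @return A data frame of class `frequency_trace` with columns `time_s`
#'   (relative to the start of the trace) and `freq_hz`.
#' @export
instantaneous_theta_frequency <- function(v, fs, band = c(6.25, 10),
                                          smooth_s = 0.25, clip = NULL,
                                          trim_s = 6 / band[1]) {
  stopifnot(fs >= 1000, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  n <- length(v)
  if (n <= 2 * (trim_s * fs))
    stop("trace shorter than twice the filter transient")
  if (!is.null(clip)) v <- pmin(v, clip)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  vf <- signal::filtfilt(bf, v - mean(v))
  # mirror-pad before the FFT so the circular discontinuity at the record
  # boundary does not leak ripple into the interior phase estimate
  pad <- c(rev(vf), vf, rev(vf))
  an <- analytic_signal(pad)[(n + 1):(2 * n)]
  ph <- signal::unwrap(Arg(an))
  k <- max(1L, round(smooth_s * fs))
  ph_s <- stats::filter(ph, rep(1 / k, k), sides = 2)
  freq <- c(NA, diff(as.numeric(ph_s))) * fs / (2 * pi)
  t <- seq_len(n) / fs - 1 / fs
  keep <- t >= trim_s & t <= t[n] - trim_s & is.finite(freq)
  structure(data.frame(time_s = t[keep], freq_hz = freq[keep]),
            class = c("frequency_trace", "data.frame"))
}

#' Per-lap precession frequency with the variability exclusion rule
#'
#' For each lap, averages the instantaneous membrane frequency within a
#' radius of the place-field center (default 15 cm). Laps whose in-window
#' frequency standard deviation exceeds `exclusion_factor` times the mean
#' standard deviation over all laps (runs at that speed) are flagged as
#' excluded; this removes artefactual estimates driven by within-cycle
#' bursting.
#'
#' @param laps A list, one element per lap, each a data frame (or list)
#'   with `time_s`, `freq_hz` and `x_m` (animal position at each sample).
#' @param xc_m Place-field center (m).
#' @param radius_m Averaging radius (m), default 0.15.
#' @param exclusion_factor Default 1.75.
#' @return Data frame with `lap`, `mean_freq_hz`, `sd_freq_hz`, `excluded`.
#' @export
lap_precession_frequency <- function(laps, xc_m, radius_m = 0.15,
                                     exclusion_factor = 1.75) {
  stopifnot(length(laps) >= 1)
  per <- lapply(laps, function(lp) {
    sel <- abs(lp$x_m - xc_m) <= radius_m
    if (!any(sel)) stop("empty window: no samples within radius of center")
    c(mean(lp$freq_hz[sel]), stats::sd(lp$freq_hz[sel]))
  })
  m <- do.call(rbind, per)
  sd_ref <- mean(m[, 2])
  data.frame(lap = seq_along(laps), mean_freq_hz = m[, 1], sd_freq_hz = m[, 2],
             excluded = m[, 2] > exclusion_factor * sd_ref)
}
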