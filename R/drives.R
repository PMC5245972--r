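#' Pacemaker current waveform
#'
#' The septal drive to interneurons, `I(t) = I0I - Itheta*cos(2*pi*f_theta*t)`
#' (pA): minimal at t = 0 (cosine peak of the pacemaker) and maximal half a
#' cycle later.
#'
#' @param I0I_pA Tonic current (pA).
#' @param Itheta_pA Pacemaker amplitude (pA).
#' @param f_theta_Hz Pacemaker frequency (Hz).
#' @return A function of time (s) returning current in pA.
#' @export
make_pacemaker_current <- function(I0I_pA, Itheta_pA, f_theta_Hz = 8) {
  force(I0I_pA); force(Itheta_pA); force(f_theta_Hz)
  function(t) I0I_pA - Itheta_pA * cos(2 * pi * f_theta_Hz * t)
}

#' Linear trajectory
#'
#' @param x0_cm Start position (cm).
#' @param v_cms Running speed (cm/s).
#' @return A function of time (s) returning position in cm.
#' @export
linear_trajectory <- function(x0_cm, v_cms) {
  force(x0_cm); force(v_cms)
  function(t) x0_cm + v_cms * t
}

#' Place-field current waveform
#'
#' Gaussian envelope current injected into a place cell along a trajectory:
#' `I(t) = IE*exp(-d(t)^2/(2*sigma^2))` where `d(t)` is the distance from
#' the field center, including any perpendicular (lateral) offset of the
#' running path, as in edge-of-field passes (14 cm offset).
#'
#' @param IE_pA Peak current (pA).
#' @param xc_cm Field center along the track (cm).
#' @param sigma_cm Field width parameter (cm).
#' @param trajectory A function of time returning position (cm), e.g.
#'   [linear_trajectory()].
#' @param lateral_cm Perpendicular offset of the path from the center (cm).
#' @return A function of time (s) returning current in pA.
#' @export
make_place_current <- function(IE_pA, xc_cm, sigma_cm, trajectory,
                               lateral_cm = 0) {
  stopifnot(sigma_cm > 0, is.function(trajectory))
  force(IE_pA); force(xc_cm); force(sigma_cm); force(lateral_cm)
  function(t) {
    d2 <- (trajectory(t) - xc_cm)^2 + lateral_cm^2
    IE_pA * exp(-d2 / (2 * sigma_cm^2))
  }
}

#' Running-speed dependence laws
#'
#' Linear laws (intercept, slope per cm/s) mapping running speed to the four
#' speed-dependent inputs: interneuron tonic current
#' `I0I = 79.5 + 0.027*v` (pA), pacemaker amplitude `Itheta = 0.065*v` (pA),
#' place-cell envelope amplitude `IE = 110 + 0.5*v` (pA) and place-cell
#' noise `sigma_nE = 1.75 - 0.025*v` (mV).
#'
#' @param I0I,Itheta,IE,sigma_nE Numeric `c(intercept, slope)` pairs.
#' @return An object of class `speed_law`.
#' @export
speed_law <- function(I0I = c(79.5, 0.027), Itheta = c(0, 0.065),
                      IE = c(110, 0.5), sigma_nE = c(1.75, -0.025)) {
  stopifnot(length(I0I) == 2, length(Itheta) == 2, length(IE) == 2,
            length(sigma_nE) == 2)
  structure(list(I0I = I0I, Itheta = Itheta, IE = IE, sigma_nE = sigma_nE),
            class = "speed_law")
}

#' Evaluate the speed laws
#'
#' @param v_cms Running speed (cm/s); must keep the evaluated noise
#'   amplitude non-negative (v <= 70 cm/s under the default law).
#' @param law A [speed_law()].
#' @return List with `I0I_pA`, `Itheta_pA`, `IE_pA`, `sigma_nE_mV`.
#' @export
speed_params <- function(v_cms, law = speed_law()) {
  stopifnot(inherits(law, "speed_law"), v_cms >= 0)
  ev <- function(co) co[1] + co[2] * v_cms
  out <- list(I0I_pA = ev(law$I0I), Itheta_pA = ev(law$Itheta),
              IE_pA = ev(law$IE), sigma_nE_mV = ev(law$sigma_nE))
  if (out$sigma_nE_mV < 0 || out$I0I_pA < 0 || out$Itheta_pA < 0 ||
      out$IE_pA < 0)
    stop("speed out of range: a speed law evaluates negative")
  out
}

#' Dorsoventral pole parameter sets
#'
#' Printed parameter sets representing the dorsal and ventral poles of CA1
#' (running speed 30 cm/s in both): the place-field width, place-cell noise,
#' interneuron tonic current, pacemaker amplitude and excitatory synaptic
#' weight all change along the axis.
#'
#' @param pole `"dorsal"` or `"ventral"`.
#' @return List with `sigma_cm`, `sigma_nE_mV`, `I0I_pA`, `Itheta_pA`,
#'   `wE_nS`, `v_cms`.
#' @export
dorsoventral_params <- function(pole = c("dorsal", "ventral")) {
  pole <- match.arg(pole)
  if (pole == "dorsal")
    list(sigma_cm = 45, sigma_nE_mV = 0.7, I0I_pA = 80.455, Itheta_pA = 1.95,
         wE_nS = 0.53, v_cms = 30)
  else
    list(sigma_cm = 600, sigma_nE_mV = 3, I0I_pA = 79.525, Itheta_pA = 0.12,
         wE_nS = 0.081, v_cms = 30)
}
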