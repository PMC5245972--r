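#' Sinusoidal phase response curve
#'
#' Infinitesimal phase response curve (PRC) of the form
#' \eqn{z(\phi) = z_0 - z_1 \sin(\phi)}, the family under which averaging the
#' weakly forced phase oscillator over a pacemaker cycle yields the Adler
#' equation.
#'
#' @param z0 Constant PRC component (rad per unit input).
#' @param z1 Amplitude of the sinusoidal PRC component (rad per unit input),
#'   must be non-negative.
#' @return An object of class `prc` with fields `z0` and `z1`.
#' @seealso [synchronization_factor()], [integrate_prc_model()]
#' @export
phase_response_curve <- function(z0, z1) {
  stopifnot(is.finite(z0), is.finite(z1), z1 >= 0)
  structure(list(z0 = z0, z1 = z1), class = "prc")
}

#' Sinusoidal pacemaker perturbation
#'
#' Weak forcing \eqn{Q(t) = Q_0 \cos(\theta(t))} with pacemaker phase
#' \eqn{\theta(t) = \omega_\theta t}. Phase zero is taken at the cosine peak.
#'
#' @param Q0 Perturbation amplitude (input units), non-negative.
#' @param omega_theta Pacemaker angular frequency (rad/s), positive.
#' @return An object of class `pacemaker_perturbation`.
#' @export
pacemaker_perturbation <- function(Q0, omega_theta) {
  stopifnot(is.finite(Q0), Q0 >= 0, is.finite(omega_theta), omega_theta > 0)
  structure(list(Q0 = Q0, omega_theta = omega_theta),
            class = "pacemaker_perturbation")
}

#' Reduced phase-model parameters
#'
#' Parameters of the averaged (Adler) description of an interneuron entrained
#' by a weak pacemaker: \eqn{d\Delta\phi/dt = \Delta\omega - A\sin\Delta\phi},
#' where the detuning \eqn{\Delta\omega = \omega - \omega_\theta} is the
#' difference between the cell's intrinsic angular frequency and that of the
#' pacemaker, and `A` is the synchronization factor.
#'
#' @param delta_omega Detuning (rad/s). Alternatively supply `omega` and
#'   `omega_theta`.
#' @param A Synchronization factor (rad/s), non-negative.
#' @param omega,omega_theta Optional intrinsic and pacemaker angular
#'   frequencies (rad/s) from which the detuning is computed.
#' @return An object of class `phase_reduction_params`.
#' @export
phase_reduction_params <- function(delta_omega = NULL, A,
                                   omega = NULL, omega_theta = NULL) {
  if (is.null(delta_omega)) {
    stopifnot(!is.null(omega), !is.null(omega_theta))
    delta_omega <- omega - omega_theta
  }
  stopifnot(is.finite(delta_omega), is.finite(A), A >= 0)
  structure(list(delta_omega = delta_omega, A = A), class = "phase_reduction_params")
}

#' Synchronization factor from PRC and pacemaker drive
#'
#' Averaging the phase model \eqn{d\phi/dt = \omega + z(\phi)Q(t)} over one
#' pacemaker cycle, with sinusoidal \eqn{z} and cosine forcing, gives the
#' Adler equation with synchronization factor \eqn{A = Q_0 z_1 / 2}.
#'
#' @param pert A [pacemaker_perturbation()].
#' @param prc A [phase_response_curve()].
#' @return Synchronization factor (rad/s).
#' @export
synchronization_factor <- function(pert, prc) {
  stopifnot(inherits(pert, "pacemaker_perturbation"), inherits(prc, "prc"))
  pert$Q0 * prc$z1 / 2
}

.regime_tol <- function(p) 1e-9 * max(abs(p$delta_omega), p$A, 1)

#' Classify the dynamical regime of the reduced model
#'
#' Phase locking occurs for \eqn{|\Delta\omega| < A} (a stable fixed phase
#' exists), frequency pulling (continuous phase precession or regression) for
#' \eqn{|\Delta\omega| > A}. Equality, within a relative tolerance of 1e-9,
#' is the saddle-node boundary.
#'
#' @param p A [phase_reduction_params()].
#' @return One of `"locking"`, `"pulling"`, `"boundary"`.
#' @export
classify_regime <- function(p) {
  stopifnot(inherits(p, "phase_reduction_params"))
  d <- abs(p$delta_omega) - p$A
  if (abs(d) <= .regime_tol(p)) "boundary" else if (d < 0) "locking" else "pulling"
}

#' Stable locking phase
#'
#' In the locking regime the phase difference settles at
#' \eqn{\Delta\phi_{lock} = \arcsin(\Delta\omega/A)}, which lies in
#' \eqn{(-\pi/2, \pi/2)}; over all admissible detunings the stable phases
#' span exactly \eqn{\pi} radians (180 degrees).
#'
#' @param p A [phase_reduction_params()] in the locking regime.
#' @return Locking phase (rad).
#' @export
locking_phase <- function(p) {
  if (classify_regime(p) != "locking")
    stop("invalid-regime: locking phase requires |delta_omega| < A")
  asin(p$delta_omega / p$A)
}

#' Precession frequency in the pulling regime
#'
#' For \eqn{|\Delta\omega| > A} the phase difference advances one full cycle
#' per period \eqn{1/f} with \eqn{f = \sqrt{\Delta\omega^2 - A^2} / 2\pi}.
#' The drift direction (sign of \eqn{\Delta\omega}; +1 precession, -1
#' regression) is attached as attribute `"drift"`.
#'
#' @param p A [phase_reduction_params()] in the pulling regime.
#' @return Precession frequency (Hz), positive, with attribute `drift`.
#' @export
precession_frequency <- function(p) {
  if (classify_regime(p) != "pulling")
    stop("invalid-regime: precession frequency requires |delta_omega| > A")
  f <- sqrt(p$delta_omega^2 - p$A^2) / (2 * pi)
  attr(f, "drift") <- sign(p$delta_omega)
  f
}

#' Integration constant of the closed-form Adler solution
#'
#' Computes the constant `c` such that [adler_solution()] passes through
#' `phi0` at `t = 0`. In the locking regime the solution has two real
#' branches (tanh and coth); the branch is returned as an attribute and
#' consumed by [adler_solution()].
#'
#' @param p A [phase_reduction_params()].
#' @param phi0 Initial phase difference (rad); wrapped to \eqn{(-\pi, \pi]}.
#' @return Constant `c` (s) with attribute `branch` (`"tan"`, `"tanh"`,
#'   `"coth"` or `"fixed"`).
#' @export
adler_constant <- function(p, phi0) {
  stopifnot(inherits(p, "phase_reduction_params"))
  dw <- p$delta_omega; A <- p$A
  phi0 <- wrap_pi(phi0)
  regime <- classify_regime(p)
  if (regime == "pulling") {
    mu <- sqrt(dw^2 - A^2)
    cc <- (2 / mu) * atan((A - dw * tan(phi0 / 2)) / mu)
    attr(cc, "branch") <- "tan"
    return(cc)
  }
  if (regime == "locking") {
    if (dw == 0) { # pure decay to 0; store tan(phi0/2) in c via branch "decay"
      cc <- phi0
      attr(cc, "branch") <- "decay"
      return(cc)
    }
    nu <- sqrt(A^2 - dw^2)
    r <- (dw * tan(phi0 / 2) - A) / nu
    if (abs(abs(r) - 1) < 1e-12) {
      cc <- phi0
      attr(cc, "branch") <- "fixed"
    } else if (abs(r) < 1) {
      cc <- (2 / nu) * atanh(r)
      attr(cc, "branch") <- "tanh"
    } else {
      cc <- (2 / nu) * atanh(1 / r)
      attr(cc, "branch") <- "coth"
    }
    return(cc)
  }
  stop("boundary regime: closed form degenerates; use integrate_adler()")
}

#' Closed-form solution of the Adler equation
#'
#' Evaluates the general solution
#' \eqn{\Delta\phi(t) = 2\arctan[(A - \sqrt{\Delta\omega^2 - A^2}
#' \tan(\tfrac{1}{2}\sqrt{\Delta\omega^2 - A^2}(c - t))) / \Delta\omega]}
#' with branch continuation across the tangent singularities so that the
#' returned trajectory is continuous and unwrapped: each completed period
#' adds \eqn{2\pi \cdot \mathrm{sign}(\Delta\omega)}. In the locking regime
#' the tangent becomes a hyperbolic tangent and the trajectory saturates at
#' the stable locking phase.
#'
#' @param p A [phase_reduction_params()].
#' @param t Numeric vector of times (s).
#' @param c Integration constant from [adler_constant()] (with its `branch`
#'   attribute); alternatively supply `phi0`.
#' @param phi0 Initial phase difference at `t = 0` (rad).
#' @return A `phase_trajectory`: list with `times`, `phase_diff` (rad,
#'   unwrapped) and `c`.
#' @export
adler_solution <- function(p, t, c = NULL, phi0 = NULL) {
  stopifnot(inherits(p, "phase_reduction_params"))
  dw <- p$delta_omega; A <- p$A
  if (dw == 0 && A == 0)
    stop("degenerate-parameters: delta_omega and A are both zero")
  if (A == 0) {
    if (is.null(phi0)) phi0 <- 0
    return(phase_trajectory(t, phi0 + dw * t, c = NA_real_))
  }
  if (is.null(c)) {
    if (is.null(phi0)) stop("supply either c or phi0")
    c <- adler_constant(p, phi0)
  }
  branch <- attr(c, "branch")
  if (is.null(branch)) {
    branch <- switch(classify_regime(p), pulling = "tan", locking = "tanh",
                     stop("boundary regime: use integrate_adler()"))
  }
  cc <- as.numeric(c)
  eval_branch <- function(t) switch(branch,
    tan = {
      mu <- sqrt(dw^2 - A^2)
      s <- mu * (t - cc) / 2
      k <- floor((s + pi / 2) / pi)
      sw <- s - k * pi
      2 * atan((A + mu * tan(sw)) / dw) + 2 * pi * sign(dw) * k
    },
    tanh = {
      nu <- sqrt(A^2 - dw^2)
      2 * atan((A + nu * tanh(nu * (cc - t) / 2)) / dw)
    },
    coth = {
      # coth diverges at t = c, where the trajectory passes through +/- pi:
      # continue with one 2*pi*sign(dw) step to keep the phase unwrapped
      nu <- sqrt(A^2 - dw^2)
      2 * atan((A + nu / tanh(nu * (cc - t) / 2)) / dw) +
        2 * pi * sign(dw) * (t > cc)
    },
    decay = 2 * atan(tan(cc / 2) * exp(-A * t)),
    fixed = rep(wrap_pi(cc), length(t)),
    stop("unknown branch")
  )
  dphi <- eval_branch(t)
  if (!is.null(phi0)) {
    # the arctan form is defined modulo 2*pi: anchor the whole (continuous)
    # trajectory so that it passes through phi0 at t = 0
    v0 <- eval_branch(0)
    dphi <- dphi + 2 * pi * round((phi0 - v0) / (2 * pi))
  }
  phase_trajectory(t, dphi, c = cc)
}

#' Phase trajectory container
#'
#' @param times Strictly increasing times (s).
#' @param phase_diff Unwrapped phase differences (rad).
#' @param c Integration constant, if produced from the closed form.
#' @return An object of class `phase_trajectory`.
#' @export
phase_trajectory <- function(times, phase_diff, c = NA_real_) {
  stopifnot(length(times) == length(phase_diff), !is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), phase_diff = as.numeric(phase_diff),
                 c = as.numeric(c)), class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> %d samples over [%.4g, %.4g] s; phase span %.4g rad\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              diff(range(x$phase_diff))))
  invisible(x)
}

.rk4 <- function(f, y0, T, dt) {
  n <- floor(T / dt + 1e-9)
  y <- numeric(n + 1)
  y[1] <- y0
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(t, y[i])
    k2 <- f(t + dt / 2, y[i] + dt / 2 * k1)
    k3 <- f(t + dt / 2, y[i] + dt / 2 * k2)
    k4 <- f(t + dt, y[i] + dt * k3)
    y[i + 1] <- y[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  list(times = seq(0, by = dt, length.out = n + 1), y = y)
}

.check_step <- function(rate, dt) {
  if (dt * rate > 0.1)
    stop("step-too-large: dt * max phase rate exceeds 0.1 rad")
}

#' Numerically integrate the Adler equation
#'
#' Classical fixed-step 4th-order Runge-Kutta integration of
#' \eqn{d\Delta\phi/dt = \Delta\omega - A\sin\Delta\phi}. Serves as the
#' independent numerical oracle for [adler_solution()].
#'
#' @param p A [phase_reduction_params()].
#' @param phi0 Initial phase difference (rad).
#' @param T Duration (s).
#' @param dt Step (s), default 1e-4.
#' @return A [phase_trajectory()].
#' @export
integrate_adler <- function(p, phi0, T, dt = 1e-4) {
  stopifnot(inherits(p, "phase_reduction_params"), T > 0, dt > 0)
  .check_step(abs(p$delta_omega) + p$A, dt)
  sol <- .rk4(function(t, y) p$delta_omega - p$A * sin(y), phi0, T, dt)
  phase_trajectory(sol$times, sol$y)
}

#' Numerically integrate the un-averaged PRC phase model
#'
#' Integrates \eqn{d\phi/dt = \omega + z(\phi)\,Q_0\cos(\omega_\theta t)}
#' with a sinusoidal PRC, i.e. the phase model before sub-theta-cycle
#' fluctuations are averaged out. Used to validate the averaged Adler
#' description: with \eqn{A = Q_0 z_1/2} the two agree in the weak-drive
#' limit.
#'
#' @param omega Intrinsic angular frequency (rad/s).
#' @param prc A [phase_response_curve()].
#' @param pert A [pacemaker_perturbation()].
#' @param phi0 Initial oscillator phase (rad).
#' @param T Duration (s).
#' @param dt Step (s), default 1e-4.
#' @return A [phase_trajectory()] whose `phase_diff` is
#'   \eqn{\phi(t) - \omega_\theta t}, directly comparable to the Adler
#'   trajectory. The absolute phase is returned as element `phase`.
#' @export
integrate_prc_model <- function(omega, prc, pert, phi0, T, dt = 1e-4) {
  stopifnot(inherits(prc, "prc"), inherits(pert, "pacemaker_perturbation"),
            T > 0, dt > 0)
  rate <- abs(omega) + pert$Q0 * (abs(prc$z0) + prc$z1)
  .check_step(rate, dt)
  f <- function(t, y)
    omega + (prc$z0 - prc$z1 * sin(y)) * pert$Q0 * cos(pert$omega_theta * t)
  sol <- .rk4(f, phi0, T, dt)
  out <- phase_trajectory(sol$times, sol$y - pert$omega_theta * sol$times)
  out$phase <- sol$y
  out
}

#' Detuning required by the speed-scaling law
#'
#' If the precession frequency is to scale with running speed as
#' \eqn{f = v/(2R)} (one cycle of precession per field traversal), the
#' detuning must satisfy \eqn{\Delta\omega^2 = A^2 + (\pi v / R)^2}.
#'
#' @param v Running speed (m/s), non-negative.
#' @param R Place-field radius (m), positive.
#' @param A Synchronization factor (rad/s), non-negative.
#' @return The (positive) detuning \eqn{\Delta\omega \ge A} (rad/s).
#' @export
speed_constraint_detuning <- function(v, R, A) {
  stopifnot(v >= 0, R > 0, A >= 0)
  sqrt(A^2 + (pi * v / R)^2)
}

#' Wrap angles to (-pi, pi]
#' @param x Angles (rad).
#' @return Wrapped angles.
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Wrap angles to [0, 2*pi)
#' @param x Angles (rad).
#' @return Wrapped angles.
#' @export
wrap_2pi <- function(x) x %% (2 * pi)
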