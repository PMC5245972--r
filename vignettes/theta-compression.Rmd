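---
title: "Interneuron phase precession and theta-sequence compression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interneuron phase precession and theta-sequence compression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetacomp)
```

# The circuit and the question

During locomotion the hippocampus exhibits a 6–10 Hz theta oscillation, and
CA1 place cells fire at theta phases that advance ("precess") as the animal
crosses the cell's place field. Within single theta cycles, the order of
spikes across cells recapitulates the slow behavioral sequence of visited
locations — a time-compressed *theta sequence*. `thetacomp` implements a
circuit model in which this compression originates in *interneurons*: a
septal pacemaker entrains spontaneously active interneurons, each
interneuron couples reciprocally to a group of pyramidal cells, and whenever
a pyramidal cell is driven by a slow spatial envelope its synaptic input
accelerates the interneuron past the pacemaker frequency, dragging both
cells through a full cycle of phase precession.

The package has four computational tiers:

1. **Reduced phase model** — analytic treatment of an interneuron as a
   phase oscillator weakly forced by the pacemaker.
2. **Spiking network** — leaky integrate-and-fire (LIF) pyramidal cells and
   interneurons with conductance synapses, simulated by a compiled
   fixed-step integrator.
3. **Measurement pipeline** — instantaneous theta frequency from membrane
   traces, spike-phase statistics, and the three sequence metrics.
4. **Capacity combinatorics** — counting constraint-satisfying place-field
   maps, cell assemblies and phase sequences.

# The reduced phase model

An oscillator with intrinsic angular frequency $\omega$ driven weakly by
$Q(t) = Q_0\cos(\omega_\theta t)$ through a sinusoidal phase response curve
$z(\phi) = z_0 - z_1\sin\phi$ obeys, after averaging over one pacemaker
cycle, the Adler equation for the phase difference
$\Delta\phi = \phi - \theta$:

$$\frac{d\Delta\phi}{dt} = \Delta\omega - A \sin \Delta\phi,
  \qquad A = \tfrac{1}{2} Q_0 z_1 ,$$

with detuning $\Delta\omega = \omega - \omega_\theta$. Two regimes follow.
For $|\Delta\omega| < A$ the phase locks stably at
$\Delta\phi_{\mathrm{lock}} = \arcsin(\Delta\omega/A)$; over all admissible
detunings these stable phases span exactly $\pi$ — 180 degrees — which is
the model's account of the dorsoventral travelling theta wave. For
$|\Delta\omega| > A$ the phase drifts ("frequency pulling") with frequency
$f = \sqrt{\Delta\omega^2 - A^2}/2\pi$; this is the precession regime that
operates inside the place field. Requiring one cycle of precession per
field traversal, $f = v/(2R)$ for speed $v$ and field radius $R$, pins the
detuning to $\Delta\omega^2 = A^2 + (\pi v/R)^2$
(`speed_constraint_detuning()`).

The closed-form trajectory (an arctangent of a tangent, turning into a
hyperbolic tangent in the locking regime) is implemented in
`adler_solution()` with explicit branch continuation: the published form is
valid only between tangent singularities, so the implementation adds
$2\pi\,\mathrm{sign}(\Delta\omega)$ per completed branch to return a
continuous unwrapped trajectory, and uses the `coth` branch (with one
$2\pi$ continuation at its singularity) for initial phases beyond the
unstable fixed point. `integrate_adler()` and `integrate_prc_model()` are
classical fixed-step RK4 integrators (default $dt = 10^{-4}$ s) used as
independent numerical oracles: the closed form is checked pointwise to
$10^{-6}$ rad, and the averaging step is validated by showing the
full-PRC trajectory converges on the Adler trajectory as $Q_0$ is halved.

Conventions: pacemaker phase is zero at the cosine peak; angles are radians
internally, degrees in user-facing summaries; "precession" denotes
$\Delta\phi$ increasing when $\Delta\omega > 0$, and the regression regime
($\Delta\omega < -A$) is labelled by the `drift` attribute. Regime
classification treats $\big||\Delta\omega| - A\big|$ below a relative
$10^{-9}$ as the saddle-node boundary to avoid floating-point
misclassification; the closed form refuses the exactly-critical case and
defers to the integrator.

# The spiking network

Membrane potentials follow

$$\frac{dV_m}{dt} = -\frac{V_m - E_0}{\tau_m}
  - \sum_j g_j(t)\,\frac{V_m - E_{\mathrm{rev}}}{C_m}
  + \frac{I_{\mathrm{ext}}}{C_m} + \xi(t),$$

with threshold $V_\theta$, reset $V_r$, and exponentially decaying
conductances incremented by the synaptic weight at presynaptic spikes.
Interneurons receive $I_{0I} - I_\theta\cos(\omega_\theta t)$; place cells
receive a Gaussian envelope $I_E \exp(-|x(t)-x_c|^2/2\sigma^2)$ along a
linear trajectory (optionally offset laterally, for edge-of-field passes).
Connectivity is bipartite: each pyramidal cell couples to exactly one
interneuron, every interneuron receives the same number of pyramidal cells,
and inhibition is the transpose — so all cells sharing an interneuron see
one common inhibitory conductance trace, which the compiled integrator
exploits.

Fixed parameters (conventional units): $\tau_{mI} = 40$ ms,
$\tau_{mE} = 20$ ms, $V_\theta = -50$ mV, $V_r = -70$ mV, $E_0 = -65$ mV,
$C_{mI} = 200$ pF, $C_{mE} = 155$ pF, $\tau_I = 10$ ms, $\tau_E = 2$ ms,
$E_I = -70$ mV, $E_E = 0$ mV, $f_\theta = 8$ Hz, $w_E = 0.5$ nS,
$w_I = 25$ nS, $\sigma = 40$ cm, $dt = 0.1$ ms. Speed dependence (in pA
and mV, $v$ in cm/s): $I_{0I} = 79.5 + 0.027v$, $I_\theta = 0.065v$,
$I_E = 110 + 0.5v$, $\sigma_{nE} = 1.75 - 0.025v$ (valid to 70 cm/s).
Dorsoventral pole sets and the two perturbation protocols (transient
silencing with pacemaker reset; 1-s interneuron silencing, optionally
jittered within ±20 cm of the field center) are provided as data.

## Numerical scheme and the noise calibration

The integrator is explicit forward Euler with the threshold tested after
the update and no refractory period; conductances decay *exactly* by
$e^{-dt/\tau}$ between spikes. Initial conditions are $V_m(0)=E_0$, zero
conductances, pacemaker phase zero. Identical configuration and seed give
bit-identical results; laps are simulated independently with seed
`base_seed + lap_index`.

The noise term deserves a paragraph, because the discretization determines
the physics. A per-step increment $(\sigma_n/\tau_m)\,\eta\,dt$ ties the
effective noise to the timestep; at $dt = 0.1$ ms it amounts to a few
hundredths of a millivolt, the pair simulation becomes effectively
deterministic, the place field acquires hard deterministic edges, and the
window of envelope amplitudes yielding exactly one cycle of interneuron
precession shifts far from where the speed-law design places it. The
package therefore defaults to the variance-preserving Ornstein–Uhlenbeck
calibration: the per-step increment is
$\sigma_n\sqrt{2\,dt/\tau_m}\;\eta$, making $\sigma_n$ the *stationary
standard deviation* of the subthreshold voltage noise, independent of the
timestep. Under this calibration the speed law's noise term does what it
is for — spreading the spiking field so that field width and spike count
stay comparable across speeds — and the one-cycle robustness band sits at
place-cell spike counts of roughly 10–25, with the modal transition to two
cycles near 25 (both measured by the acceptance checks). The
timestep-bound discretization remains available via
`simulate(noise_mode = "timestep_bound")` for sensitivity analyses.

Interneurons are noiseless by default (noise there is a protocol parameter
of the dedicated noise sweep). The synaptic driving force uses the
previous-step voltage (explicit Euler throughout).

## What the simulator emulates — and what it does not

The simulator is the package's data generator: all analysis operations
consume its spike trains and membrane traces. It emulates idealized
one-dimensional traversals at constant speed, Gaussian place-field drive,
a perfectly sinusoidal common pacemaker, and one-compartment neurons with
a single synapse class per direction. It does not include CA3/entorhinal
afferents, synaptic plasticity, short-term synaptic dynamics, adaptation,
dendrites, or behavioral variability in running speed. Tests passing on
this generator therefore certify the internal consistency of the model and
pipeline, not the model's fidelity to any particular recording.

# Measurement pipeline

*Instantaneous theta frequency.* Membrane traces are clipped at threshold
(capping spike transients), band-passed 6.25–10 Hz with a zero-phase
2nd-order Butterworth, converted to instantaneous phase via an FFT analytic
signal (mirror-padded so record-boundary leakage cannot ripple into the
interior), unwrapped, smoothed with a 250 ms moving average, and
differentiated. Six periods of the low band edge are trimmed at each end;
on stationary sinusoids across the band the estimator is unbiased to within
0.02 Hz. Per-lap precession frequency averages this estimate within 15 cm
of the field center, excluding laps whose in-window standard deviation
exceeds 1.75 times the mean over laps at that speed.

*Phase–position metrics.* The single-cell metric is the Pearson
correlation between spike positions and spike phases after adding the
phase offset that minimizes it (exhaustive 1° grid; a 0.1° oracle in the
tests bounds the grid error at 0.01). Phases are wrapped to $[0,2\pi)$
after rotation and then treated as linear values — deliberately a rotated
linear correlation, not a circular–linear coefficient. The population
metric applies the same computation to pooled spikes with position
replaced by distance from the firing cell's field center. The single-cycle
theta-sequence metric correlates within-cycle spike times with field
centers in windows one pacemaker period wide, offset by the population
phase offset, half-open to avoid double counting, skipping cycles with
fewer than 3 spikes or 2 distinct cells.

*Cycles precessed.* The winding number of the interneuron's spiking
relative to the pacemaker over the first-to-last place-cell spike of the
lap: consecutive spike-phase differences are wrapped to $(-\pi,\pi]$,
summed, negated (so that movement toward earlier pacemaker phases counts
positive), divided by $2\pi$ and rounded. The window convention follows the
field traversal; it is exact on noiseless synthetic ramps for all winding
numbers tested (0–3 and regression).

*Binned phase comparison.* For silencing experiments, circular mean ±
circular standard error of spike phase in five equal spatial bins spanning
the field, per condition, with the per-bin circular difference wrapped to
$(-\pi,\pi]$; empty bins are reported missing, never zero-filled.

# Capacity combinatorics

On a circular track of $N_{\mathrm{bins}} = L/x_{\mathrm{res}}$ bins, with
place cells partitioned equally among $N_I$ interneurons and an exclusion
zone of $N_d = D/x_{\mathrm{res}}$ bins between same-interneuron fields,
the sequential counting argument gives

$$N_{\mathrm{maps}} = \frac{1}{(F N_p)!}\prod_{i=1}^{F N_p}
 \Big(N_p N_{\mathrm{bins}} - (i-1)\,\tfrac{N_p}{N_I} N_d\Big),$$

evaluated in log space via log-gamma, alongside its Stirling form. The
bound on the active fraction is $F < (N_I/N_p)(L/D)$. Assemblies are
counted by choosing $n$ interneurons and one cell from each
($\binom{N_I}{n}(N_p/N_I)^n$), and phase sequences by repeating the
construction $m$ times on a depleting interneuron pool.

Two conventions required decisions the derivation leaves open. First, the
exclusion convention: `verify_map()` defaults to a symmetric minimum
circular distance (violation iff distance $< N_d$), while the counting
formula removes exactly $N_d$ bins per prior field, which corresponds to a
contiguous $N_d$-bin block centred on the field (extra bin clockwise when
$N_d$ is even). Both are exposed via the `exclusion` argument. Second, the
formula's exactness: a brute-force enumeration oracle
(`brute_force_map_count()`) shows the product formula is exact when the
pairwise exclusion is symmetric (odd $N_d$) and zones of placed fields
cannot overlap; with even $N_d$ the order-dependence of the block makes the
formula overcount slightly, and with overlapping zones the sequential
subtraction double-removes shared bins and undercounts. The tests measure
both biases on tiny instances rather than hiding them. Note also that the
formula's map count *increases* with $F$ over most of the valid range
(more fields, more maps) while the log count per field decreases; the count
decreases strictly in $D$.

One documented discrepancy: for the headline population
($N_p = 10^4$, $N_I = 10^3$, $n = 100$) the printed assembly formula
evaluates to about $10^{240}$, not the $10^{500}$ order quoted in prose.
The package reports the formula's value as computed and does not adjust it.
The map capacity ($>10^{5000}$ at $F = 0.2$, $L = 5$ m, $D = 1$ m,
$x_{\mathrm{res}} = 0.1$ m) and the sequence capacity ($>10^{1500}$ at
$n = 100$, $m = 7$) follow from their formulas directly.

$F N_p$ is rounded to the nearest integer number of fields. Exact counts
are returned as doubles (exact below $2^{53}$, ample for every
oracle-sized instance); all large instances live in log space with a
base-10 converter (`nat_to_log10()`).

# Experiment drivers and problem sizes

Every `run_*()` function is deterministic given its seed and returns
summary tables carrying `n` and dispersion, never bare means. Scaled-down
runs are parameter choices (`n_laps`, `n_trials`, `n_repeats`, `densities`),
never code changes. The test suite uses desk-scale sizes chosen to keep the
full suite in the tens of minutes: 8–20 laps for pair experiments, 40
trials per amplitude for the envelope sweep, $N_p = 1000$ with two map
repeats per density for the network-density comparison, and a 32-cell
network for the noise sweeps; the acceptance script uses the printed
protocol sizes where the source states them (20 laps for the minimal pair,
100 trials per envelope amplitude, 15 amplitudes).

Two measurement subtleties matter when reproducing the headline angles.
The 180° span of stable LIF locking phases is reached only at the
saddle-node edges of the locking interval, where settling slows
critically; `locking_span()` therefore bisects the edges on the tonic
current and probes them with long simulations (150 s), while a naive
coarse sweep underestimates the span by tens of degrees. And in the
dorsoventral comparison, the pole separation is measured between
out-of-field locking phases after at least 100 s of settling, because the
ventral pole's pacemaker amplitude (0.12 pA) makes its locking dynamics
extremely slow.

# Known limitations

* The mapping from depolarizing current to intrinsic frequency is the LIF
  f–I curve; the reduced-model interface deliberately exposes the detuning
  directly rather than parameterizing $\omega(I)$, since no specific f–I
  family is canonical (for more realistic f–I curves the regression regime
  may vanish).
* The relation between the Gaussian drive width $\sigma$ and the field
  radius $R$ of the speed-scaling law is not fixed by the model; $R$ is a
  user-supplied quantity in the reduced tier, while in simulations the
  spiking field width emerges from threshold, drive and noise.
* The Pearson-on-wrapped-phases metrics inherit the usual sensitivity to
  phase wrap placement; the offset optimization mitigates but does not
  eliminate it, which is visible as a mild negative bias on pure-noise
  input (about $-0.08$ at $n = 1000$).
* The even-$N_d$ counting convention cannot be made simultaneously
  symmetric and exactly $N_d$ bins wide; the package follows the formula's
  convention and quantifies the residual bias by enumeration.
* STDP-based associative learning downstream of the compressed sequences
  is conceptual context, not implemented machinery.
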