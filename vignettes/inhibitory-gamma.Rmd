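---
title: "Exact rate equations for inhibition-based gamma oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact rate equations for inhibition-based gamma oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qiffre)
```

## The problem

Networks of recurrently coupled inhibitory interneurons generate fast
collective oscillations in the gamma band (interneuronal gamma, "ING"):
fast synaptic inhibition combined with subthreshold integration produces
an effective delayed negative feedback, and a large fraction of neurons
becomes transiently frequency-entrained.  Classical Wilson-Cowan-type
firing-rate models -- a rate variable driven through a static f-I curve --
cannot produce these rhythms without inserting an explicit delay: their
fixed point is unconditionally stable.  The missing ingredient is spike
synchrony, which lives in the interplay between the population firing
rate and the *mean subthreshold voltage*.

This package implements, side by side:

* the **QIF-FRE**: exact macroscopic equations for a heterogeneous
  all-to-all network of inhibitory quadratic integrate-and-fire (QIF)
  neurons,
  $$\tau_m \dot R = \Delta/(\pi \tau_m) + 2 R V, \qquad
    \tau_m \dot V = V^2 - (\pi \tau_m R)^2 - J \tau_m S + \Theta, \qquad
    \tau_d \dot S = -S + R;$$
* the **H-FRE** (heuristic rate model) with the matching steady-state
  transfer function
  $$\Phi(I) = \frac{1}{\pi\tau_m}\sqrt{\frac{I + \sqrt{I^2 + \Delta^2}}{2}};$$
* the **slow-synapse reduction** $\tau_d \dot S = -S + \Phi(-J\tau_m S +
  \Theta)$, which is formally the Wilson-Cowan equation for one
  inhibitory population;
* microscopic **QIF** and **Wang-Buzsaki (WB)** network simulators; and
* a **stability engine** for the characteristic equation, the parametric
  Hopf boundaries, and the critical heterogeneity.

The exactness of the QIF-FRE rests on two structural assumptions taken as
given here: all-to-all coupling, and quenched input currents drawn from a
Lorentzian distribution with center $\Theta$ and half-width $\Delta$ (the
Lorentzian ansatz closes the macroscopic equations; the derivation itself
is outside the scope of this package).

## Units and the reduced parameters

Internally every rate is carried in 1/ms, so that combinations like
$\tau_m R$ are dimensionless exactly as the equations require; every
user-facing rate is reported in Hz.  Voltages of the QIF model are
dimensionless (positive = suprathreshold); WB voltages are in mV.

For $\Theta > 0$ the five parameters reduce to three:
$j = J/\sqrt\Theta$, $\delta = \Delta/\Theta$,
$\tau = \sqrt\Theta\,\tau_d/\tau_m$, under
$r = \tau_m R/\sqrt\Theta$, $v = V/\sqrt\Theta$,
$s = \tau_m S/\sqrt\Theta$, $\tilde t = \sqrt\Theta\, t/\tau_m$.  The
printed rendering of this change of variables is easy to garble, so the
package fixes it by an algebraic consistency requirement: the reduced
system must be the exact image of the dimensional one, which the test
suite verifies by integrating both and mapping trajectories onto each
other pointwise (they agree to solver roundoff, since the classical
Runge-Kutta scheme is equivariant under the time rescaling).  The same
requirement resolves the transfer function above: it is the unique
$\Phi$ consistent with the stationary QIF-FRE.

At the reference values $\tau_m = 10$ ms, $\Theta = 4$ the most likely
intrinsic period is $\pi\tau_m/\sqrt\Theta \approx 15.71$ ms
($\approx 63.66$ Hz), which sets the scale of the collective rhythm.

## Stability analysis

Linearizing the reduced system at its fixed point
($0 = v_*^2 - \pi^2 r_*^2 - j r_* + 1$ with
$v_* = -\delta/(2\pi r_*)$, $s_* = r_*$) gives the characteristic
equation
$$-2 j r_* = (1 + \lambda\tau)\left[(2\pi r_*)^2 +
  \left(\lambda + \tfrac{\delta}{\pi r_*}\right)^2\right].$$
The package expands it into a cubic and takes companion-matrix
eigenvalues; every root is validated against a residual bound
($<10^{-10}$) and, in the tests, against direct Jacobian eigenvalues over
random parameter triples.  Three structural facts follow:

* $\tau = 0$ (instantaneous synapses): the remaining quadratic has
  complex roots for any $j > 0$ -- the fixed point is always a focus.
  Damped ringing is the macroscopic trace of transient spike synchrony,
  and it is the oscillatory mode that recurrent inhibition can
  destabilize.
* $\delta = 0$ (identical neurons): the expansion near marginality gives
  the growth rate $\nu \approx J\tau_d R_*/[\tau_m(1+(2\pi\tau_d R_*)^2)]$,
  positive whenever $J\tau_d > 0$: the whole quadrant oscillates.  On the
  $J = 0$ boundary the frequency is exactly the intrinsic rate,
  $\omega_c = 2\pi R_*$.
* $\delta > 0$: setting $\lambda = i\omega$ yields
  $\omega^2 = 4v_*^2 + 4\pi^2 r_*^2 - 4 v_*/\tau$ and a quadratic in
  $\tau$ with branches $\tau^\pm(r_*)$; together with
  $j(r_*) = v_*^2/r_* + 1/r_* - \pi^2 r_*$ they trace a closed Hopf
  boundary.  The branches merge where the discriminant
  $(\pi^2 r_*^2 - 1)^2 - (14 + 50\pi^2 r_*^2)v_*^2 - 15 v_*^4$
  vanishes, defining $\delta^*(r_*)$; maximizing it over
  $r_* \in (0, 1/\pi)$ gives the critical heterogeneity

```{r}
critical_delta()
```

above which no oscillation survives at any coupling strength or synaptic
speed.  Because several printed forms of these expressions are
typographically unreliable in circulation, the implementation treats the
marginal-stability substitution itself as normative and uses the legible
anchors (zeros of $\delta^*$ at $0$ and $1/\pi$, the numerical values
above, the phase-diagram geometry) purely as validation; the derivation
was re-done from the Jacobian and is cross-checked in the tests by an
independent route (bisection on the disappearance of the Hopf region).

## The spiking simulators

**QIF network.**  Euler stepping with `dt = 1e-3 * tau_m`; quenched
currents and (by default) initial voltages on deterministic Lorentzian
grids, `eta_i = Theta + Delta * tan(pi/2 * (2i - N - 1)/(N + 1))`.  The
initial voltage grid is centered on the macroscopic `v0` with half-width
`pi * tau_m * r0` -- the spread the mean-field theory associates with
rate `r0` -- so network and rate equations start from the same
macroscopic state.  A neuron crossing `+V_theta` (default 100) spikes, is
held for `2 tau_m / V_theta`, and re-enters at `-V_theta`; the hold
compensates the truncated transit tails, so the single-neuron period
matches the ideal QIF period to better than $10^{-4}$ relative at
`V_theta = 100`.  Spike times are stamped at the crossing step
(`"midpoint"` stamping is available; the difference is a uniform
`tau_m / V_theta` shift).  The integration step is not part of the model
definition; the tests validate it by dt-halving.  The population rate is
a trailing-window count (`tau_s = 1e-2 * tau_m`, with the smoother
`3e-2 * tau_m` variant used when comparing rate traces against the
mean-field model), and the shared gating variable integrates
`tau_d dS/dt = -S + R` from the instantaneous estimate.  Refractory
neurons are excluded from the mean-voltage observable, which would
otherwise be dominated by the frozen values at `+-V_theta`.

**WB network.**  Standard Wang-Buzsaki kinetics (instantaneous sodium
activation, gating accelerated by `phi = 5`), Euler `dt = 0.001` ms,
spikes at interpolated upward 0 mV crossings, inhibition injected as the
shared current `k * C_m * S`.  The leak reversal is `E_L = -65` mV, the
standard value for this model, which reproduces the SNIC threshold
`0.1601` uA/cm^2 found by [snic_threshold()].  Gating rates are served
from piecewise-linear tables (step 0.005 mV, relative error ~1e-9;
`exact_rates = TRUE` disables them) -- the standard speed trick of
conductance-based simulators.  Two numerical guards depart from a naive
transcription: gating variables are clamped to $[0,1]$ (forward Euler can
overshoot at extreme voltages), and initial voltages are truncated to
$[-90, 30]$ mV, because the tails of a half-width-5 mV Lorentzian reach
membrane potentials of hundreds of mV where the gating ODEs are stiff
beyond the Euler stability limit and physically meaningless.  The
truncation touches only the initial condition, about 11% of the mass of
the initial spread.

The `snic_threshold()` probe uses a 2 s window after a 0.5 s discard.
Near a SNIC the firing period diverges as $(I - I_c)^{-1/2}$, so a finite
window biases the bisection upward by roughly the current at which the
period equals the window; for this model that bias is
$\sim 2\times10^{-4}$ uA/cm^2, below the reported tolerance.

## Figure-level protocols

* `oscillation_amplitude()`: mean over five 200 ms windows of the
  peak-to-peak excursion after a 1000 ms transient (defaults; all
  configurable).  Applied to the mean membrane potential, the observable
  least contaminated by finite-size fluctuations.
* `oscillation_frequency()`: inter-peak intervals with a prominence floor
  of 5% of the post-transient range.  The floor is a package choice made
  to reject finite-size ripple while keeping genuine small-amplitude
  cycles near a Hopf boundary.
* `phase_diagram_sweep()`: for each synaptic constant, the coupling is
  stepped with the final state of each run seeding the next
  (continuation), in either direction.  Continuation lets later cells use
  a short per-cell transient.
* `compare_models()`: common initial state and drive, channels
  window-averaged onto a 1 ms comparison grid, pairwise relative L2
  distances over the post-transient span.  The averaging compares network
  traces within their finite-size fluctuation band instead of at raw
  estimator resolution.

## Choices made where the protocol is open

* **Forcing periods.**  The three periodic-drive regimes (slow, medium,
  fast) are fixed at $T_\Theta = 1000, 100, 20$ ms: well above, on the
  order of, and near the membrane time constant respectively.  The
  breakdown of the slow-synapse reduction is assessed comparatively
  across these fixtures, not against absolute numbers.
* **Micro-macro comparison span.**  250 ms with a 100 ms transient at
  $N = 5000$.  Two finite-size effects grow with the span in the
  oscillatory regime: estimator noise (handled by the 1 ms comparison
  grid) and a slow phase drift, since the network's limit-cycle period
  differs from the mean-field one by about 0.1% at this size (the
  discrepancy shrinks with $N$ and with the Euler step, as the test suite
  verifies at $N = 20000$ only indirectly through convergence checks at
  smaller sizes).  A span of a dozen cycles measures waveform agreement
  rather than accumulated dephasing.
* **Reduced phase-diagram grids.**  The full-scale protocol (N = 1000,
  fine grids, cluster-scale) is available through the same functions; the
  shipped sweep fixtures use a 6x6 grid over $\tau_d \in [5, 60]$ ms,
  $k \in [2, 22]$ mV at $N = 300$, sized so the whole three-sweep
  fragility experiment runs on a desktop.  With $\sigma = 0.01$ uA/cm^2
  fixed, the relative heterogeneity $\delta = \sigma/\bar I$ is set
  through $\bar I$ (0.2 and 0.1667 for $\delta = 0.05, 0.06$); the
  $\delta = 0$ sweep uses $\sigma = 0$ at $\bar I = 0.2$.  The grid
  placement follows the mean-field mapping: at $\bar I = 0.2$ the
  intrinsic period is roughly 68 ms, and since the reduced synaptic
  constant is $\tau = \pi \tau_d / \bar T$, the oscillatory region sits
  at synaptic constants several times larger than in the
  $\bar I = 0.5$ preset -- a probe map confirms it around
  $\tau_d \approx 20\text{--}40$ ms, $k \approx 10\text{--}18$ mV at
  $\delta = 0.05$.  A cell counts as oscillatory above 4 mV mean-voltage
  amplitude: at $N = 300$ the asynchronous finite-size ripple stays
  below ~2 mV, partial synchronization near the critical heterogeneity
  reaches 4-5 mV, and full synchrony tens of mV.
* **Sweep durations.**  300 ms transient + three 200 ms windows per cell
  (with continuation), rather than the 1000 + 1000 ms of the full-scale
  protocol; at $N = 300$ the amplitude contrast between synchronous and
  asynchronous cells is far larger than the residual transient error.

## What the synthetic conditions do and do not show

All inputs are parameter sets; there is no external data.  The simulators
realize exactly the idealization the theory assumes -- all-to-all
coupling, quenched Lorentzian currents, first-order synapses, no noise,
no delays, no sparse connectivity.  Agreement between network and rate
equations here validates the reduction and its implementation; it does
not certify the description of cortical circuits, where finite
connectivity, synaptic noise and non-Lorentzian heterogeneity all matter.
The WB comparison probes one step of biological realism (conductance-based
Class 1 neurons): the theory's qualitative predictions (closed oscillatory
region, fragility to heterogeneity) carry over, but the critical
heterogeneity is smaller (~6% against 14.5%), because the steep WB f-I
curve amplifies current dispersion into rate dispersion.  Known further
limitations: no second-order synapse variants, no stochastic mean-field
extensions, no classification of the WB clustering/bistable states seen
at strong coupling (the sweep protocol reports, but does not analyze,
direction-dependent differences), and no super/sub-critical
classification of the Hopf bifurcation.

## Numerical notes

* Rate-model integration: fixed-step RK4, `dt = tau_m/100` by default;
  deterministic and reproducible, no adaptive-step nondeterminism.
  Acceptance-level results are required (and tested) to survive dt
  halving.
* Fixed points: bracketed root finding polished by Newton to residuals
  below $10^{-12}$; cubic roots via the companion matrix; Hopf-curve
  sampling on 2000 log-spaced $r_*$ values with bisection refinement of
  the interval ends where the discriminant changes sign.
* Degenerate inputs: `tau_d = 0` switches the QIF-FRE to its planar form
  (a supplied `s` differing from `r` triggers a warning); `Delta = 0`
  keeps the rate channel at zero once it reaches zero; `eta <= 0` in
  [single_qif_period()] is an error (excitable regime).
* Determinism: every stochastic option (random initial voltages) takes an
  explicit seed recorded in the series metadata; the deterministic
  defaults make identical config + seed reproduce bit-identical outputs.
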