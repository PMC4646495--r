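---
title: "Virtual-teacher coordination dynamics: models, calibration, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-teacher coordination dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdclamp)
```

This vignette is the package's account of its science: the models it
integrates, the parameters that matter and how their defaults were fixed,
what the synthetic partner does and does not capture about a human learner,
and the numerical choices behind the analysis pipeline.

## The virtual teacher

The virtual teacher (VT) is a hybrid Van der Pol–Rayleigh oscillator,

$$\ddot x + (\alpha \dot x^2 + \beta x^2 - \gamma)\,\dot x + \omega^2 x =
  \underbrace{[A + B(x-\mu y)^2](\dot x - \mu\dot y)}_{\text{HKB coupling}} +
  \underbrace{C[(\dot x - \dot y)\cos\Psi + \omega y \sin\Psi]}_{\text{intentional coupling}},$$

integrated by classical fixed-step RK4 at 500 Hz with the partner signal
held constant within each step (the partner is *sampled* at the loop rate;
sub-step interpolation would invent data). Both directions of the loop pass
through a configurable delay, one tick (2 ms) by default.

**Why this damping form.** With $\gamma > 0$ the linear damping is negative
(energy injection) and the two nonlinear channels saturate it: the Rayleigh
term $\alpha\dot x^3$ flattens velocity extrema while the Van der Pol term
$\beta x^2 \dot x$ flattens position extrema. Because the two distort the
waveform in opposite directions, a mixed form stays near-sinusoidal even at
stiff $\gamma$. Zeroing either coefficient recovers the pure form.

**Calibration.** First-order averaging gives the amplitude flow
$\dot r = r\,(4\gamma - 3\alpha\omega^2 r^2 - \beta r^2)/8$, so a unit-
amplitude cycle requires $4\gamma = 3\alpha\omega^2 + \beta$;
`calibrate_vt()` starts from that point, splits the saturation between the
two channels by `vdp_share`, and then refines $\omega$ and the saturation
scale against a simulated cycle so the measured period is exactly
$1/\omega_{hz}$ and the amplitude exactly 1. The shipped defaults use
$\gamma = 18\,s^{-1}$ and `vdp_share = 0.4`, giving total harmonic
distortion of 3.9 % (under the 5 % target for a "near-sinusoidal" cycle)
and an amplitude relaxation rate of $\gamma$, i.e. convergence to the cycle
well within a second. The stiff $\gamma$ matters in closed loop: the
intentional term pumps energy into the VT in proportion to
$|C|(1-\cos\Psi)$, and a soft oscillator would inflate its amplitude
severalfold during Exposition, which both weakens the phase attraction
(the pull scales as the partner-to-VT amplitude ratio) and amplifies the
HKB $B$-term's distortion of the co-produced phase.

**Coupling defaults ($A = 2$, $B = -3.5$, $\mu = 1$).** These were fixed by
direct closed-loop simulation against the default surrogate, not by
averaged theory: first-order averaging underpredicts the fixed-point
distortion at $C=-10$ by roughly a factor of four, and the $A$ coefficient
empirically *improves* Exposition accuracy while slowing the Memory-period
escape from anti-phase — the opposite of its role in the averaged phase
equation. The chosen pair makes the dyad's in-phase state strongly stable
and renders anti-phase weakly unstable at the collective level, so that
after the intentional coupling is switched off the co-produced phase
reliably collapses to 0° from any specified pattern within the 11 s Memory
period — the empirically observed outcome. A consequence worth knowing:
during Exposition the same coupling biases mid-range patterns (105–150°)
a little toward 90°, an undershoot of up to ~19°; the corresponding human
experiments likewise report produced phases below the specified value in
the 90–180° range.

## The surrogate learner

The partner is modeled at the phase level. It integrates its own movement
phase $\theta_y$,

$$\dot\theta_y = \omega_h + \underbrace{-a\sin\hat\varphi - 2b\sin 2\hat\varphi
  + c\sin(\psi_{int} - \hat\varphi)}_{\text{coordination adjustment}},
  \qquad y = \text{amplitude}\cdot\cos\theta_y,$$

with Euler–Maruyama phase noise of intensity $\sigma$ and an estimate
$\hat\varphi$ of the current relative phase formed from the VT signal seen
through a perceptual delay (50 ms by default), compensated by phase
extrapolation at the preferred frequency — the predictive timing that
trained rhythmic movement exhibits. Velocity is the analytic derivative of
the readout; noise enters the phase only, because the empirical variability
of interest is relative-phase variability.

Two design points deserve emphasis:

* **The surrogate owns its phase.** An alternative would be to slave the
  partner's phase to the VT's (emitting
  $\cos(\theta_{VT,delayed} + \varphi)$). That construction makes the
  measured dyad phase identically equal to the internal $\varphi$ and hence
  *independent of every VT coupling* — the virtual teacher could not steer
  anything. Integrating $\theta_y$ freely lets the collective relative
  phase emerge from both partners' adjustments, as in the real closed loop,
  while the ground-truth phase remains available for testing (the `phi`
  column of a simulated trial).
* **Sign convention.** The package's phase flow uses the canonical
  negative-sign HKB form, under which in-phase is stable for positive
  $a, b$ and anti-phase is additionally stable iff $b > a/4$. Reported
  relative phase is VT-minus-partner, so a partner that lags the VT by a
  quarter cycle reads +90°; under the intentional coupling with negative
  $C$ the co-produced phase settles at $+\Psi$ in this convention
  (equivalently $-\Psi$ partner-relative — the mirror image the
  constant-error statistic treats as the same pattern).

**Defaults** ($a = 0.5$, $b = 0.35\,s^{-1}$, $c = 0$,
$\sigma = 0.08\ \mathrm{rad}/\sqrt{s}$, delay 50 ms, amplitude 1,
$\omega_h = 2\pi$): chosen, once, so that the stated repertoire properties
all hold robustly — bistability with the in-phase basin strictly dominant
(about 61 % of deterministic initial conditions), a stationary phase spread
at each attractor comfortably inside 10°, no spontaneous switching on trial
timescales at the default noise, and noise-induced switches (at elevated
$\sigma$) that go from anti-phase to in-phase and not the reverse. The
noise level is deliberately at the low end of human relative-phase
variability: with the Memory-period collapse and attractor identification
required to resolve cleanly within 5-second windows, a more human-like
$\sigma \approx 0.3$ would leave the anti-phase attractor too blurred to
classify against a 10° criterion. What passing tests therefore show is the
*structure* of the dynamics (attractors, basins, steering, collapse,
information flow), not human-scale dispersion.

**Trial starts.** Trials begin with a 6 s pacing metronome and the
instruction to produce peak flexion on each beat; the VT's initial
condition is peak flexion, and the surrogate's initial phase is drawn as
metronome-synchronized with Gaussian jitter (SD 0.25 rad ≈ 40 ms of tap
error at 1 Hz). Uniform-random starts would occasionally begin a trial at
the antipode of the intentional attractor, where the steering term
vanishes, producing un-human-like lingering.

**What the surrogate does not capture.** No practice-dependent parameter
change is fitted: learning across blocks is *scheduled* (the study
condition), with intentional strength $c$ rising over blocks
$(0, 0.8, 1.3, 1.9, 2.8)\,s^{-1}$ toward the experienced pattern and noise
following $(0.40, 0.60, 0.50, 0.30, 0.12)$ — exploration rising when
rewards begin to arrive, then falling as the pattern consolidates. There is
no biomechanics, no amplitude adaptation, no attention lapses, and the
perceptual delay is constant.

## Analysis pipeline

Preprocessing applies, in order: mean-centering, linear least-squares
detrending (configurable to none), zero-phase second-order Butterworth
low-pass filtering at 20 Hz (forward–backward, so band-limited signals are
delayed by zero samples), and cycle-by-cycle normalization into $[-1, 1]$,
with cycles delimited by zero crossings and each half-cycle rescaled by its
own extremum (the operational reading of "normalized cycle by cycle").
Relative phase comes from the analytic signal (frequency-domain Hilbert
construction); it is computed over the *whole* trial so that no filter or
Hilbert edge coincides with a segment boundary, and the built-in trimming
then drops the pacing period and the final second. A 6–20–11 s trial yields
a 20 s Exposition segment and two 5 s Memory segments (M1, transient; M2,
potential stabilization). Circular mean and circular variance ($1 - R$) are
the standard first-moment statistics; constant error is the wrapped
distance to the nearer of $+\Psi$ and $-\Psi$, computed on the segment's
circular mean (not sample-wise).

Reward detection evaluates the continuous relative phase at the partner's
peak-velocity instants, one candidate per movement cycle (cycles delimited
by successive peak-flexion maxima, located on a 2.5 Hz-filtered copy so
phase-noise wiggles cannot double-count cycles), within ±40° of ±90°, at
most one reward per cycle and never two within 0.75 cycles. Percentages
use the protocol maxima (20 per Exposition, 10 per analyzed Memory) and are
capped at 100 because a nominally 1 Hz movement can fit a 21st cycle into a
20 s window.

## Transfer entropy

The estimator is the histogram plug-in form of the conditional-entropy
difference, computed from joint counts over (target future, target past,
source past) with $0\log 0 = 0$ and log base 2. Defaults follow the
analysis design: past-state vectors of length $k = m = 5$ (conservative for
near-limit-cycle movement data), prediction lag and embedding delay both
set to the first zero crossing of the target's autocorrelation (the
first-minimum convention is available), 4 equal-width amplitude bins on the
normalized signals, and decimation of the 500 Hz series to 50 Hz so that
the 11-dimensional histogram is populated over 5–20 s segments. Estimates
on short segments carry small-sample bias (a warning is attached below 10
samples per occupied state); comparisons in the package are therefore
*orderings* across segments and conditions, never absolute magnitudes. An
independent reference implementation (`te_oracle()`, the two conditional
entropies computed directly) is used by the test suite to pin the estimator
to machine precision on discrete sequences.

## Numerical choices and degenerate inputs

* Angles are stored in radians internally and wrapped to $(-\pi, \pi]$;
  every user interface speaks degrees.
* `fixed_points()` brackets sign changes of the phase flow on a 2048-point
  circular grid (including the seam at ±180°) and polishes roots with
  bisection to $10^{-12}$; stability is the sign of a central-difference
  derivative.
* RK4 steps that produce non-finite state raise an integration-failure
  error naming the time; `dt <= 0`, constant series (no cycles, no
  autocorrelation zero crossing), too-short segments for an embedding, and
  schedule gaps are all rejected with typed messages.
* Determinism: a single integer seed fixes a session; per-trial seeds are
  drawn once from it so any trial can be reproduced in isolation. The
  compiled and pure-R engines consume identical RNG streams and agree to
  $10^{-10}$.
* Problem sizes in the shipped tests and acceptance script are the
  protocol's own: 52-trial scanning sessions, 50-trial learning sessions,
  200-seed basin statistics, 100-seed directionality checks.

## Known limitations

The Exposition-phase undershoot near 105–150° (up to ~19°) is structural:
the same HKB coupling that must destabilize anti-phase during Memory drags
mid-range patterns toward 90° during Exposition. The transfer-entropy
magnitudes depend on binning, decimation and segment length and are not
comparable across configurations. The surrogate's phase-level description
cannot express amplitude–phase interactions in the learner. And all
reported properties are properties of this synthetic dyad; human data
would add inter-individual variability, drifts and lapses that the
generator deliberately omits.
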