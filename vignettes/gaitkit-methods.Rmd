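---
title: "Insole-sensor walking analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insole-sensor walking analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkit)
```

## The measurement problem

A walking gait cycle of one foot alternates between a *stance* phase (foot
on the ground: heel strike, foot flat, mid stance, heel off) and a *swing*
phase (foot in the air: toe off, mid swing, late swing). All of the forward
progress of that foot happens during swing, and the foot is stationary — at
zero velocity — whenever it is flat in stance. An instrumented insole that
senses both plantar pressure and acceleration can exploit this structure
directly:

* pressure tells you *when* the foot is airborne, with no drift and no
  integration;
* acceleration, integrated only across the airborne window and reset at
  each stance, tells you *how far* it moved, without accumulating the
  unbounded drift that plagues free inertial double integration.

`gaitkit` implements this pressure-gated inertial pipeline for an insole
with a triaxial accelerometer and eight pressure sensors, each reporting a
2-bit pressing level, sampled at 50 Hz.

## Signal model and pipeline stages

### Pressure word codec

The eight 2-bit levels are fused into a single 16-bit word with Sensor 1 in
the most significant bit pair, $w = \sum_{i=1}^{8} \ell_i 4^{8-i}$. The
codec is exactly bijective (the tests enumerate all 65,536 words) and
strictly monotone in each sensor's level with more significant sensors
fixed. Only two facts about the word matter to segmentation: $w = 0$ means
every sensor is off, and $w = 1$ means only Sensor 8 reads the lowest
nonzero level. The finer structure is retained for future phase-level
analyses (heel strike vs foot flat), which the stance template of the
simulator already exercises.

### Gravity separation

Gravity is tracked per axis by the exponential low-pass recurrence
$g(t) = \alpha\,g(t-1) + (1-\alpha)\,a_{raw}(t)$ with $\alpha = 0.8$, and
the linear acceleration is $a = a_{raw} - g$. The recurrence needs a
starting value. The package seeds it with the first raw sample
(`gravity_init = "first"`), which is exact when the recording starts at
rest in stance — the measurement protocol has subjects standing still
before walking — and converges geometrically otherwise. A zero
initialisation is available because it makes the operator strictly linear,
which the property tests use.

$\alpha = 0.8$ at 50 Hz corresponds to a time constant of roughly 0.1 s.
This is deliberately *not* a sharp separation: at typical swing frequencies
the gravity tracker follows a substantial fraction of the motion, so the
linear channel is a high-pass-shaped version of the true acceleration
rather than the true acceleration itself. The distance estimator is built
around a calibrated coefficient precisely so that this kind of systematic,
stable distortion is absorbed (see *Why the ratio needs the measurement
model* below).

### Band-pass stage

A configurable Butterworth band-pass (defaults: corners 5 and 10 Hz, order
2) is provided for sensor-noise removal. It is applied forward-backward
(`signal::filtfilt`), so it is zero-phase: the filtered acceleration stays
time-aligned with the pressure-derived swing mask, which matters because
the gating in the next stage is sample-wise.

The 5–10 Hz band sits *above* the dominant gait band (~1–3 Hz). Applied to
a clean walking signal it removes most of the stride displacement along
with the noise. The stage is therefore switchable (`bandpass_enabled`),
and every simulator-based distance and calibration analysis in this
package runs with it disabled; it is meaningful for hardware recordings
whose noise genuinely lives above 5 Hz, and its corners are exposed rather
than buried. Segmentation never depends on it (pressure words are discrete
states and are not filtered).

### Swing segmentation

The raw per-sample indicator is $F(k) = 1 \iff p(k) \le \text{threshold}$,
with threshold 1. Two remarks:

* Swing requires *all* sensors off, so the natural cutoff would be
  $p = 0$; the threshold of 1 exists solely to absorb a hardware artifact
  in which Sensor 8 reports the lowest nonzero level during late swing,
  just before heel strike. Stated as an inequality the other way around
  (swing above the threshold) the rule would contradict the all-off
  requirement; the package implements the orientation that satisfies it,
  and the segmentation tests pin the behaviour on the three canonical
  words 0, 1 and 16384.
* The indicator is then debounced: swing runs shorter than `min_swing`
  samples are flipped to stance, then stance runs shorter than
  `min_stance` are flipped to swing. The defaults, 5 samples = 0.1 s at
  50 Hz, are several times shorter than any physiological swing (~0.4 s)
  or stance (~0.6 s), so debouncing can only remove chatter, never a real
  phase. Debouncing is idempotent: interior runs of the output always meet
  the minimum lengths.

Maximal swing runs become stride segments. Runs touching either recording
boundary are dropped with a warning: their integrals would be truncated,
and the protocol (stand still, walk, stand still) makes complete runs the
expected case. One swing equals one stride of the instrumented foot, so
the stride count is the number of segments, and swing boundary times are
the run edges — accurate to one sample (0.02 s) by construction when the
pressure signal is clean.

### Distance estimation

Within each stride's swing window of $N$ samples, with $\Delta t = 1/f_s$
and velocities reset to zero at toe-off:

$$v_{MAG}[k] = \sum_{j \le k} a[j]\,\Delta t,\quad
  d_{MAG} = \sum_{k=1}^{N} v_{MAG}[k]\,\Delta t,\qquad
  a[k] = \sqrt{a_x^2 + a_y^2 + a_z^2},$$

and analogously $v_z, d_z$ from the vertical channel. The cumulative
distance is

$$d[n] = d[n-1] + K\,\frac{d_{MAG}[n]}{|d_z[n]|} + L_0,\qquad d[0] = 0,$$

with foot length $L_0 = 0.26$ m (an average adult value) added once per
stride, and $K$ a dimensionless calibrated coefficient. $K$ is not a mere
unit conversion: it projects the airborne tracing distance onto the
horizontal walking direction and simultaneously absorbs the quadrature
constant and the gravity-separation distortion.

Numerical choices here, all covered by tests:

* **Rectangular, left-endpoint quadrature**, exactly as the sums are
  written, not trapezoidal. Fidelity to the online sample-by-sample
  formulation is worth more than quadrature accuracy, because $K$ absorbs
  the constant.
* **$|d_z|$, not signed $d_z$.** Over a complete lift-and-land swing the
  net vertical displacement is near zero and its sign is not meaningful;
  the magnitude keeps the ratio positive and the cumulative distance
  monotone.
* **Degenerate strides.** If $|d_z|$ falls below `dz_epsilon` (default
  1 mm) the ratio is undefined; the stride is flagged and uses the median
  ratio of the unflagged strides of the same recording. If every stride is
  flagged the estimate errors out rather than guessing.
* **Scale invariance.** Multiplying all accelerations by $c > 0$ scales
  $d_{MAG}$ and $d_z$ by $c$ and leaves the ratio — and hence the distance
  — unchanged. The estimator depends on the *shape* of the swing, not its
  amplitude; the tests assert this exactly.
* **First stride.** A walk started from standing begins with a short first
  step rather than a full stride. Its swing is still detected and
  integrated like any other; no special offset is applied.

### Calibration and evaluation

For each labelled walk the coefficient that reproduces its reference
distance exactly follows from the batch form:
$K_i = (d^{(r)}_i - N_i L_0) / \sum_n \text{ratio}_{i,n}$, an exact
algebraic inversion rather than an iterative tuning — for a single walk
the two coincide, and refitting a walk with its own $K_i$ returns its
reference to floating-point accuracy (a by-construction identity the tests
assert at 1e-9). The final coefficient is the arithmetic mean of the
per-walk coefficients.

Evaluation uses leave-one-out cross-validation — deterministic, no random
fold assignment — and reports the estimate mean, median, min, max, SD and
the mean relative error $e = \frac{1}{N}\sum_i |d^{(m)}_i - d^{(r)}_i| /
d^{(r)}_i$. Absolute deviations are used: a signed mean could report a
near-zero error for estimates that scatter widely around the reference,
which is not what a per-walk accuracy figure should mean. $e$ is invariant
under common rescaling of estimates and reference.

## The synthetic gait simulator

`simulate_walk()` generates the signals the insole would record during a
straight, level walk, plus exact ground truth. Design decisions:

* **Trajectory first, accelerations by differencing.** Each stride's foot
  trajectory is closed-form — vertical: half-sine of amplitude
  `lift_height`; forward: cycloidal advance with zero velocity at toe-off
  and landing — and the accelerations are the *exact second central
  differences* of the sampled trajectory. This links ground truth and
  pipeline output mathematically: the rectangular double sum of the clean
  forward acceleration telescopes exactly to the stride length, which the
  tests verify at 1e-9, making parameter-recovery tests meaningful rather
  than circular.
* **Gravity injected, not bypassed**, so the gravity-separation recurrence
  is exercised end-to-end, followed by i.i.d. Gaussian noise per axis.
* **Pressure structure.** Stance uses a heel→flat→heel-off→toe activation
  template across the 8 sensors (every stance word is well above the
  threshold); swing is word 0, except that samples in the last quarter of
  each swing take word 1 with probability `pressure_glitch_prob`,
  reproducing the late-swing Sensor-8 artifact the threshold rule absorbs.

**Why the ratio needs the measurement model.** With exact
second-difference accelerations, the vertical double sum telescopes to
exactly zero over a complete swing — the foot lands at its take-off
height. The finite $d_z$ the estimator divides by is therefore *created*
by the gravity-separation recurrence, whose high-pass action breaks the
telescoping in a deterministic, stable way. Consequently the simulator's
ground-truth per-stride ratio is defined as the noiseless measurement: the
same recurrence (with the configured $\alpha$) and the same rectangular sums,
computed by plain loops over the exact swing windows. On glitch-only,
noise-free recordings the pipeline reproduces these ratios to
floating-point accuracy.

Default study conditions, chosen once as representative of normal adult
walking and then left alone: swing 0.4 s, stance 0.6 s (one stride per
second), nominal stride length 1.3 m — giving ~1.3 m/s, inside the
1–1.6 m/s band observed for healthy adults — lift height 0.05 m, 5%
uniform per-stride length jitter, accelerometer noise SD 0.2 m/s² per axis
(consumer-MEMS-during-gait scale), glitch probability 0.3.
`simulate_database()` builds labelled multi-walk databases (e.g. 84 walks
over 16 m, 30 over 89 m); with `true_K` supplied, walks are labelled with
the distance implied by their own noiseless trajectory under that single
coefficient, the configuration in which LOOCV must recover the coefficient
exactly on clean data.

**What the simulator does not emulate** — and therefore what passing tests
do *not* show about hardware data: soft-tissue and shoe-mounting
artifacts, correlated (non-white) sensor noise, accelerometer bias, scale
and axis misalignment, foot orientation change during swing (the sensor
frame is assumed gravity-aligned), left/right asymmetry, turning,
dragging, slopes or stairs, and pathological gait. Results on real insoles
depend on a calibration performed on the same hardware and population.

## Problem sizes used by the test-suite

The packaged checks run at desk scale, chosen to exercise the claims
without excess: exhaustive 65,536-word codec round-trip; 100-case
loop-oracle equivalence at 1e-12 relative for the recurrence, the gating
and the double sums; 50 simulated recordings of 5–100 strides (glitches
enabled) for exact stride counting; 10 clean recordings for one-sample
swing-boundary agreement; and 84-walk databases for coefficient recovery —
below 1% mean relative error noiseless, below 5% at the default noise
level. The acceptance script regenerates the stride-counting figure from
scratch with a caller-supplied seed.

## Known limitations

* The estimator assumes straight, level, normal walking; the ratio-based
  projection has no notion of heading, so turns shorten the estimate.
* The coefficient $K$ is population- and hardware-specific; it should be
  recalibrated per device batch, and ideally per walking-speed regime.
* Boundary-touching swings are discarded, so a recording cut mid-swing
  loses that stride.
* The band-pass defaults are kept for fidelity to the measurement system
  but are rarely appropriate for distance work (see above); this tension
  is surfaced as a switch rather than silently resolved.
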