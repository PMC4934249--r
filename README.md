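# gaitkit

Stride counting and walking-distance estimation from shoe-insole sensors.

`gaitkit` analyses recordings from an instrumented insole that combines a
triaxial accelerometer with eight plantar pressure sensors, each reporting a
2-bit pressing level. It is aimed at people working on wearable gait
monitoring — digital-health researchers, movement scientists, engineers
prototyping insole hardware — who need a transparent, testable reference
implementation of pressure-gated inertial distance estimation, plus a
synthetic gait simulator so every stage can be validated without hardware.

## The method

**Pressure fusion.** The eight 2-bit sensor levels are packed into one
16-bit word, Sensor 1 in the most significant bit pair:
*w* = Σᵢ ℓᵢ · 4^(8−i). A word of 0 means every sensor is off; a word of 1
means only Sensor 8 is "slightly pressed" — an artifact that occurs in late
swing just before heel strike.

**Gravity separation.** Per axis, gravity is tracked by the exponential
low-pass g(t) = α·g(t−1) + (1−α)·a_raw(t) with α = 0.8, and linear
acceleration is a(t) = a_raw(t) − g(t). A configurable 5–10 Hz Butterworth
band-pass (order 2, zero-phase) is available for noise removal.

**Swing segmentation.** A sample is in swing iff its pressure word is at or
below the threshold (default 1, absorbing the Sensor-8 artifact), followed
by a 0.1 s debounce. Each maximal swing run is one stride of the
instrumented foot, so the stride count is the number of swing runs, and the
swing start/stop times fall out of the run boundaries.

**Distance.** Within each swing the acceleration magnitude
a[k] = √(ax² + ay² + az²) and the vertical channel are double-integrated
with rectangular sums (velocity reset to zero at toe-off):

    vMAG[k] = Σ_{j≤k} a[j]·Δt      dMAG = Σ_k vMAG[k]·Δt
    vz[k]   = Σ_{j≤k} az[j]·Δt     dz   = Σ_k vz[k]·Δt

giving the tracing displacement dMAG (path of the foot through the air) and
the vertical displacement dz. The cumulative distance after stride *n* is

    d[n] = d[n−1] + K · dMAG[n] / |dz[n]| + L0

with foot length L0 = 0.26 m and a dimensionless coefficient K calibrated
from labelled walks: for each reference walk, K is inverted exactly from
the batch form (d(r) − N·L0)/Σ ratio, and the final K is the mean across
walks. Evaluation uses leave-one-out cross-validation and the mean relative
error e = (1/N)·Σ |d(m)ᵢ − d(r)| / d(r).

## Worked example

Simulate a 20-walk database over a 16 m course, calibrate K by LOOCV, then
estimate an independent walk:

```r
library(gaitkit)

db     <- simulate_database(n_walks = 20, reference_distance = 16, seed = 42)
params <- gait_params(bandpass_enabled = FALSE)

fit <- fit_K(db, params)
fit
#> Calibrated distance coefficient K = 0.0130029 (mean of 20 walk coefficients, SD 0.000432)

loocv_evaluate(db, params)
#> Distance evaluation over 20 walk(s):
#> # A tibble: 1 × 7
#>       n  mean median   min   max    sd  error
#>   <int> <dbl>  <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1    20  16.0   16.0  15.3  16.9 0.455 0.0219

sim <- simulate_walk(n_strides = 12, seed = 7)
params$K <- fit$K
glance(estimate_walk(sim$recording, params))
#> # A tibble: 1 × 6
#>   stride_count total_distance n_flagged mean_stride      K    L0
#>          <int>          <dbl>     <int>       <dbl>  <dbl> <dbl>
#> 1           12           15.1         0        1.26 0.0130  0.26
```

The held-out estimates average 16.0 m with a mean relative error of 2.2%
on this noisy synthetic database, and the fresh walk (true distance
15.46 m) is estimated at 15.1 m with all 12 strides counted. `tidy()` on
any result gives the per-stride or per-fold table; `autoplot()` draws the
recording, the cumulative distance, or the evaluation scatter.

A command-line wrapper ships in `inst/exec/gaitkit` with subcommands
`simulate`, `strides`, `distance`, `calibrate` and `evaluate`.

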