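# holoscope

Computational core of a **lensless on-chip in-line holographic
microscope**, for researchers building or evaluating low-cost point-of-care
imaging devices: a CMOS sensor records the interference pattern (hologram)
of a semi-transparent sample placed a fraction of a millimeter above it,
and everything optical happens in software. The package provides

- **angular-spectrum propagation** of complex scalar fields (exact, with
  hard evanescent cutoff),
- a **forward simulator** producing ground-truth phantoms (USAF-1951 bar
  targets; disc phantoms mimicking ~15 µm cells and polystyrene beads) and
  their hologram/background recordings,
- **backpropagation reconstruction** plus **iterative support-constrained
  phase recovery** that suppresses the twin image inherent to in-line
  holography,
- full-reference **image-quality metrics** (oblique-edge blur coefficient
  K<sub>blur</sub>, covariance-based quality index Q) and **USAF-1951
  resolution scoring**,
- a deterministic **cell/particle segmentation and counting pipeline**
  (two-threshold classification, border/size cleaning, distance-transform
  watershed).

## The model

A semi-transparent object has transmittance `t(x₀,y₀) = 1 + Δt(x₀,y₀)` with
`|Δt| ≪ 1`. Illuminated by a plane wave A, the field propagates the
sample-to-sensor distance z₂ by the angular spectrum method,

```
P_z(ε,η) = exp( j·z·(2π/λ)·√(1 − (λε)² − (λη)²) )   for (λε)² + (λη)² < 1,
         = 0                                         otherwise,
```

and the sensor records the intensity

```
I = |A′ + a|² = |A′|² + A′*·a + A′·a* + |a|²,
```

where A′ is the propagated reference wave and `a = P[z₂]{A·Δt}` the object
wave. Backpropagating √I over −z₂ recovers the object but superimposes the
out-of-focus conjugate (**twin image**). The iterative recovery loop
alternates two constraints: outside the thresholded object support the
object-plane field is replaced by `m·D₋z₂` (the backpropagated background,
scaled by the iteration coefficient `m = mean|U| / mean|D|`), and at the
sensor plane the modulus is reset to √I while the recovered phase is kept.
The loop typically converges in well under 15 iterations.

## Worked example

```r
library(holoscope)

geom <- optical_geometry(wavelength = 587e-9, z2 = 0.5e-3,
                         pixel_pitch = 1.12e-6,
                         grid_rows = 256, grid_cols = 256)
phantom    <- make_disc_phantom(geom, n_cells = 5, n_particles = 3, seed = 42)
hologram   <- record_hologram(phantom, geom)
background <- record_background(geom)

result <- iterate_phase_recovery(hologram, background, geom, recovery_config())
result
#> <recovery_result> 7 iteration(s), converged (last residual 0.000896)

truth <- Mod(phantom$transmittance)
sqrt(mean((recovered_amplitude(result, naive = TRUE) - truth)^2))  # 0.0385
sqrt(mean((recovered_amplitude(result) - truth)^2))                # 0.0023

count_objects(recovered_amplitude(result))
#> <count_report> 5 cell(s), 3 particle(s); removed: 0 border, 0 small
```

The recovery converged in 7 iterations; the root-mean-square error of the
recovered amplitude against the known transmittance drops from 0.0385
(plain backpropagation, twin-image ringing included) to 0.0023, and the
counting pipeline recovers the simulated 5 cells and 3 particles exactly —
particles are distinguished from cells by their darker recovered amplitude.

USAF-1951 arithmetic used for resolution scoring:

```r
usaf_frequency(6, 4)                        # 90.50967 lp/mm
usaf_frequency(6, 4) / usaf_frequency(6, 1) # 1.414214
```

## Command line

A thin dispatcher over the same functions
(`simulate | recover | assess | count | demo`):

```sh
Rscript inst/cli/holoscope.R simulate --config run.yaml --out sim --n-cells 5 --n-particles 3
Rscript inst/cli/holoscope.R recover  --config run.yaml --out sim \
        --hologram sim/hologram.tif --background sim/background.tif
Rscript inst/cli/holoscope.R count    --config run.yaml --out sim \
        --amplitude sim/recovered_modulus.tif
```

Exit codes: 0 success, 2 configuration error, 3 I/O error. Quantitative
images are 32-bit float TIFF; previews are PNG; reports are JSON/CSV with a
manifest of input hashes for reproducibility.

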