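---
title: "Methods: in-line holographic imaging, phase recovery and counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-line holographic imaging, phase recovery and counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoscope)
```

## The imaging model

A lensless in-line holographic microscope places a semi-transparent sample
a distance $z_2$ (here 0.5 mm) above a bare image sensor and illuminates it
with a quasi-coherent source. The sample is modeled by a complex
transmittance $t(x_0, y_0) = 1 + \Delta t(x_0, y_0)$ in the weak-object
regime $|\Delta t| \ll 1$. After the sample, the field propagates to the
sensor by the angular spectrum method: the spatial-frequency spectrum is
multiplied by

$$
P_z(\epsilon, \eta) =
\begin{cases}
\exp\!\left(j z \frac{2\pi}{\lambda}
  \sqrt{1 - (\lambda\epsilon)^2 - (\lambda\eta)^2}\right)
  & (\lambda\epsilon)^2 + (\lambda\eta)^2 < 1\\[2pt]
0 & \text{otherwise,}
\end{cases}
$$

which is exact for scalar fields (no Fresnel approximation). Frequencies
past the cutoff are evanescent and are zeroed hard — no apodization — so
propagation never increases energy and conserves it exactly for
band-limited fields. The sensor records only the intensity

$$
I = |A' + a|^2 = |A'|^2 + A'^{*}a + A'a^{*} + |a|^2 ,
$$

the sum of the reference light, the two interference terms that carry the
object information, and the object self-interference (negligible for weak
objects). Backpropagating $\sqrt{I}$ over $-z_2$ restores the object
superimposed with its defocused conjugate — the twin image — which is the
artifact the iterative recovery removes.

### Assumptions

* **Plane-wave illumination.** The source-to-sample distance $z_1$ (5 cm)
  and the source pinhole are carried as metadata only; partial-coherence
  blur is not modeled. The forward model is therefore an idealization of a
  real LED + pinhole device.
* **Thin, weak objects.** The transmittance model is a single thin plane;
  multiple scattering and volume effects are out of scope.
* **Monochromatic light** at a single wavelength (default 587 nm).

## The iterative phase-recovery loop

1. **Initialize** with the naive reconstruction: amplitude $\sqrt{I}$ at
   the sensor, phase zero, backpropagated over $-z_2$.
2. **Object-plane (support) constraint.** A binary support $S$ is estimated
   by thresholding the object-plane modulus (Otsu by default — absorbing
   objects are darker than the surround), followed by morphological closing
   and a 2 px dilation so $S$ safely covers object edges. Outside $S$ the
   field is replaced by $m \cdot D_{-z_2}$, where $D_{-z_2}$ is the
   backpropagated square root of the (normalized) background and the
   iteration coefficient $m = \operatorname{mean}|U| /
   \operatorname{mean}|D|$ matches the two levels. Inside $S$ the field is
   kept.
3. **Sensor-plane (modulus) constraint.** The constrained field is
   propagated forward, its phase retained, and its modulus reset to
   $\sqrt{I}$; the result is backpropagated.

Steps 2–3 repeat until the relative $L_2$ change of the object-plane
modulus falls below the tolerance (default $10^{-3}$) or the iteration cap
(default 15) is reached. The loop is fully deterministic.

### Choices the literature leaves open

* **"Root mean square" of the hologram** is read as the pixelwise square
  root of intensity — the field modulus — the only reading consistent with
  the sensor-plane modulus constraint and standard in-line holography
  practice.
* **The iteration coefficient $m$** is written ambiguously in the source
  material; it is implemented as the ratio of region means
  $\operatorname{mean}|U^i| / \operatorname{mean}|D|$, which makes $m$ a
  dimensionless scalar. The averaging region defaults to outside-$S$ (the
  region the replacement acts on) and can be switched to the full field
  (`m_region = "full_field"`).
* **Support updating** across iterations is unspecified; the support is
  frozen after iteration 1 by default (`support_update_every = 0`), which
  is deterministic and testable; periodic re-estimation is available as a
  config option.
* **Background removal** defaults to division ($I/B$), which removes the
  reference term multiplicatively and also flattens illumination
  non-uniformity; subtraction and pass-through are available. When no
  background is supplied, a uniform field at the hologram's mean level
  substitutes for $D$, with a warning.
* **Convergence metric**: $\||U^{i+1}| - |U^i|\|_2 / \||U^i|\|_2$ at the
  object plane. Residual monotonicity is not guaranteed by the algorithm
  and is not asserted; converged runs must only end at or below their
  first residual.

## The synthetic-data generator

The simulator is the package's source of ground truth and emulates the
study conditions of a bench device: λ = 587 nm, $z_2$ = 0.5 mm, 1.12 µm
pixels. Disc phantoms mimic 15 µm polystyrene beads and mouse ascites
tumor cells; the two classes differ in amplitude transmittance (defaults
0.3 for high-refractive-index particles, 0.7 for cells — particles render
darker, which is the physical basis of the intensity classifier).
Placement is seeded rejection sampling with a minimum separation; the
object list is exact ground truth for counting tests. USAF-1951 phantoms
render three-bar elements at the standard frequency
$f = 2^{g + (e-1)/6}$ lp/mm with bar width $0.5/f$ and 5× bar length,
recording each element's bounding box for contrast probing.

What the generator does **not** emulate: partial coherence (LED spectral
width, pinhole size), sensor noise beyond optional Poisson/Gaussian models,
Bayer color sampling, dark current, optical aberrations, and real cell
morphology (discs are hard-edged). Passing tests therefore demonstrate the
correctness of the algorithms under the stated physics, not performance on
photographs from a physical device, whose raw images are not distributed.

## Quality metrics

* **Blur coefficient** $K_{\mathrm{blur}} = S_{\mathrm{out}} /
  S_{\mathrm{in}}$, the ratio of oblique-edge energies
  $S = \sum |y_f|$ of test and reference images. The oblique differential
  filter is unspecified in the source material; the package fixes a
  versioned 3×3 kernel (identity string `oblique-diag-3x3-v1`): a diagonal
  first difference summed with its mirrored counterpart, i.e. $+2$ at the
  center and $-1$ at the two opposite oblique neighbours. Any consistent
  oblique kernel preserves the metric's ordering since $K_{\mathrm{blur}}$
  is a ratio; fixing and versioning one makes values reproducible.
  Blur gives values in $(0,1)$; noise or ringing can push the ratio above
  1 because spurious structure adds edge energy — the metric's nominal
  $[0,1]$ range assumes a distortion-free test image.
* **Quality index** $Q = 4\sigma_{xy}\bar x\bar y \,/\,
  [(\sigma_x^2 + \sigma_y^2)(\bar x^2 + \bar y^2)]$, computed globally
  (one number per image). The cross term is implemented as the sample
  covariance with the same $n-1$ normalization as the variances, the only
  reading under which $Q(x, x) = 1$ holds identically.
* **USAF resolution scoring**: for each rendered element and orientation,
  the across-bar profile (averaged along the bars) must separate all three
  bars from their adjacent gaps with Michelson contrast
  $(g - b)/(g + b) \ge 0.1$ (default) in both orientations; the finest
  such element is the resolution limit.

## The counting pipeline

1. **Two-threshold classification** into background / cell / particle.
   Defaults are Otsu-derived: a first split isolates objects from
   background, a second Otsu split of the object pixels separates the
   darker particles from the lighter cells. Thresholds are named by class,
   so swapping the two values swaps the labels exactly. This deterministic
   classifier replaces interactive, model-bearing pixel classifiers: for
   recovered amplitude images the class separation is an intensity
   separation, so a reproducible two-threshold rule suffices.
2. **Cleaning**: components touching the image border are removed (the
   incomplete-edge rule), components below `min_area_px` (default 20 px)
   are removed, interior holes are filled; the two removal counts are
   reported separately.
3. **Watershed splitting** of adherent objects on the distance transform.
   The basin-merging tolerance scales with the expected radius
   (`max(0.5, 0.1 · min_separation_px)`): the saddle between two discs one
   radius apart is only ≈ 0.13 r deep, while discretization ripple on a
   single convex disc stays below 0.5 px, so singles are never over-split
   and pairs separate once their centers are ≈ 1.2 radii apart.
4. **Counting** with deterministic labeling: ids are assigned in raster
   order of centroids, so identical inputs give identical reports.

## Numerical choices

* All field arithmetic is double-precision complex; the iterative loop
  accumulates round-off otherwise.
* DFT frequency convention: cycles per meter on the standard grid with
  spacing $1/(N \cdot \text{pitch})$, DC at the corner.
* No zero-padding by default — padding changes results, so the default is
  the plain transform; an optional power-of-two `pad_factor` suppresses
  wrap-around for large propagation distances.
* Quantitative images are stored as 32-bit float TIFF. The encoder accepts
  $[0,1]$ only, so images with values above 1 are rescaled and the
  reciprocal scale stored as a 1×1 second TIFF page, undone on read.
* Degenerate inputs are contracts, not crashes: constant fields yield an
  empty, flagged support (the recovery then returns the naive
  reconstruction with a warning); constant images are rejected by the
  metrics (0/0); empty masks count zero objects.

## Problem sizes used in the tests

Unit and property tests run on 16–256 px grids; the reference convergence
simulation runs once at 512×512 (ten 15 µm discs, amplitude transmittance
0.3, seed 42) where the loop converges in 6 iterations at tolerance
$10^{-3}$; end-to-end counting exactness is checked across 20 seeded
256×256 phantoms. These sizes were chosen so the full suite exercises
every code path at desk scale while remaining fast enough to run on every
change.

## Known limitations

* $z_2$ is a required input; there is no autofocus search, and no
  multi-height or multi-wavelength phase retrieval.
* The support constraint assumes absorbing objects (darker than the
  surround); pure-phase objects would need a different support rule.
* Watershed splitting assumes roughly convex objects and cannot separate
  centers closer than ≈ 1.2 radii (see above).
* The resolution score requires the phantom's layout metadata; it does not
  locate bar elements in arbitrary photographs.
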