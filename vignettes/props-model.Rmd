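---
title: "The props imaging model: geometry, simulation and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The props imaging model: geometry, simulation and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propsim)
```

## The imaging model

propsim models *projections with parameter selection* (props): single-shot
optical projection imaging in a scanned tilted-sheet geometry (oblique plane
microscopy, lattice light-sheet microscopy) in which a rolling shutter,
synchronized to the shear translation of the image across the camera,
selects which axial sub-volume contributes to the projection.

Coordinates and conventions, fixed throughout the package:

* `x` is the scan axis along the coverslip, `y` the sheet-invariant axis
  (camera columns), `z` the height above the coverslip. All lengths are in
  micrometers, times in seconds, angles in degrees. Volume arrays are
  indexed `(z, y, x)` with voxel-center continuous coordinates.
* The light sheet is a plane spanning `y` and the unit vector
  `(sin φ, 0, cos φ)`; `φ` is its tilt from the z-axis (`optics_config()`).
  The sheet and the conjugate focal plane move together along `x` during the
  focal sweep, `s(t)` linear in time (`sweep_config()`).
* Optical magnification is fixed at 1: the camera row coordinate `u` is
  expressed directly in sample-space micrometers. The instrument's actual
  magnification only rescales `u` and has no effect on the model.

A point at `(x, y, z)` is illuminated when the sheet passes through it, at
scan position `s = x − z·tan φ`, and images to camera row

```
u = z / cos φ + g(s),        g(s) = r·s + q(s) + b,
```

where `g` is the shear waveform (`shear_waveform()`): linear rate `r`,
nonlinear component `q(s)` (zero by default) and static offset `b`. A
synchronized rolling shutter (`shutter_config()`) keeps rows within `W/2` of
its center `u_sh(s) = r·s + c₀ + v_u·τ`, with `v_u = r·v_s` the row speed
and `τ` the shutter-versus-sweep delay.

The entire geometry follows from the **row residual**

```
u − u_sh = z / cos φ + q(s) + b − c₀ − v_u·τ,
```

which is independent of `x` and of `r`. With `q ≡ 0` the shutter therefore
admits exactly the slab

```
z_depth  = W · cos φ
z_center = (c₀ + v_u·τ − b) · cos φ
```

(`slab_bounds()`): the shutter width dials the projection depth, the delay
(or a row offset) moves the slab axially, and neither depends on the viewing
angle. The viewing angle is set by the shear rate alone: rows are constant
along sample lines `x = x₀ + z·tan ψ` with

```
tan ψ = tan φ − 1 / (r · cos φ)
```

(`viewing_angle()`, inverse `shear_rate_for_view()`); `r = 1/sin φ` is the
top-down view. Positive `τ` moves the slab toward +z and positive `ψ` tilts
the viewing direction toward +x; both signs are conventions of this package
(the geometry itself does not fix them) and are used consistently
everywhere.

### Frame coordinate

The simulator reports frames with the row coordinate `(u − b)/r`, i.e. in
sample-space micrometers. This applies the (trivial, global) scale component
of the shear-warp factorization's final 2D warp, and nothing else: without
it, frames acquired at different shear rates would live on laterally scaled
grids and could not be compared pixel-for-pixel with a digital rendering or
with each other. A structure at height `z` then appears at `x − z·tan ψ`.
The residual warp is an affine the package deliberately does not apply
(small angles; nothing downstream needs it).

### Curved-surface selection

With a nonlinear waveform the selected layer center varies during the sweep.
`design_shear_waveform()` solves the inverse problem for a target surface
`z*(x)`: each surface point is illuminated at `s(x) = x − z*(x)·tan φ`, and
provided

```
max |dz*/dx| · tan φ < 1
```

`s(x)` is strictly increasing, so the inverse map `x(s)` exists and

```
q(s) = c₀ + v_u·τ − b − z*(x(s)) / cos φ
```

holds the shutter center on the surface. The bound is a real optical
constraint, not a numerical convenience: beyond it, two surface points would
demand different shear values at the same scan position.

`predicted_surface()` inverts a given waveform back to the surface it
selects. The implicit per-x equation
`z/cos φ = C − q(x − z·tan φ)` could be iterated as a fixed point, but the
iteration map has derivative `−tan φ · z*′ / (1 − z*′·tan φ)`, which exceeds
1 in magnitude as soon as `z*′·tan φ > 1/2` — well inside the admissible
surface family — and there it oscillates without converging. The package
instead parameterizes the selection along the sweep, which is exact under
the same invertibility bound and needs no iteration: at scan position `s`
the shutter selects `z(s) = cos φ·(C − q(s))` at `x(s) = s + z(s)·tan φ`;
`x(s)` is strictly increasing, and `z_c(x)` is read off by monotone linear
interpolation on a dense `s` grid (4096 samples by default; the error is the
interpolation error of a smooth curve, far below the 0.5 µm round-trip
tolerance used in the tests).

A nonlinear waveform also perturbs the local effective shear rate to
`r + dq/ds`, hence the local viewing angle; `local_view_angle()` exposes
this as a diagnostic without asserting anything about it.

## The forward simulator

`simulate_projection()` integrates one camera exposure directly from the
model above (the hot loop is compiled C++). For each sweep step `s_k` and
each volume z-plane it samples the oblique sheet plane by linear
interpolation along x, computes the camera row, applies the shutter window
as a hard mask, and splats the sample linearly into the frame. Numerical
choices:

* **Sweep discretization.** `n_steps` defaults to one step per camera-row
  pixel of travel. Accumulation is scaled by `Δs/dx`, which makes the total
  collected intensity independent of the step size; a convergence test
  checks that halving the step changes frames by well under 1%. For a
  full-open, top-down acquisition the frame total equals the volume total to
  within interpolation losses (energy conservation, tested at 1%).
* **Interpolation.** Trilinear volume sampling (in practice: linear along x
  on each z-plane, since the sheet is y-invariant); out-of-volume samples
  read 0. Deposition uses linear splatting, which conserves mass exactly.
* **Shutter edge.** A hard binary mask at the sample level, membership on
  the closed interval; sub-row partial exposure is not modeled. This matches
  the renderer's hard slab, so the two pipelines select identical voxel
  sets. Ties exactly on a slab edge are included — deterministic, and
  irrelevant in practice because fixtures place edges between voxel centers.
* **Sheet profile.** Gaussian across the sheet with 1/e half-thickness
  `sheet_sigma`, discretized as 9 weighted sub-planes over ±3σ;
  `sheet_sigma = 0` is the ideal thin sheet. All geometry benchmarks use the
  thin sheet so slab edges are sharp.
* **Noise.** Optional, applied to the finished frame:
  `Poisson(photon_scale·v)/photon_scale + N(0, read_sigma) + offset`,
  seeded, with the caller's RNG state preserved.

Detection depth-of-focus blur is deliberately *not* modeled: in props the
projection depth is decoupled from the depth of focus, and modeling the
latter would only blur the quantity under study. Likewise there is no
aberration model and no non-Gaussian sheet.

`simulate_projection_sequence()` applies per-frame shutter delays cyclically
over a 3D+t movie — the interleaved two-slab acquisition used for two-layer
functional imaging — on a shared frame grid so the interleaved series stay
registered. `simulate_stack()` provides the conventional plane-by-plane
z-stack for data-size and projection-equivalence comparisons
(`data_size_ratio()`).

## The digital oracle

`slab_project()` is the post-hoc rendering analog: mask z-planes by slab
membership (hard, or a Gaussian window of matched FWHM, `σ = Δz/2.355`),
shear each plane by sampling at `x₀ + z·tan ψ`, reduce along z (sum, max or
mean). `curved_project()` reduces over `z*(x) ± half_width` and maps the
curved layer to a planar image with untransformed x. Because the renderer
never touches the sweep, the shutter or the waveform, it is an independent
check of the optical pipeline; the central equivalence property (NRMSE
< 0.05, bead centroids within half a pixel, across tilts, widths, delays
and shear rates) is asserted in the test suite, and on thin-sheet bead
phantoms the agreement is at machine precision.

## Phantoms: what they emulate, and what they do not

All generators are seeded (same seed → bit-identical output) and return
ground-truth tables sufficient for every recovery statistic downstream.

* `make_bead_phantom()` — isotropic Gaussian beads; `bead_ladder()` arranges
  prescribed z values at strictly distinct x positions, cycling a few y
  lanes so bead images never overlap in a frame.
* `make_vessel_phantom()` — smooth random tubes (cubic-spline center-lines,
  radius 2–4 µm) spanning the z-range: a vasculature stand-in with
  structure at every depth. No attempt at network topology realism.
* `make_shell_phantom()` — a cylindrically curved shell
  `z*(x) = z_bottom + R − sqrt(R² − (x − x_c)²)` (y-invariant, matching the
  one-dimensional shear) decorated with on-surface blobs and optional
  off-surface distractors, each flagged in the returned table. The default
  arc (R = 150 µm over a ±88 µm span, maximum slope 0.72) respects the
  invertibility bound at 45° tilt with margin.
* `make_calcium_phantom()` — two layers of soma-like Gaussian cells whose
  intensity follows `F(t) = F0·(1 + Σ A·k(t − t_k))` with the
  double-exponential kernel `k(t) = (1 − e^{−t/τ_r})·e^{−t/τ_d}`. Defaults
  `τ_r = 0.05 s`, `τ_d = 0.5 s`, `A = 0.5` resemble soma-targeted GCaMP
  kinetics at the 20–50 Hz frame rates the model targets; the kinetic form
  is this package's choice. Layer-2 cells sit on the midpoints of the
  layer-1 x grid (small jitter), keeping the two layers laterally
  distinguishable in projections — without this, randomly co-located cells
  make the layer-separation measurement ill-posed regardless of optics.
* `add_haze()` — a deliberately simple scattering surrogate: per-plane
  normalized Gaussian blur growing with depth (`σ(z) = σ₀ + k·z`) plus a
  uniform pedestal of `pedestal_frac ×` the plane mean. It reproduces the
  qualitative phenomenology that matters here (features wash out with
  depth, projections accumulate background that a narrow slab rejects); it
  is not a radiative-transfer model, so passing haze tests says nothing
  about quantitative scattering physics in real tissue.

More generally, the phantoms carry no detection PSF, no photobleaching and
no sample motion, so green tests demonstrate the *geometry and selection
logic* of props, not image quality on real specimens.

## Measurement methodology

The geometry benchmarks are measured, not computed: a bead counts as
*included* in a slab when its frame signal exceeds 50% of its signal in a
full-open-shutter acquisition of the same phantom (`measure_slab()`). The
signal is the intensity summed over a small window around the bead's
predicted position — a mass estimate, invariant to pixel-phase effects that
bias peak heights when bead size is below the pixel pitch. The 50% rule
makes the measurement robust to the bead's own axial extent: a bead centered
exactly on a slab edge retains exactly half its mass. Two quantization
effects bound the accuracy: the discrete z-grid moves the effective slab
edge to a half-voxel boundary (so fixtures use `dz` no larger than the
ladder step), and the ladder itself quantizes each edge by at most one bead
spacing. Benchmark ladders are designed so slab edges fall between both
grids.

dF/F uses a 20th-percentile baseline by default (robust for sparse
transients; a mean-over-window estimator is available), and is invariant to
global intensity scaling. Background subtraction removes the per-pixel
temporal median (or minimum) and clamps at zero by default — the
display-oriented convention; signed residuals are available. SBR is the
plain foreground/background mean ratio over disjoint masks. Galvo
calibration is ordinary least squares with residual diagnostics
(`calibrate_shear()`), as a linearity assessment of command-to-shift data.

## Problem sizes

The test suite and the benchmark script run on desk-scale phantoms chosen so
every quantity is still sharply measurable: ladders of 81–801 beads on
volumes from roughly 120×40×220 voxels (sub-micron voxels for the
2.5 µm-depth benchmark) up to 801×41×487 voxels at (0.5, 2, 2) µm for the
mesoscopic 362 µm-depth case; 48³–64³ volumes for the oracle-equivalence
grid (81 parameter combinations); and ~100-frame calcium movies at 50 Hz.
The full suite runs in seconds on one CPU.

## Known limitations

* Surfaces and shears are one-dimensional (`z*(x)`, y-invariant), matching
  single-galvo optics; 2D surface fitting is out of scope.
* Only synchronized shutters are modeled; the slab edges are hard at sample
  granularity (no sub-row exposure model).
* TIFF I/O stores 32-bit integer samples scaled by a power of two recorded
  in a JSON sidecar; round trips are exact to one part in 2³² of the scale,
  not bit-exact for arbitrary doubles.
* Structured-illumination reconstruction, hardware/DAQ control, and
  multi-photon background suppression are out of scope; only the slab
  selection geometry they would share is modeled.
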