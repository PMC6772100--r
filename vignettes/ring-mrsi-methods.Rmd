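---
title: "Concentric-ring MRSI reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentric-ring MRSI reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(ringmrsi)
```

## The problem

Magnetic resonance spectroscopic imaging (MRSI) resolves metabolite spectra
(tNAA near 2.01 ppm, tCr near 3.02 ppm, tCho near 3.2 ppm, lipids between
0.2 and 2.3 ppm) on a spatial grid. Concentric-ring trajectories acquire
this spatial-spectral dataset efficiently: each ring of k-space is
re-traversed every spectral dwell time, so one TR yields a full FID for an
entire ring. Scan time is then proportional to the number of rings, and the
natural acceleration strategy is to *leave rings out* and reconstruct them
with parallel imaging.

`ringmrsi` implements the full chain for this setting:

1. ring trajectories with iterative Pipe-Menon density compensation and
   Kaiser-Bessel convolution gridding,
2. a digital phantom and multichannel acquisition simulator, including
   interleaved / static / moved water-reference calibration scans,
3. constant- and variable-density ring undersampling,
4. hybrid through-time/through-k-space (tt/tk) GRAPPA reconstruction of the
   missing rings, direct or as a ladder of two-fold reconstructions,
5. MUSICAL-style coil combination with intrinsic zero-order prephasing,
6. an evaluation suite: pseudo-replica SNR and g-factor maps, percent RMSE
   against the fully sampled reference, residual-lipid maps and
   band-integrated metabolite maps.

## Trajectory and gridding

`make_ring_trajectory(n_rings, points_per_ring, matrix_size, fov)` places
ring i (1-based) at radius `(i - 0.5) / fov` cycles/mm - equidistant rings
with the first at half the Nyquist spacing - with an identical uniform
angular grid on every ring. `n_rings = matrix_size / 2` is
Nyquist-complete; rings beyond that are rejected. The identical angular
grid across rings is load-bearing: the GRAPPA kernel matches source and
target samples by angular index.

Gridding uses a Kaiser-Bessel kernel of width 3 on a two-fold oversampled
grid, with the kernel shape parameter from the standard Beatty formula and
deapodization by the kernel's analytic Fourier transform. Kernel spreading
wraps periodically at the grid boundary (the oversampled grid is an FFT
grid; clipping instead of wrapping costs several percent of accuracy for
samples near the Nyquist radius). The gridded adjoint agrees with a direct
adjoint-DFT oracle to well under 1% at desk scale; the forward model
(`image_to_rings`) is always the exact non-uniform DFT, evaluated in
memory-bounded chunks, so the simulator never inherits gridding error.

### Density compensation

`pipe_menon_dcf` runs the fixed point `w <- w / (w (*) C)` until
`max|w (*) C - 1| < tol` (defaults `n_iter = 30`, `tol = 1e-2`;
non-convergence returns the best iterate with a warning, never an error).
Two choices deserve explanation:

* **Kernel support.** The convolution kernel is the radial Kaiser-Bessel
  profile dilated so its support radius equals the ring spacing
  `1/fov`. Density must be measured on the scale of one Nyquist cell: a
  narrower kernel decouples the rings and under-resolves the angular
  direction on outer rings, a wider one couples several rings and inflates
  the weights of the k-space boundary rings. With this support the
  converged per-ring weights match the analytic annulus-area weights
  `2 pi r dk / points_per_ring` to better than 1% on all rings except the
  innermost (where the annulus rule itself breaks down at the k-space
  center; the innermost ring is excluded from that comparison).
  Because the angular grids are identical on all rings, the fixed point is
  solved exactly on the per-ring weight vector, making "weights constant
  along each ring" exact rather than approximate.

* **Normalization.** Weights are scaled so they sum to the fraction of
  Cartesian k-space area covered by the sampled disk,
  `pi n_rings^2 / matrix_size^2`. This is the quadrature-consistency
  condition: the density-compensated adjoint then reproduces the amplitude
  of compact objects exactly (a unit-amplitude Gaussian round-trips with
  unit peak height), which is the property the quantitative evaluation
  (%RMSE, SNR maps) rests on. A DC-anchored normalization (unit mean for
  the reconstruction of a uniform image) was evaluated and rejected: ring
  sampling reconstructs FOV-filling objects with an edge halo, which biases
  a DC anchor and scales compact-object amplitudes by about 0.65 at desk
  scale.

## The phantom and the forward model

`make_phantom` builds an ellipsoidal brain with a GM shell, WM interior,
two CSF "ventricles" and a 2-3 voxel subcutaneous lipid rim strictly
outside the brain mask, lightly jittered by its seed (deterministic given
the seed). Each compartment carries amplitudes for tNAA / tCr / tCho,
two lipid resonances (rim only) and water. Defaults that matter:

* **Water concentration is 100x the metabolites** (about 90-120 vs about
  0.2-1.2), as in tissue; the calibration scans observe only water and the
  MRSI scan only metabolites and lipids (water suppression is emulated as
  perfect).
* **Tissue-dependent relaxation**: every resonance's T2* is scaled per
  compartment (GM 1.0, WM 1.2, CSF 2.5, lipid 0.6). This is not cosmetic.
  A spatially uniform water T2* makes every calibration time frame a
  scalar multiple of the first, so through-time kernel repetitions add no
  information, the calibration design matrix becomes rank-deficient, and
  the GRAPPA weights memorize the calibration without generalizing.
  Relaxation heterogeneity is precisely what gives through-time
  calibration its diversity in vivo.
* **Lipid rim amplitude 5/10** (about 10x the metabolites), i.e. residual
  subcutaneous lipid. The package evaluates metabolite maps by spectral
  band integration (a deliberate substitute for model-based fitting, see
  below); with full-strength unsuppressed lipids the Lorentzian tails of
  the rim dominate every metabolite band and band integration stops being
  a usable proxy. Lipid-leakage *orderings* between configurations are
  unaffected by this amplitude.
* **B0 map defaults to zero**; off-resonance correction during gridding is
  not implemented (the GRAPPA comparison does not depend on it).

Coil sensitivities (`make_coil_profiles`) are complex Gaussian blobs on a
circle around the FOV with a random phase offset, a linear phase roll of
0.8 cycles per FOV away from each coil, and mild quadratic curvature. The
localization and phase roll give the sensitivities a k-space footprint on
the order of one ring spacing; that footprint is what permits *any*
coil-based method to move information across rings. Very broad, phase-flat
profiles make ring interpolation ill-posed regardless of the algorithm -
an 8-channel desk-scale array must be tight to be informative, just as a
real 32-channel array is.

`acquire` evaluates the exact NUDFT of sensitivity-weighted FID cubes at
every ring sample and adds seeded i.i.d. complex Gaussian noise
(`E|n|^2 = noise_sd^2`). The default `noise_sd = 0.5` puts the combined
spectral SNR of the desk phantom near 20, matching the regime the method
is used in. Calibration scans are the same operation with 27 spectral
points and flip-angle scaling `sin(flip)/sin(42 deg)` (5 deg for the
interleaved calibration, 13 deg for the static/moved prescans). The
"moved" prescan rotates the phantom (default 15 deg, bilinear
interpolation, masks re-derived) while the coil array stays fixed in the
scanner frame - which is what a head rotation does.

## Undersampling

`make_pattern(n_rings, nominal_R, n_full_inner)` keeps the innermost
`n_full_inner` rings (5 by default for variable-density patterns; 0 gives
constant density) and every `nominal_R`-th of the remaining outer rings,
starting after skipping `nominal_R - 1`. The effective acceleration is the
ring-count ratio, since scan time is proportional to measured rings: on 32
rings with a 5-ring core this gives R_eff = 32/18 = 1.78 for two-fold and
32/11 = 2.91 for four-fold undersampling. The "skip R-1 then keep" outer
phase is the convention that reproduces those ring counts; starting parity
is otherwise immaterial to R_eff.

## tt/tk-GRAPPA

Each missing sample is reconstructed independently from six source points:
three angular neighbors (centered on the target's angular index, circular
wrap) on each of the nearest measured rings below and above. At the
k-space boundary the two nearest measured rings on the available side are
used instead and the target is flagged. Weights are trained on the
fully sampled calibration scan by sliding the same kernel through a
15 x 4 (points x rings) segment centered on the target - ring placements
mirror the target kernel's ring offsets exactly and never wrap across the
k-space center, point placements wrap along the ring - giving
13 x 3 = 39 spatial repetitions, multiplied by the first 21 calibration
time points for 819 kernel occurrences. The solve refuses to run (unless
forced) if the repetitions do not reach the number of unknowns per target
coil, `6 x n_coils` (192 for a 32-channel array; 48 at desk scale).

The per-target complex least-squares problem is solved by SVD, which
yields the minimum-norm solution and handles rank-deficient systems
transparently (flagged in the diagnostics); a Tikhonov path through the
normal equations is available via `lambda > 0` but the default is plain
least squares. Weights depend only on the calibration data; the same
weights fill every spectral time point of the FID, and the fill at time t
uses only measured samples at time t.

The first `n_time_points` calibration FID points are used as through-time
repetitions (the earliest points have the highest SNR); `n_time_points`
defaults to 21 of the 27 calibration points.

For four- and eight-fold undersampling, `reconstruct_recursive` walks a
ladder of consecutive two-fold reconstructions (R = 8 -> 4 -> 2 -> full),
re-solving weights at each stage against the same calibration with the
same geometry; `recursive = FALSE` gives the direct single-kernel
reconstruction. On the desk phantom the recursive ladder is slightly more
accurate than the direct solve, and %RMSE grows monotonically with
acceleration - both orderings are asserted by the test suite rather than
quoted here.

## Coil combination

`weights_from_calibration` grids the first calibration time point of each
coil to `U_c` and forms `w_c = conj(U_c) / sum_c |U_c|^2`, zeroing voxels
whose root-sum-of-squares falls below 5% of its maximum. Combining the
calibration with its own weights gives identically 1 inside the mask, so
the combined data inherit a zero-order prephase: any signal sharing the
water phase at t = 0 combines real-positive. The `sum |U|^2` normalization
makes the combined amplitude water-referenced (metabolite over water),
which removes coil shading; the root-sum-of-squares alternative can be
selected by post-hoc rescaling but is not the default. Noise prewhitening
is off by default (the simulator's coil noise is white); the noise
covariance slot in the coil profiles is the hook for it. Combination runs
in the image domain after GRAPPA and gridding, matching the pipeline order
of the acquisition it models (parallel imaging in k-space first).

## Evaluation

* `pseudo_replica` adds seeded complex noise to the measured samples,
  reruns the supplied reconstruction closure per replica, and reports the
  per-voxel complex standard deviation and SNR = |mean|/sd. Because the
  whole reconstruction is rerun, noise propagation through GRAPPA and
  combination is captured exactly. Default 50 replicas at desk scale.
* `g_factor` is `SNR_full / (SNR_PI * sqrt(R_total))` with `R_total` the
  pattern's effective (ring-count) acceleration; non-positive-SNR voxels
  are masked and counted rather than propagated.
* `percent_rmse` is the global-l2 form `100 ||map - ref|| / ||ref||` over
  a mask. Reconstructions are referenced against the fully sampled
  reconstruction combined with the *matching* calibration, except that
  moved-prescan reconstructions are referenced against the static-prescan
  gold standard (the moved calibration cannot define its own truth).
* `metabolite_maps` integrates spectral magnitude over fixed bands (tNAA
  1.9-2.1, tCr 2.9-3.1, tCho 3.1-3.3 ppm) and forms tCho/tCr where the
  denominator exceeds a floor. Band integration deliberately replaces
  model-based spectral fitting: it is linear, assumption-free and fast,
  at the price of truncation-sidelobe leakage between bands (about 7%
  between well-separated resonances at 64 spectral points) and
  sensitivity to baseline contamination.
* `lipid_map` integrates 0.2-2.3 ppm and normalizes by the median tCr of
  the fully sampled reference, making lipid leakage comparable across
  calibration and acceleration configurations.

## Problem sizes

The default **desk** configuration is a 32 x 32 matrix, 16 rings,
128 points/ring, 8 coils, 64 spectral points at 2778 Hz bandwidth, 220 mm
FOV, calibration with 27 spectral points. A full
simulate-undersample-reconstruct-combine-evaluate pass takes seconds to a
couple of minutes on one CPU, which is what allows the test suite to
exercise every ordering on freshly simulated data. The **full**
configuration (64 x 64, 32 rings, 540 points/ring, 32 coils, 882 spectral
points) carries the full-scale acquisition geometry; its exact forward
model is memory-chunked but its runtime is minutes-to-hours, so no test
depends on it.

## What the simulations do and do not show

The phantom exercises the reconstruction algebra end to end: trajectory,
density compensation, gridding, undersampling, weight training on a
separate water-reference scan, recursive application, combination and
noise propagation. It does not emulate B0 inhomogeneity, intra-scan
motion, macromolecular baselines, eddy currents, gradient imperfections,
chemical-shift displacement or T1 saturation differences between the
calibration modes (the TR difference between interleaved and prescan
calibrations enters only as the flip-angle amplitude factor). Passing
tests therefore demonstrate correctness of the method's implementation
and the qualitative orderings it predicts (error vs acceleration,
matched vs rotated calibration, recursion vs direct), not in vivo
performance figures.

## Container and interfaces

All pipeline stages exchange a single versioned container file written
with R's native serialization (`save_container` / `load_container`):
arrays, trajectories, patterns, weights, maps, configuration, seed and a
log round-trip bitwise, corrupted or truncated files fail with a named
integrity error, and a version field guards against format drift. Image
maps export to NIfTI via `export_nifti`. The command line
(`inst/cli/ringmrsi.R`, a thin wrapper over `mrsi_cli()`) chains
`simulate`, `undersample`, `reconstruct`, `combine`, `evaluate` and
`report`; every output container embeds the configuration and seed that
produced it. The embedded creation timestamp is the one field excluded
from byte-level determinism; object-level content is reproducible from
the seed alone.
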