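# ringmrsi

Reconstruction toolkit for **MR spectroscopic imaging (MRSI) on
concentric-ring k-space trajectories**, with accelerated acquisition by
ring undersampling and **hybrid through-time/through-k-space (tt/tk)
GRAPPA** reconstruction, water-reference (MUSICAL-style) coil combination,
and a complete simulation + evaluation environment.

## Who this is for

Concentric-ring MRSI encodes space and spectrum simultaneously: every
spectral dwell re-traverses one ring, so one TR yields the full FID of a
ring and scan time scales with the number of rings. Accelerating the scan
means *discarding rings* and synthesizing them from the measured
neighbors. `ringmrsi` is for researchers developing or evaluating such
reconstructions who need a fully controlled, ground-truth-bearing
environment: every stage of the in vivo pipeline is reproduced on a
digital phantom, so reconstruction algebra, calibration strategies and
noise propagation can be studied quantitatively without scanner data.

## The method

**Sampling.** `n` equidistant rings, ring *i* at radius `(i - 1/2)/FOV`
(first ring at half the Nyquist spacing), identical angular grids on all
rings. Gridding uses iterative Pipe–Menon density compensation
(`w ← w / (w ⊛ C)`) and Kaiser–Bessel convolution gridding (kernel width
3, two-fold oversampling).

**Undersampling.** Constant density (every R-th ring) or variable density
(innermost 5 rings always measured, constant undersampling outside). The
effective acceleration is the ring-count ratio; on 32 rings with a 5-ring
core, nominal R = 2 and 4 give R_eff = **1.78** and **2.91**.

**Reconstruction.** Each missing sample is predicted from a 3 × 2 kernel —
three angular neighbors on the nearest measured ring on each side — with
per-target complex weights `W = argmin ‖SW − T‖₂` trained on a fully
sampled, low-flip-angle water-reference calibration. Kernel repetitions
are harvested through k-space (a 15 × 4 segment slid 13 × 3 = 39 ways)
**and** through time (21 calibration FID points), giving 819 equations
against `6 × n_coils` unknowns per target coil. Four- and eight-fold
undersampling can be reconstructed directly or as consecutive two-fold
stages (recursive ladder).

**Combination.** Coil images are combined with
`w_c = conj(U_c) / Σ|U_c|²`, where `U_c` is the gridded first calibration
time point — simultaneously phasing every spectrum to the water reference
at t = 0 (intrinsic zero-order prephasing).

**Evaluation.** Pseudo-replica Monte-Carlo SNR maps and the g-factor
`g = SNR_full / (SNR_PI √R_total)`; percent RMSE
`100·‖map − ref‖₂/‖ref‖₂` of band-integrated metabolite maps (tNAA, tCr,
tCho) against the fully sampled reference; residual-lipid integrals over
0.2–2.3 ppm normalized to the median reference tCr.

## Worked example

```r
library(ringmrsi)

# the printed pattern arithmetic of the full-scale geometry
make_pattern(n_rings = 32, nominal_R = 2, n_full_inner = 5)
#> undersampling_pattern: 32 rings, nominal R = 2, 5-ring core, 18 measured, effective R = 1.78
count_repetitions(grappa_geometry())
#> spatial   total
#>      39     819

# simulate a desk-scale study and reconstruct a two-fold variable-density scan
cfg   <- mrsi_config("desk")          # 32x32, 16 rings, 8 coils, 64 spectral pts
study <- simulate_study(cfg, seed = 1)
pattern   <- make_pattern(16, 2, 5)
result    <- run_recon(study, pattern, calib_mode = "imusical")
reference <- run_recon(study, NULL,    calib_mode = "imusical")
metrics   <- evaluate_recon(study, result, reference,
                            with_g = TRUE, n_replicas = 50, seed = 3)
```

This prints (seed 1):

```
effective R: 1.60
%RMSE  tNAA 8.8  tCr 7.9  tCho 7.4
mean g-factor: 1.03   in-brain lipid integral: 5.01
```

Read: discarding 6 of 16 rings (a 1.6-fold scan-time saving) costs 7–9%
RMSE on the metabolite maps relative to the fully sampled reconstruction;
the mean g-factor of 1.03 says the reconstruction loses almost no SNR
beyond the unavoidable `√R` sampling penalty; the lipid integral is
compared across configurations (e.g. matched vs motion-corrupted
calibration) to quantify lipid leakage.

## Command line

A thin CLI over the same functions lives at `inst/cli/ringmrsi.R`:

```sh
Rscript inst/cli/ringmrsi.R simulate    --preset desk --seed 1 --out sim.rds
Rscript inst/cli/ringmrsi.R undersample --in sim.rds --pattern 16:2:5 --out und.rds
Rscript inst/cli/ringmrsi.R reconstruct --in und.rds --out rec.rds
Rscript inst/cli/ringmrsi.R combine     --in rec.rds --out cmb.rds --nifti maps/
Rscript inst/cli/ringmrsi.R evaluate    --in cmb.rds --out ev.rds --json metrics.json
Rscript inst/cli/ringmrsi.R report      --in ev.rds
```

Each stage reads and writes a single versioned container (R serialization;
`load_container(save_container(x)) == x` bitwise) that embeds the exact
configuration and seed that produced it. Image maps export to NIfTI.

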