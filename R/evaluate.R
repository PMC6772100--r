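#' Pseudo-replica noise and SNR maps
#'
#' Monte-Carlo noise propagation: adds `n_replicas` independent complex
#' Gaussian noise realizations of standard deviation `noise_sd` to the
#' measured samples of `ksp`, runs `recon_fn` on each replica, and returns
#' the per-voxel complex standard deviation of the reconstructed signal and
#' `SNR = |mean| / sd`. Because the noise is injected and the
#' reconstruction is rerun in full, the maps capture noise propagation
#' through every reconstruction step, including GRAPPA.
#'
#' @param recon_fn function `ring_kspace -> complex image` (deterministic).
#' @param ksp input k-space; noise is added only on measured rings.
#' @param noise_sd injected complex noise standard deviation.
#' @param n_replicas number of replicas (>= 8 for usable maps; >= 2 hard
#'   minimum).
#' @param seed RNG seed for the replica noise.
#' @return list with `noise_map`, `snr_map`, `mean_map`, `n_replicas`.
#' @export
pseudo_replica <- function(recon_fn, ksp, noise_sd, n_replicas = 50,
                           seed = 1) {
  stopifnot(is.function(recon_fn), inherits(ksp, "ring_kspace"),
            noise_sd > 0)
  if (n_replicas < 2) stop("n_replicas must be >= 2")
  meas <- ksp$measured_rings
  n_meas <- sum(meas) * ksp$traj$points_per_ring * ksp$n_coils * ksp$n_spec
  imgs <- with_seed(seed, {
    lapply(seq_len(n_replicas), function(j) {
      kj <- ksp
      kj$data[, meas, , ] <- kj$data[, meas, , , drop = FALSE] +
        array(complex_noise(n_meas, noise_sd),
              c(ksp$n_coils, sum(meas), ksp$traj$points_per_ring,
                ksp$n_spec))
      recon_fn(kj)
    })
  })
  arr <- simplify2array(imgs)
  dm <- dim(arr)
  nd <- length(dm)
  mean_map <- apply(arr, seq_len(nd - 1L), mean)
  # complex std: sqrt(E |x - mean|^2), unbiased
  dev2 <- Mod(sweep(arr, seq_len(nd - 1L), mean_map, "-"))^2
  noise_map <- sqrt(apply(dev2, seq_len(nd - 1L), sum) / (n_replicas - 1L))
  list(noise_map = noise_map, mean_map = mean_map,
       snr_map = Mod(mean_map) / noise_map, n_replicas = n_replicas)
}

#' g-factor map of a parallel-imaging reconstruction
#'
#' `g = SNR_full / (SNR_PI * sqrt(R_total))`, elementwise inside the mask:
#' the SNR loss of the accelerated reconstruction beyond the intrinsic
#' `sqrt(R)` sampling penalty.
#'
#' @param snr_full,snr_pi per-voxel SNR maps of the fully sampled and
#'   accelerated reconstructions (e.g. from [pseudo_replica()]).
#' @param r_total effective acceleration factor of the pattern.
#' @param mask logical image restricting the map (default: voxels where
#'   both SNRs are positive and finite).
#' @return object of class `gfactor_map`: `g`, `mask`, `r_total`,
#'   `n_dropped` (voxels masked for non-positive SNR).
#' @export
g_factor <- function(snr_full, snr_pi, r_total, mask = NULL) {
  stopifnot(identical(dim(snr_full), dim(snr_pi)), r_total >= 1)
  ok <- is.finite(snr_full) & is.finite(snr_pi) & snr_pi > 0 & snr_full > 0
  if (is.null(mask)) mask <- ok
  n_dropped <- sum(mask & !ok)
  mask <- mask & ok
  g <- array(NA_real_, dim(snr_full))
  g[mask] <- snr_full[mask] / (snr_pi[mask] * sqrt(r_total))
  structure(list(g = g, mask = mask, r_total = r_total,
                 n_dropped = n_dropped),
            class = "gfactor_map")
}

#' @export
print.gfactor_map <- function(x, ...) {
  cat(sprintf(
    "gfactor_map: R_total = %.2f, mean g = %.3f, median g = %.3f over %d voxels\n",
    x$r_total, mean(x$g[x$mask]), median(x$g[x$mask]), sum(x$mask)))
  invisible(x)
}

#' Percent root-mean-square error of a map against a reference
#'
#' `100 * ||map - ref||_2 / ||ref||_2` over the mask (global l2
#' normalization).
#'
#' @param map,ref_map numeric images of identical shape.
#' @param mask logical image (default: everywhere).
#' @return scalar %RMSE.
#' @export
percent_rmse <- function(map, ref_map, mask = NULL) {
  stopifnot(identical(dim(map), dim(ref_map)))
  if (is.null(mask)) mask <- array(TRUE, dim(map))
  if (!any(mask)) stop("mask is empty")
  ref <- ref_map[mask]
  nrm <- sqrt(sum(Mod(ref)^2))
  if (nrm == 0) stop("reference map is zero over the mask")
  100 * sqrt(sum(Mod(map[mask] - ref)^2)) / nrm
}

## ---- spectra --------------------------------------------------------------

#' Frequency and ppm axes of a spectral reconstruction
#'
#' The spectrum is the centered DFT of the FID; frequency bin k (0-based,
#' after fftshift) sits at `(k - n/2) / (n * dwell)` Hz and
#' `carrier_ppm + f / f0_mhz` ppm.
#'
#' @param n_spec spectral points; `dwell` dwell time in s.
#' @param carrier_ppm carrier position (default 4.7, water).
#' @param f0_mhz proton frequency in MHz (default 297.2, 7 T).
#' @return list with `hz` and `ppm` vectors of length `n_spec`.
#' @export
ppm_axis <- function(n_spec, dwell, carrier_ppm = 4.7, f0_mhz = 297.2) {
  hz <- ((seq_len(n_spec) - 1) - n_spec %/% 2) / (n_spec * dwell)
  list(hz = hz, ppm = carrier_ppm + hz / f0_mhz)
}

#' Spatial-spectral FID cube to spectra
#'
#' Centered DFT along the spectral (last) dimension.
#'
#' @param combined complex array `(N, N, n_spec)`.
#' @return complex array `(N, N, n_spec)` ordered to match [ppm_axis()].
#' @export
fid_to_spectra <- function(combined) {
  dm <- dim(combined)
  nt <- dm[length(dm)]
  M <- matrix(combined, prod(dm[-length(dm)]), nt)
  sp <- t(stats::mvfft(t(M)))
  sp <- sp[, fftshift_idx(nt), drop = FALSE]
  array(sp, dm)
}

band_columns <- function(ppm, band) {
  which(ppm >= min(band) & ppm <= max(band))
}

# integrate spectral magnitude over a ppm band
band_integral <- function(spectra, ppm, band) {
  cols <- band_columns(ppm, band)
  if (!length(cols))
    stop("ppm axis [", signif(min(ppm), 3), ", ", signif(max(ppm), 3),
         "] does not cover the band [", band[1], ", ", band[2], "]")
  dm <- dim(spectra)
  apply(Mod(spectra[, , cols, drop = FALSE]), c(1, 2), sum)
}

#' Band-integrated metabolite maps and ratio maps
#'
#' Replaces model-based spectral fitting with simple magnitude integration
#' over fixed ppm bands (defaults: tNAA 1.9-2.1, tCr 2.9-3.1,
#' tCho 3.1-3.3 ppm) and forms the tCho/tCr ratio map where the
#' denominator is above `ratio_floor` times its in-mask median.
#'
#' @param combined combined spatial-spectral FID cube `(N, N, n_spec)`.
#' @param dwell spectral dwell time (s).
#' @param bands named list of `c(lo, hi)` ppm bands.
#' @param mask logical image for ratio flooring (default: all voxels).
#' @param ratio_floor relative denominator floor (default 0.2).
#' @param carrier_ppm,f0_mhz spectral axis parameters.
#' @return object of class `metabolic_map`: `maps` (named list of images),
#'   `ratios` (tCho/tCr when both bands present), `mask`.
#' @export
metabolite_maps <- function(combined, dwell,
                            bands = list(tNAA = c(1.9, 2.1),
                                         tCr = c(2.9, 3.1),
                                         tCho = c(3.1, 3.3)),
                            mask = NULL, ratio_floor = 0.2,
                            carrier_ppm = 4.7, f0_mhz = 297.2) {
  dm <- dim(combined)
  ax <- ppm_axis(dm[3], dwell, carrier_ppm, f0_mhz)
  lohi <- vapply(bands, range, numeric(2))
  ov <- FALSE
  if (length(bands) > 1) {
    o <- order(lohi[1, ])
    ov <- any(lohi[1, o][-1] < lohi[2, o][-length(bands)])
  }
  if (ov) warning("metabolite integration bands overlap")
  spectra <- fid_to_spectra(combined)
  maps <- lapply(bands, function(b) band_integral(spectra, ax$ppm, b))
  if (is.null(mask)) mask <- array(TRUE, dm[1:2])
  ratios <- list()
  if (all(c("tCho", "tCr") %in% names(maps))) {
    den <- maps$tCr
    floorv <- ratio_floor * median(den[mask])
    ok <- mask & den > floorv
    rmap <- array(NA_real_, dm[1:2])
    rmap[ok] <- maps$tCho[ok] / den[ok]
    ratios$tCho_tCr <- rmap
  }
  structure(list(maps = maps, ratios = ratios, mask = mask, ppm = ax$ppm),
            class = "metabolic_map")
}

#' Residual-lipid integral map
#'
#' Integrates the spectral magnitude of each voxel over 0.2-2.3 ppm and
#' normalizes by the median tCr amplitude of the fully sampled reference
#' reconstruction, making lipid leakage comparable across calibration and
#' acceleration configurations.
#'
#' @param combined combined spatial-spectral FID cube.
#' @param dwell spectral dwell time (s).
#' @param tcr_ref tCr amplitude image of the fully sampled reference
#'   reconstruction.
#' @param mask logical image over which the median tCr is taken (brain
#'   mask); default all voxels.
#' @param band integration band in ppm (default `c(0.2, 2.3)`).
#' @param carrier_ppm,f0_mhz spectral axis parameters.
#' @return numeric image of normalized lipid integrals.
#' @export
lipid_map <- function(combined, dwell, tcr_ref, mask = NULL,
                      band = c(0.2, 2.3), carrier_ppm = 4.7,
                      f0_mhz = 297.2) {
  dm <- dim(combined)
  if (is.null(mask)) mask <- array(TRUE, dm[1:2])
  ax <- ppm_axis(dm[3], dwell, carrier_ppm, f0_mhz)
  if (min(ax$ppm) > band[1] || max(ax$ppm) < band[2])
    stop("spectral bandwidth does not cover the ", band[1], "-", band[2],
         " ppm lipid band")
  med_tcr <- median(tcr_ref[mask])
  if (!is.finite(med_tcr) || med_tcr <= 0)
    stop("median reference tCr is not positive")
  band_integral(fid_to_spectra(combined), ax$ppm, band) / med_tcr
}

#' Export an image map as NIfTI
#'
#' @param map numeric image (2D) or array (3D).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size in mm (scalar, default 1).
#' @return the path, invisibly.
#' @export
export_nifti <- function(map, path, voxel_mm = 1) {
  img <- RNifti::asNifti(map, pixdim = rep(voxel_mm, length(dim(map))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
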