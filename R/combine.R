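#' MUSICAL-style coil combination weights from a water-reference calibration
#'
#' Grids the first spectral time point of each calibration coil to an image
#' `U_c` and forms per-voxel combination weights
#' `w_c = conj(U_c) / sum_c |U_c|^2`. Combining any dataset whose t = 0
#' phase matches the calibration's therefore yields a real-positive first
#' time point inside the mask (intrinsic zero-order prephasing), and the
#' `sum |U|^2` normalization corrects the coil sensitivity magnitude.
#' Voxels whose root-sum-of-squares falls below `floor_frac` of its maximum
#' are zeroed and excluded from the mask.
#'
#' @param calib fully sampled calibration `ring_kspace`.
#' @param dcf density weights for the gridding.
#' @param floor_frac relative root-sum-of-squares floor (default 0.05).
#' @param gridder optional precomputed [make_gridder()].
#' @return object of class `combination_weights`: `weights` complex
#'   `(N, N, n_coils)`, `mask`, `norm_mode`, `source`.
#' @export
weights_from_calibration <- function(calib, dcf, floor_frac = 0.05,
                                     gridder = NULL) {
  stopifnot(inherits(calib, "ring_kspace"))
  if (!all(calib$measured_rings))
    stop("calibration dataset must be fully sampled")
  if (all(calib$data == 0)) stop("calibration data are identically zero")
  nc <- calib$n_coils
  N <- calib$traj$matrix_size
  # (ring, point, coil) block of the first spectral time point
  s1 <- aperm(calib$data[, , , 1, drop = FALSE], c(2, 3, 1, 4))
  dim(s1) <- c(calib$traj$n_rings, calib$traj$points_per_ring, nc)
  U <- grid_to_image(s1, calib$traj, dcf, gridder = gridder)
  ssq <- apply(Mod(U)^2, c(1, 2), sum)
  mask <- sqrt(ssq) > floor_frac * max(sqrt(ssq))
  w <- array(0i, c(N, N, nc))
  for (cc in seq_len(nc)) {
    wc <- Conj(U[, , cc]) / ssq
    wc[!mask] <- 0i
    w[, , cc] <- wc
  }
  structure(list(weights = w, mask = mask, norm_mode = "ssq",
                 source = calib$meta$source %||% "unknown",
                 calib_image = U),
            class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat(sprintf(
    "combination_weights (%s calibration, norm '%s'): %d coils, %d voxels in mask\n",
    x$source, x$norm_mode, dim(x$weights)[3], sum(x$mask)))
  invisible(x)
}

#' Combine per-coil spatial-spectral images
#'
#' `s(x, t) = sum_c w_c(x) m_c(x, t)`; linear in the input.
#'
#' @param mrsi_images complex array `(N, N, n_coils)` or
#'   `(N, N, n_coils, n_spec)`.
#' @param weights a [weights_from_calibration()] result.
#' @return combined complex array `(N, N)` or `(N, N, n_spec)`.
#' @export
combine_coils <- function(mrsi_images, weights) {
  stopifnot(inherits(weights, "combination_weights"))
  dm <- dim(mrsi_images)
  dw <- dim(weights$weights)
  if (is.null(dm) || length(dm) < 3L || any(dm[1:3] != dw))
    stop("images shaped (", paste(dm, collapse = ", "),
         ") do not match weights (", paste(dw, collapse = ", "), ")")
  nc <- dw[3]
  nt <- if (length(dm) == 4L) dm[4] else 1L
  out <- array(0i, c(dm[1], dm[2], nt))
  M <- array(mrsi_images, c(dm[1], dm[2], nc, nt))
  for (cc in seq_len(nc)) {
    Mc <- M[, , cc, , drop = FALSE]
    dim(Mc) <- c(dm[1], dm[2], nt)
    out <- out + as.vector(weights$weights[, , cc]) * Mc
  }
  if (length(dm) == 3L) dim(out) <- dm[1:2]
  out
}

#' Grid and combine a full multichannel spatial-spectral k-space
#'
#' Convenience pipeline step: grids every coil and spectral time point of
#' `ksp` and applies the combination weights, yielding the combined
#' spatial-spectral image cube.
#'
#' @param ksp fully sampled (or reconstructed) `ring_kspace`.
#' @param weights combination weights.
#' @param dcf density compensation.
#' @param gridder optional precomputed gridder.
#' @return complex array `(N, N, n_spec)`.
#' @export
recon_combined <- function(ksp, weights, dcf, gridder = NULL) {
  stopifnot(inherits(ksp, "ring_kspace"))
  if (is.null(gridder)) gridder <- make_gridder(ksp$traj)
  # reorder to (ring, point, coil, time) and grid in one batch
  s <- aperm(ksp$data, c(2, 3, 1, 4))
  imgs <- grid_to_image(s, ksp$traj, dcf, gridder = gridder)
  combine_coils(imgs, weights)
}
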