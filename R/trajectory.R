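#' Build a concentric-ring k-space trajectory
#'
#' Constructs the sampling geometry used throughout the package: `n_rings`
#' equidistant circles in k-space with the first ring at half the Nyquist
#' ring spacing, i.e. radius of ring i (1-based) is `(i - 0.5) / fov`
#' cycles/mm, and an identical uniform angular grid on every ring.
#'
#' With `n_rings = matrix_size / 2` the outermost ring sits just inside the
#' Nyquist radius `kmax = matrix_size / (2 * fov)` and the trajectory is
#' Nyquist-complete for the target matrix.
#'
#' @param n_rings number of rings (>= 1, at most `matrix_size / 2`).
#' @param points_per_ring samples per ring (>= 4), equal on all rings.
#' @param matrix_size target Cartesian matrix edge (even).
#' @param fov field of view in mm.
#' @return An object of class `ring_trajectory` with fields `n_rings`,
#'   `points_per_ring`, `matrix_size`, `fov`, `ring_radii` (cycles/mm),
#'   `angles` (radians), `kmax` and `delta_k`.
#' @examples
#' traj <- make_ring_trajectory(16, 128, 32, 200)
#' traj$ring_radii[1] * 200  # first ring at half the Nyquist spacing
#' @export
make_ring_trajectory <- function(n_rings, points_per_ring, matrix_size, fov) {
  stopifnot(length(n_rings) == 1L, n_rings >= 1,
            length(points_per_ring) == 1L, points_per_ring >= 4,
            length(matrix_size) == 1L, matrix_size >= 2,
            length(fov) == 1L, fov > 0)
  n_rings <- as.integer(n_rings)
  points_per_ring <- as.integer(points_per_ring)
  matrix_size <- as.integer(matrix_size)
  if (matrix_size %% 2L != 0L)
    stop("matrix_size must be even, got ", matrix_size)
  if (n_rings > matrix_size / 2)
    stop("n_rings = ", n_rings, " places rings beyond the Nyquist radius for a ",
         matrix_size, "x", matrix_size, " matrix (maximum is ",
         matrix_size %/% 2L, ")")
  delta_k <- 1 / fov
  structure(list(
    n_rings = n_rings,
    points_per_ring = points_per_ring,
    matrix_size = matrix_size,
    fov = fov,
    delta_k = delta_k,
    ring_radii = (seq_len(n_rings) - 0.5) * delta_k,
    angles = 2 * pi * (seq_len(points_per_ring) - 1L) / points_per_ring,
    kmax = matrix_size / (2 * fov)
  ), class = "ring_trajectory")
}

#' @export
print.ring_trajectory <- function(x, ...) {
  cat(sprintf(
    "ring_trajectory: %d rings x %d points (%d samples), matrix %dx%d, FOV %g mm\n",
    x$n_rings, x$points_per_ring, x$n_rings * x$points_per_ring,
    x$matrix_size, x$matrix_size, x$fov))
  cat(sprintf("  ring radii %.4g .. %.4g cycles/mm (kmax %.4g)\n",
              x$ring_radii[1], x$ring_radii[x$n_rings], x$kmax))
  invisible(x)
}

# kx/ky sample coordinates as (n_rings x points_per_ring) matrices
traj_kcoords <- function(traj) {
  list(kx = outer(traj$ring_radii, cos(traj$angles)),
       ky = outer(traj$ring_radii, sin(traj$angles)))
}

# voxel center coordinates in mm, 0-based index n -> (n - N/2) * fov / N
voxel_coords <- function(matrix_size, fov) {
  ((seq_len(matrix_size) - 1L) - matrix_size / 2) * fov / matrix_size
}

## ---- Kaiser-Bessel kernel -------------------------------------------------

# Beatty et al. beta for given kernel width (grid units) and oversampling
kb_beta <- function(width, os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

# Kernel value at offset u (grid units); support |u| < width/2
kb_kernel <- function(u, width, beta) {
  out <- numeric(length(u))
  inside <- abs(u) < width / 2
  arg <- 1 - (2 * u[inside] / width)^2
  out[inside] <- besselI(beta * sqrt(pmax(arg, 0)), 0) / besselI(beta, 0)
  out
}

# Fourier transform of the kernel at normalized frequency f (cycles per
# grid unit); used for deapodization.
kb_ft <- function(f, width, beta) {
  z2 <- beta^2 - (pi * width * f)^2
  out <- numeric(length(f))
  pos <- z2 > 0
  z <- sqrt(abs(z2))
  out[pos] <- sinh(z[pos]) / z[pos]
  out[!pos] <- ifelse(z[!pos] == 0, 1, sin(z[!pos]) / z[!pos])
  width * out / besselI(beta, 0)
}

## ---- centered FFT helpers -------------------------------------------------

fftshift_idx <- function(n) c((n %/% 2 + 1L):n, 1L:(n %/% 2))

fftshift2 <- function(m) {
  m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
}

# centered 2D inverse DFT (unnormalized sum), even dimensions
ifft2c <- function(m) fftshift2(fft(fftshift2(m), inverse = TRUE))

# centered 2D forward DFT
fft2c <- function(m) fftshift2(fft(fftshift2(m)))

## ---- gridder --------------------------------------------------------------

#' Precompute a Kaiser-Bessel gridding operator for a ring trajectory
#'
#' Builds the sparse interpolation matrix that spreads ring samples onto a
#' `oversampling`-times oversampled Cartesian k-space grid, together with the
#' deapodization image. Passing the result to [grid_to_image()] avoids
#' rebuilding the operator for every coil/time frame.
#'
#' @param traj a [make_ring_trajectory()] object.
#' @param oversampling grid oversampling factor (default 2).
#' @param kb_width kernel width in oversampled grid cells (default 3).
#' @return list with the sparse spreading matrix and deapodization terms.
#' @export
make_gridder <- function(traj, oversampling = 2, kb_width = 3) {
  stopifnot(inherits(traj, "ring_trajectory"), oversampling >= 1.25,
            kb_width >= 2)
  N <- traj$matrix_size
  G <- as.integer(round(oversampling * N))
  beta <- kb_beta(kb_width, oversampling)
  kc <- traj_kcoords(traj)
  # 0-based fractional grid coordinates on the oversampled grid
  ux <- as.vector(kc$kx) * oversampling * traj$fov + G / 2
  uy <- as.vector(kc$ky) * oversampling * traj$fov + G / 2
  ns <- length(ux)
  half <- ceiling(kb_width / 2)
  offs <- seq.int(-half, half)
  ii <- jj <- integer(0); xx <- numeric(0)
  bx <- floor(ux); by <- floor(uy)
  # kernel support wraps periodically on the FFT grid
  for (ox in offs) {
    jx <- bx + ox
    wx <- kb_kernel(ux - jx, kb_width, beta)
    sel_x <- wx > 0
    if (!any(sel_x)) next
    for (oy in offs) {
      jy <- by + oy
      wy <- kb_kernel(uy - jy, kb_width, beta)
      sel <- sel_x & wy > 0
      if (!any(sel)) next
      ii <- c(ii, ((jx[sel] %% G) + 1L) + (jy[sel] %% G) * G)
      jj <- c(jj, which(sel))
      xx <- c(xx, wx[sel] * wy[sel])
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(G * G, ns),
                            repr = "C")
  f <- (seq_len(N) - 1L - N / 2) / G
  d1 <- kb_ft(f, kb_width, beta)
  structure(list(A = A, G = G, N = N, deapod = outer(d1, d1),
                 oversampling = oversampling, kb_width = kb_width,
                 beta = beta, n_samples = ns,
                 n_rings = traj$n_rings,
                 points_per_ring = traj$points_per_ring),
            class = "ring_gridder")
}

dcf_weights <- function(dcf, traj = NULL) {
  w <- if (inherits(dcf, "density_weights")) dcf$w else dcf
  if (!is.null(traj) &&
      !identical(dim(w), c(traj$n_rings, traj$points_per_ring)))
    stop("density weights have shape ", paste(dim(w), collapse = "x"),
         " but trajectory expects ", traj$n_rings, "x", traj$points_per_ring)
  w
}

#' Grid ring samples onto a Cartesian image
#'
#' Density-compensates the samples, convolves them onto an oversampled
#' Cartesian k-space grid with a Kaiser-Bessel kernel, inverse-FFTs,
#' deapodizes and crops to `matrix_size`. The result approximates the
#' adjoint non-uniform DFT `img(r) = sum_s w_s x_s exp(+2i pi k_s . r)`.
#' Linear in `samples`.
#'
#' @param samples complex array `(ring, point)` or `(ring, point, ...)`;
#'   trailing dimensions (coils, time frames) are gridded in batch.
#' @param traj ring trajectory the samples live on.
#' @param dcf density weights ([pipe_menon_dcf()] result or a numeric
#'   `(ring, point)` matrix).
#' @param oversampling,kb_width gridding parameters (defaults 2 and 3).
#' @param gridder optional precomputed [make_gridder()] operator.
#' @return complex image `(matrix_size, matrix_size)` or with the input's
#'   trailing dimensions appended.
#' @export
grid_to_image <- function(samples, traj, dcf, oversampling = 2, kb_width = 3,
                          gridder = NULL) {
  if (is.null(gridder)) gridder <- make_gridder(traj, oversampling, kb_width)
  dm <- dim(samples) %||% stop("samples must be an array (ring, point, ...)")
  if (dm[1] != gridder$n_rings || dm[2] != gridder$points_per_ring)
    stop("samples shaped ", paste(dm, collapse = "x"),
         " do not match trajectory ", gridder$n_rings, " rings x ",
         gridder$points_per_ring, " points")
  w <- as.vector(dcf_weights(dcf, traj))
  ns <- gridder$n_samples
  nb <- as.integer(prod(dm) / ns)
  S <- matrix(samples, ns, nb) * w
  KG <- as.matrix(gridder$A %*% Re(S)) + 1i * as.matrix(gridder$A %*% Im(S))
  G <- gridder$G; N <- gridder$N
  crop <- (G / 2 - N / 2 + 1L):(G / 2 + N / 2)
  out <- array(0i, c(N, N, nb))
  for (b in seq_len(nb)) {
    img <- ifft2c(matrix(KG[, b], G, G))
    out[, , b] <- img[crop, crop] / gridder$deapod
  }
  if (length(dm) > 2L) {
    dim(out) <- c(N, N, dm[-(1:2)])
  } else {
    dim(out) <- c(N, N)
  }
  out
}

#' Evaluate ring k-space samples of a Cartesian image (forward model)
#'
#' Computes the non-uniform DFT
#' `x(k_s) = sum_r img(r) exp(-2i pi k_s . r)` by an exact direct sum
#' (chunked over samples to bound memory). This is the simulator's forward
#' operator and the reference adjoint partner of [grid_to_image()].
#'
#' @param image complex/numeric array `(N, N)` or `(N, N, ...)` with
#'   `N = traj$matrix_size`; trailing dimensions are transformed in batch.
#' @param traj ring trajectory.
#' @return complex array `(ring, point)` (plus trailing input dimensions).
#' @export
image_to_rings <- function(image, traj) {
  stopifnot(inherits(traj, "ring_trajectory"))
  dm <- dim(image) %||% stop("image must be an array")
  N <- traj$matrix_size
  if (dm[1] != N || dm[2] != N)
    stop("image shaped ", paste(dm, collapse = "x"),
         " does not match matrix_size ", N)
  kc <- traj_kcoords(traj)
  kxf <- as.vector(kc$kx); kyf <- as.vector(kc$ky)
  xs <- voxel_coords(N, traj$fov)
  xv <- rep(xs, times = N); yv <- rep(xs, each = N)
  nb <- as.integer(prod(dm) / (N * N))
  M <- matrix(image, N * N, nb)
  ns <- length(kxf)
  out <- matrix(0i, ns, nb)
  chunk <- max(1L, floor(4e6 / (N * N)))
  for (i0 in seq.int(1L, ns, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, ns)
    E <- exp(-2i * pi * (outer(kxf[i0:i1], xv) + outer(kyf[i0:i1], yv)))
    out[i0:i1, ] <- E %*% M
  }
  if (length(dm) > 2L) {
    dim(out) <- c(traj$n_rings, traj$points_per_ring, dm[-(1:2)])
  } else {
    dim(out) <- c(traj$n_rings, traj$points_per_ring)
  }
  out
}

## ---- Pipe-Menon density compensation --------------------------------------

#' Iterative Pipe-Menon density compensation for ring trajectories
#'
#' Runs the fixed-point iteration `w <- w / (w (*) C)`, where `(*)` is
#' convolution with the gridding kernel evaluated at the sample locations,
#' until `max |w (*) C - 1| < tol` or `n_iter` iterations. Rotational
#' symmetry of the ring geometry (equal angular grids on all rings) is
#' exploited: the convolution collapses onto a per-ring kernel matrix, so the
#' weights are exactly constant along each ring.
#'
#' The kernel is a radial Kaiser-Bessel profile whose support radius equals
#' the ring spacing `1/fov`: local density is measured on the scale of one
#' Nyquist cell, so the converged weights track the annulus-area density of
#' each ring without inflating the k-space boundary rings.
#'
#' Weights are normalized by quadrature consistency: they sum to the
#' fraction of Cartesian k-space covered by the sampled disk,
#' `pi * (n_rings * dk)^2 / (matrix_size * dk)^2`, so that the
#' density-compensated adjoint reproduces the amplitude of compact objects
#' (the reconstruction of the forward transform of a centered unit-amplitude
#' Gaussian has unit peak intensity up to resolution loss).
#'
#' @param traj ring trajectory.
#' @param n_iter maximum iterations (default 30).
#' @param tol convergence tolerance on `max |w (*) C - 1|` (default 1e-2).
#' @param oversampling,kb_width gridding parameters used for the kernel
#'   shape and the normalization reconstruction.
#' @return object of class `density_weights`: `w` (ring x point matrix,
#'   constant along rings), `per_ring`, `converged`, `iterations`,
#'   `max_dev`.
#' @export
pipe_menon_dcf <- function(traj, n_iter = 30, tol = 1e-2,
                           oversampling = 2, kb_width = 3) {
  stopifnot(inherits(traj, "ring_trajectory"), n_iter >= 1, tol > 0)
  nr <- traj$n_rings; np <- traj$points_per_ring
  beta <- kb_beta(kb_width, oversampling)
  r <- traj$ring_radii / traj$delta_k    # radii in Nyquist-grid units
  ang <- traj$angles
  K <- matrix(0, nr, nr)
  half_w <- kb_width / 2          # dilate support to one ring spacing
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (abs(r[i] - r[j]) >= 1) next
    d <- sqrt(pmax(r[i]^2 + r[j]^2 - 2 * r[i] * r[j] * cos(ang), 0))
    K[i, j] <- sum(kb_kernel(d * half_w, kb_width, beta))
  }
  w <- rep(1, nr)
  it <- 0L; max_dev <- Inf
  while (it < n_iter) {
    it <- it + 1L
    conv <- as.vector(K %*% w)
    max_dev <- max(abs(conv - 1))
    if (max_dev < tol) break
    w <- w / conv
  }
  converged <- max_dev < tol
  if (!converged)
    warning("Pipe-Menon iteration did not reach tol = ", tol, " in ",
            n_iter, " iterations (max deviation ", signif(max_dev, 3),
            "); returning best iterate")
  wfull <- matrix(w, nr, np)
  # quadrature normalization: total weight equals the sampled-disk fraction
  # of the Cartesian k-space area (exact amplitude for compact objects)
  scale <- (pi * nr^2 / traj$matrix_size^2) / (sum(w) * np)
  w <- w * scale
  structure(list(w = matrix(w, nr, np), per_ring = w,
                 converged = converged, iterations = it,
                 max_dev = max_dev),
            class = "density_weights")
}

#' @export
print.density_weights <- function(x, ...) {
  cat(sprintf(
    "density_weights: %d rings x %d points, %s after %d iterations (max dev %.3g)\n",
    nrow(x$w), ncol(x$w),
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$max_dev))
  invisible(x)
}
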