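#' Digital brain phantom for spectroscopic imaging simulations
#'
#' Builds a 2D phantom with gray matter (GM), white matter (WM), CSF
#' "ventricles" and a 2-3 voxel subcutaneous lipid rim outside the brain,
#' together with per-compartment metabolite amplitudes, chemical shifts and
#' Lorentzian linewidths. The tissue geometry is jittered slightly by
#' `seed` so different phantoms are not pixel-identical, but the result is
#' fully deterministic given the seed.
#'
#' Resonances: tNAA (2.01 ppm), tCr (3.02 ppm), tCho (3.20 ppm), two lipid
#' components (0.9 and 1.3 ppm, rim only) and water (4.7 ppm, used by the
#' calibration scans; concentration two orders of magnitude above the
#' metabolites, as in tissue).
#'
#' @param matrix_size image edge in voxels (>= 16).
#' @param seed integer seed controlling the geometric jitter.
#' @return object of class `digital_phantom` with `tissue_maps` (list of
#'   occupancy images in `[0, 1]`, disjoint), `metabolite_concs`
#'   (compartment x resonance matrix), `resonances` (data frame: name, ppm,
#'   t2star_ms), `b0_map` (Hz, zero by default) and `brain_mask`.
#' @export
make_phantom <- function(matrix_size = 32, seed = 1) {
  stopifnot(matrix_size >= 16)
  N <- as.integer(matrix_size)
  x <- ((seq_len(N) - 1) - N / 2) / (N / 2)
  X <- matrix(x, N, N); Y <- matrix(x, N, N, byrow = TRUE)
  jit <- with_seed(seed, rnorm(5, 0, 0.015))
  cx <- jit[1]; cy <- jit[2]
  a <- 0.74 * (1 + jit[3]); b <- 0.60 * (1 + jit[4])
  phi <- jit[5] * 2
  xr <- (X - cx) * cos(phi) + (Y - cy) * sin(phi)
  yr <- -(X - cx) * sin(phi) + (Y - cy) * cos(phi)
  in_ell <- function(s) (xr / (a * s))^2 + (yr / (b * s))^2 <= 1
  brain <- in_ell(1)
  rim <- in_ell(1.22) & !in_ell(1.05)
  csf <- ((xr - 0.13)^2 / 0.012 + yr^2 / 0.05 <= 1) |
         ((xr + 0.13)^2 / 0.012 + yr^2 / 0.05 <= 1)
  csf <- csf & brain
  wm <- in_ell(0.78) & brain & !csf
  gm <- brain & !wm & !csf
  to_img <- function(m) { storage.mode(m) <- "double"; m }
  tissue_maps <- list(gm = to_img(gm), wm = to_img(wm), csf = to_img(csf),
                      lipid = to_img(rim))
  resonances <- data.frame(
    name = c("tNAA", "tCr", "tCho", "lip09", "lip13", "water"),
    ppm = c(2.01, 3.02, 3.20, 0.90, 1.30, 4.70),
    t2star_ms = c(30, 28, 32, 18, 18, 25),
    stringsAsFactors = FALSE)
  concs <- rbind(
    gm    = c(tNAA = 1.20, tCr = 1.00, tCho = 0.22, lip09 = 0, lip13 = 0, water = 100),
    wm    = c(tNAA = 1.00, tCr = 0.75, tCho = 0.30, lip09 = 0, lip13 = 0, water = 90),
    csf   = c(tNAA = 0.05, tCr = 0.05, tCho = 0.02, lip09 = 0, lip13 = 0, water = 120),
    lipid = c(tNAA = 0, tCr = 0, tCho = 0, lip09 = 5, lip13 = 10, water = 30))
  # tissue-dependent relaxation (CSF long, lipid short); scales every
  # resonance's T2* within the compartment
  t2star_scale <- c(gm = 1.0, wm = 1.2, csf = 2.5, lipid = 0.6)
  structure(list(
    matrix_size = N, seed = seed,
    tissue_maps = tissue_maps,
    metabolite_concs = concs,
    t2star_scale = t2star_scale,
    resonances = resonances,
    b0_map = matrix(0, N, N),
    brain_mask = brain
  ), class = "digital_phantom")
}

#' Ground-truth amplitude map of one resonance
#'
#' Recomputes `sum_compartment occupancy * concentration` for a named
#' resonance; the reference for %RMSE evaluation.
#'
#' @param phantom a [make_phantom()] object.
#' @param resonance resonance name, e.g. `"tNAA"`.
#' @return numeric image.
#' @export
truth_map <- function(phantom, resonance) {
  stopifnot(inherits(phantom, "digital_phantom"))
  if (!resonance %in% colnames(phantom$metabolite_concs))
    stop("unknown resonance '", resonance, "'; known: ",
         paste(colnames(phantom$metabolite_concs), collapse = ", "))
  out <- matrix(0, phantom$matrix_size, phantom$matrix_size)
  for (comp in rownames(phantom$metabolite_concs))
    out <- out + phantom$tissue_maps[[comp]] *
      phantom$metabolite_concs[comp, resonance]
  out
}

#' Smooth complex coil sensitivity profiles
#'
#' Places `n_coils` Gaussian-magnitude receive profiles on a circle around
#' the field of view, each with a smooth per-coil phase (random offset,
#' linear roll of about `ramp` cycles across the FOV away from the coil,
#' and mild quadratic curvature), emulating a tight receive array.
#' Bandlimited by construction. The localization (`sigma`) and phase roll
#' give the sensitivities a k-space footprint on the order of the ring
#' spacing, which is what lets a parallel-imaging kernel move information
#' across rings; very broad, phase-flat profiles would make any coil-based
#' reconstruction ill-posed regardless of algorithm.
#'
#' @param matrix_size image edge.
#' @param n_coils number of channels.
#' @param seed seed for the per-coil phase offsets.
#' @param sigma Gaussian magnitude width, in units of the half-FOV.
#' @param ramp linear phase roll in cycles per FOV.
#' @param curv quadratic phase curvature (cycles at unit normalized
#'   distance from the coil center).
#' @return object of class `coil_profiles`: `sens` complex array
#'   `(N, N, n_coils)`, `noise_cov` (identity), `n_coils`.
#' @export
make_coil_profiles <- function(matrix_size = 32, n_coils = 8, seed = 1,
                               sigma = 0.35, ramp = 0.8, curv = 0.2) {
  stopifnot(n_coils >= 1, sigma > 0)
  N <- as.integer(matrix_size)
  x <- ((seq_len(N) - 1) - N / 2) / (N / 2)
  X <- matrix(x, N, N); Y <- matrix(x, N, N, byrow = TRUE)
  ph0 <- with_seed(seed, stats::runif(n_coils, -pi, pi))
  sens <- array(0i, c(N, N, n_coils))
  for (cc in seq_len(n_coils)) {
    th <- 2 * pi * (cc - 1) / n_coils
    px <- 1.25 * cos(th); py <- 1.25 * sin(th)
    mag <- exp(-((X - px)^2 + (Y - py)^2) / (2 * sigma^2))
    phase <- ph0[cc] + 2 * pi * ramp * (X * cos(th) + Y * sin(th)) +
      2 * pi * curv * ((X - px)^2 + (Y - py)^2)
    sens[, , cc] <- mag * exp(1i * phase)
  }
  structure(list(n_coils = n_coils, sens = sens, noise_cov = diag(n_coils),
                 matrix_size = N, seed = seed),
            class = "coil_profiles")
}

#' Simulate the spatial-spectral FID cube of a phantom
#'
#' Per voxel, `FID(t) = sum_m A_m exp(2i pi f_m t) exp(-t / T2*_m)
#' exp(2i pi b0 t)` with `f_m = (ppm_m - carrier_ppm) * f0_mhz` (Hz).
#'
#' @param phantom a [make_phantom()] object.
#' @param n_spec number of spectral (FID) time points (>= 8).
#' @param dwell spectral dwell time in seconds (1 / spectral bandwidth).
#' @param resonances character vector of resonance names to include;
#'   defaults to the metabolites and lipids (water suppressed).
#' @param carrier_ppm carrier (water) position, default 4.7 ppm.
#' @param f0_mhz proton frequency in MHz (Hz per ppm), default 297.2 (7 T).
#' @return complex array `(N, N, n_spec)`.
#' @export
simulate_fid_cube <- function(phantom, n_spec, dwell,
                              resonances = NULL, carrier_ppm = 4.7,
                              f0_mhz = 297.2) {
  stopifnot(inherits(phantom, "digital_phantom"), n_spec >= 8, dwell > 0)
  known <- phantom$resonances$name
  if (is.null(resonances)) resonances <- setdiff(known, "water")
  bad <- setdiff(resonances, known)
  if (length(bad))
    stop("unknown resonance(s) ", paste(bad, collapse = ", "),
         "; known: ", paste(known, collapse = ", "))
  N <- phantom$matrix_size
  tt <- (seq_len(n_spec) - 1) * dwell
  cube <- array(0i, c(N, N, n_spec))
  t2scale <- phantom$t2star_scale %||%
    setNames(rep(1, nrow(phantom$metabolite_concs)),
             rownames(phantom$metabolite_concs))
  for (m in resonances) {
    row <- phantom$resonances[phantom$resonances$name == m, ]
    f <- (row$ppm - carrier_ppm) * f0_mhz
    for (comp in rownames(phantom$metabolite_concs)) {
      A <- phantom$tissue_maps[[comp]] * phantom$metabolite_concs[comp, m]
      if (all(A == 0)) next
      t2 <- row$t2star_ms * t2scale[[comp]]
      tv <- exp((2i * pi * f - 1000 / t2) * tt)
      cube <- cube + outer(A, tv)
    }
  }
  if (any(phantom$b0_map != 0))
    cube <- cube * exp(2i * pi * outer(phantom$b0_map, tt))
  cube
}

#' Simulate a multichannel concentric-ring MRSI acquisition
#'
#' Applies the coil sensitivities to the phantom's FID cube, evaluates the
#' exact non-uniform DFT on the ring trajectory at every spectral time point,
#' scales by `flip_scale` and adds i.i.d. complex Gaussian noise.
#'
#' @param phantom,coils,traj phantom, coil profiles and trajectory sharing
#'   the same matrix size.
#' @param n_spec spectral points; `dwell` spectral dwell time (s).
#' @param flip_scale relative excitation scaling (1 for the MRSI scan;
#'   calibration scans use `sin(flip)/sin(flip_mrsi)`).
#' @param noise_sd standard deviation of the complex noise per sample
#'   (`E|n|^2 = noise_sd^2`); must be >= 0.
#' @param seed seed for the noise stream.
#' @param resonances passed to [simulate_fid_cube()].
#' @return object of class `ring_kspace`: `data` complex
#'   `(coil, ring, point, spectral_time)`, `traj`, `dwell`, `n_spec`,
#'   `measured_rings`, `flip_scale`, `meta`.
#' @export
acquire <- function(phantom, coils, traj, n_spec, dwell, flip_scale = 1,
                    noise_sd = 0, seed = NULL, resonances = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(coils, "coil_profiles"),
            inherits(traj, "ring_trajectory"))
  if (phantom$matrix_size != coils$matrix_size ||
      phantom$matrix_size != traj$matrix_size)
    stop("phantom (", phantom$matrix_size, "), coils (", coils$matrix_size,
         ") and trajectory (", traj$matrix_size, ") matrix sizes differ")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cube <- simulate_fid_cube(phantom, n_spec, dwell, resonances)
  nc <- coils$n_coils
  nr <- traj$n_rings; np <- traj$points_per_ring
  data <- array(0i, c(nc, nr, np, n_spec))
  for (cc in seq_len(nc)) {
    weighted <- cube * as.vector(coils$sens[, , cc])  # recycles over t
    data[cc, , , ] <- image_to_rings(weighted, traj) * flip_scale
  }
  if (noise_sd > 0)
    data <- data + with_seed(seed,
      array(complex_noise(length(data), noise_sd), dim(data)))
  new_ring_kspace(data, traj, dwell,
                  meta = list(noise_sd = noise_sd, seed = seed,
                              source = "mrsi"),
                  flip_scale = flip_scale)
}

new_ring_kspace <- function(data, traj, dwell, measured_rings = NULL,
                            flip_scale = 1, meta = list()) {
  dm <- dim(data)
  stopifnot(length(dm) == 4L, dm[2] == traj$n_rings,
            dm[3] == traj$points_per_ring)
  structure(list(
    data = data, traj = traj, dwell = dwell, n_spec = dm[4],
    n_coils = dm[1],
    measured_rings = measured_rings %||% rep(TRUE, traj$n_rings),
    flip_scale = flip_scale, meta = meta
  ), class = "ring_kspace")
}

#' @export
print.ring_kspace <- function(x, ...) {
  cat(sprintf(
    "ring_kspace: %d coils x %d rings x %d points x %d spectral points (%s)\n",
    x$n_coils, x$traj$n_rings, x$traj$points_per_ring, x$n_spec,
    x$meta$source %||% "unknown source"))
  cat(sprintf("  dwell %.4g s (bandwidth %.4g Hz), flip_scale %.3g, %d/%d rings measured\n",
              x$dwell, 1 / x$dwell, x$flip_scale,
              sum(x$measured_rings), x$traj$n_rings))
  invisible(x)
}

#' Simulate a water-reference calibration acquisition
#'
#' Produces the low-spectral-resolution, low-flip-angle calibration dataset
#' used for coil combination and GRAPPA weight training. Three modes:
#' `"imusical"` (interleaved, matched head position, 5 degree excitation),
#' `"static"` (separate prescan, matched position, 13 degrees) and
#' `"moved"` (prescan after head rotation by `rotation_deg`, 13 degrees).
#' Only the water resonance is simulated (no water suppression in the
#' calibration module).
#'
#' @param phantom,coils,traj as for [acquire()].
#' @param mode one of `"imusical"`, `"static"`, `"moved"`.
#' @param rotation_deg head rotation for `"moved"` (default 15).
#' @param n_spec calibration spectral points (default 27).
#' @param dwell spectral dwell time (s).
#' @param noise_sd,seed noise parameters, as for [acquire()].
#' @param flip_deg excitation flip angle; defaults to 5 (imusical) or 13
#'   (static/moved). `mrsi_flip_deg` (default 42) sets the reference.
#' @return a `ring_kspace` with `meta$source = mode`.
#' @export
make_calibration <- function(phantom, coils, traj,
                             mode = c("imusical", "static", "moved"),
                             rotation_deg = 15, n_spec = 27, dwell,
                             noise_sd = 0, seed = NULL,
                             flip_deg = NULL, mrsi_flip_deg = 42) {
  mode <- match.arg(mode)
  flip_deg <- flip_deg %||% if (mode == "imusical") 5 else 13
  flip_scale <- sin(flip_deg * pi / 180) / sin(mrsi_flip_deg * pi / 180)
  ph <- if (mode == "moved") apply_motion(phantom, rotation_deg) else phantom
  ksp <- acquire(ph, coils, traj, n_spec = n_spec, dwell = dwell,
                 flip_scale = flip_scale, noise_sd = noise_sd, seed = seed,
                 resonances = "water")
  ksp$meta$source <- mode
  ksp$meta$flip_deg <- flip_deg
  ksp$meta$rotation_deg <- if (mode == "moved") rotation_deg else 0
  ksp
}

## ---- motion ---------------------------------------------------------------

# bilinear rotation of a (possibly complex) image about its center;
# zero-filled outside
rotate_image <- function(img, rotation_deg) {
  if (rotation_deg == 0) return(img)
  N <- nrow(img)
  th <- rotation_deg * pi / 180
  ctr <- (N + 1) / 2
  ix <- matrix(seq_len(N), N, N) - ctr
  iy <- matrix(seq_len(N), N, N, byrow = TRUE) - ctr
  # inverse mapping: source = R(-th) . target
  sx <- cos(th) * ix + sin(th) * iy + ctr
  sy <- -sin(th) * ix + cos(th) * iy + ctr
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(xx, yy) {
    ok <- xx >= 1 & xx <= N & yy >= 1 & yy <= N
    v <- array(0, dim(img)); v[ok] <- img[cbind(xx[ok], yy[ok])]
    v
  }
  v <- pick(x0, y0) * (1 - fx) * (1 - fy) +
       pick(x0 + 1, y0) * fx * (1 - fy) +
       pick(x0, y0 + 1) * (1 - fx) * fy +
       pick(x0 + 1, y0 + 1) * fx * fy
  v
}

#' Rotate a phantom or coil profile set (head-motion emulation)
#'
#' Emulates the "moved" prescan: the object is rotated in-plane by
#' `rotation_deg` (bilinear interpolation, masks re-derived). Rotating the
#' phantom while the coil array stays fixed reproduces a head rotation
#' relative to the receive array.
#'
#' @param x a `digital_phantom` or `coil_profiles` object.
#' @param rotation_deg rotation in degrees, `|rotation_deg| <= 45`.
#' @return rotated copy of `x`.
#' @export
apply_motion <- function(x, rotation_deg) {
  stopifnot(abs(rotation_deg) <= 45)
  UseMethod("apply_motion")
}

#' @export
apply_motion.digital_phantom <- function(x, rotation_deg) {
  if (rotation_deg == 0) return(x)
  out <- x
  out$tissue_maps <- lapply(x$tissue_maps, rotate_image, rotation_deg)
  out$b0_map <- rotate_image(x$b0_map, rotation_deg)
  out$brain_mask <- (out$tissue_maps$gm + out$tissue_maps$wm +
                     out$tissue_maps$csf) > 0.5
  out$tissue_maps$lipid[out$brain_mask] <- 0
  out
}

#' @export
apply_motion.coil_profiles <- function(x, rotation_deg) {
  if (rotation_deg == 0) return(x)
  out <- x
  for (cc in seq_len(x$n_coils))
    out$sens[, , cc] <- rotate_image(Re(x$sens[, , cc]), rotation_deg) +
      1i * rotate_image(Im(x$sens[, , cc]), rotation_deg)
  out
}
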