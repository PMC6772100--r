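#' Run configuration presets
#'
#' Bundles the geometry, undersampling, GRAPPA, calibration and evaluation
#' parameters of a study. The `"desk"` preset (32 x 32 matrix, 16 rings,
#' 128 points/ring, 8 coils, 64 spectral points at 2778 Hz) keeps full
#' pipeline runs in the seconds-to-minutes range; the `"full"` preset
#' carries the full-scale single-slice acquisition geometry (64 x 64, 32
#' rings, 540 points/ring, 882 spectral points, 32 coils, calibration with
#' 27 spectral points).
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... named overrides for any top-level block, e.g.
#'   `pattern = list(nominal_R = 4, n_full_inner = 5)`.
#' @return object of class `mrsi_config` (a validated nested list).
#' @export
mrsi_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    geometry = switch(preset,
      desk = list(matrix_size = 32L, n_rings = 16L, points_per_ring = 128L,
                  n_coils = 8L, n_spec = 64L, bandwidth_hz = 2778,
                  fov_mm = 220),
      full = list(matrix_size = 64L, n_rings = 32L, points_per_ring = 540L,
                  n_coils = 32L, n_spec = 882L, bandwidth_hz = 2778,
                  fov_mm = 220)),
    pattern = list(nominal_R = 2L, n_full_inner = 5L),
    grappa = list(kernel_points = 3L, kernel_rings = 2L,
                  segment_points = 15L, segment_rings = 4L,
                  n_time_points = 21L, lambda = 0),
    calibration = list(mode = "imusical", rotation_deg = 15,
                       n_spec = 27L),
    evaluation = list(n_replicas = 50L,
                      bands = list(tNAA = c(1.9, 2.1), tCr = c(2.9, 3.1),
                                   tCho = c(3.1, 3.3))),
    noise_sd = 0.5,
    carrier_ppm = 4.7, f0_mhz = 297.2
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config block '", nm, "'")
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "mrsi_config")
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  stopifnot(g$matrix_size %% 2 == 0, g$n_rings <= g$matrix_size / 2,
            g$points_per_ring >= 4, g$n_coils >= 1, g$n_spec >= 8,
            g$bandwidth_hz > 0, g$fov_mm > 0,
            cfg$pattern$nominal_R >= 1,
            cfg$pattern$n_full_inner >= 0,
            cfg$calibration$n_spec >= cfg$grappa$n_time_points,
            cfg$evaluation$n_replicas >= 2,
            cfg$noise_sd >= 0)
  invisible(cfg)
}

config_traj <- function(cfg) {
  g <- cfg$geometry
  make_ring_trajectory(g$n_rings, g$points_per_ring, g$matrix_size, g$fov_mm)
}

#' Simulate a complete study (phantom, coils, MRSI scan, calibrations)
#'
#' Generates the phantom and coil profiles, the fully sampled MRSI
#' acquisition, and the three calibration datasets (interleaved/matched,
#' static prescan, and moved prescan after head rotation), plus the
#' trajectory, density compensation and gridding operator shared by all
#' reconstructions. All randomness derives from `seed`.
#'
#' @param cfg an [mrsi_config()].
#' @param seed integer master seed.
#' @return list of class `mrsi_study`.
#' @export
simulate_study <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "mrsi_config"))
  g <- cfg$geometry
  seed <- as.integer(seed)
  dwell <- 1 / g$bandwidth_hz
  traj <- config_traj(cfg)
  phantom <- make_phantom(g$matrix_size, seed = seed)
  coils <- make_coil_profiles(g$matrix_size, g$n_coils, seed = seed + 1L)
  dcf <- pipe_menon_dcf(traj)
  gridder <- make_gridder(traj)
  mrsi <- acquire(phantom, coils, traj, n_spec = g$n_spec, dwell = dwell,
                  flip_scale = 1, noise_sd = cfg$noise_sd, seed = seed + 2L)
  calib <- list(
    imusical = make_calibration(phantom, coils, traj, "imusical",
                                n_spec = cfg$calibration$n_spec,
                                dwell = dwell, noise_sd = cfg$noise_sd,
                                seed = seed + 3L),
    static = make_calibration(phantom, coils, traj, "static",
                              n_spec = cfg$calibration$n_spec,
                              dwell = dwell, noise_sd = cfg$noise_sd,
                              seed = seed + 4L),
    moved = make_calibration(phantom, coils, traj, "moved",
                             rotation_deg = cfg$calibration$rotation_deg,
                             n_spec = cfg$calibration$n_spec,
                             dwell = dwell, noise_sd = cfg$noise_sd,
                             seed = seed + 5L))
  structure(list(config = cfg, seed = seed, dwell = dwell,
                 phantom = phantom, coils = coils, traj = traj,
                 dcf = dcf, gridder = gridder, mrsi = mrsi, calib = calib),
            class = "mrsi_study")
}

config_geom <- function(cfg) {
  do.call(grappa_geometry, cfg$grappa)
}

#' Undersample, reconstruct and combine one configuration of a study
#'
#' Convenience wrapper chaining [decimate()], [reconstruct_recursive()]
#' (skipped for the identity pattern), [weights_from_calibration()] and
#' [recon_combined()] for a given pattern and calibration mode.
#'
#' @param study a [simulate_study()] result.
#' @param pattern undersampling pattern (NULL = fully sampled reference).
#' @param calib_mode `"imusical"`, `"static"` or `"moved"`.
#' @param recursive recursive two-fold ladder (default TRUE).
#' @param geom optional [grappa_geometry()] override.
#' @return list: `combined` spatial-spectral cube, `recon` (filled
#'   `ring_kspace`), `cweights`, `pattern`.
#' @export
run_recon <- function(study, pattern = NULL, calib_mode = "imusical",
                      recursive = TRUE, geom = NULL) {
  stopifnot(inherits(study, "mrsi_study"))
  calib <- study$calib[[calib_mode]]
  if (is.null(calib)) stop("unknown calibration mode '", calib_mode, "'")
  geom <- geom %||% config_geom(study$config)
  cweights <- weights_from_calibration(calib, study$dcf,
                                       gridder = study$gridder)
  if (is.null(pattern)) {
    recon <- study$mrsi
  } else {
    under <- decimate(study$mrsi, pattern)
    recon <- reconstruct_recursive(under, calib, pattern, geom,
                                   recursive = recursive)
  }
  combined <- recon_combined(recon, cweights, study$dcf, study$gridder)
  list(combined = combined, recon = recon, cweights = cweights,
       pattern = pattern)
}

#' Quantitative metrics for a reconstructed configuration
#'
#' Computes band-integrated metabolite maps, their %RMSE against the fully
#' sampled reference combined with the same calibration, the mean in-brain
#' residual-lipid integral, and (optionally) the pseudo-replica g-factor
#' map against the fully sampled reconstruction.
#'
#' @param study the simulated study.
#' @param result a [run_recon()] result for the accelerated configuration.
#' @param reference a [run_recon()] result for the fully sampled reference
#'   (same calibration mode).
#' @param with_g compute the pseudo-replica g-factor map (slower).
#' @param n_replicas replicas for the pseudo-replica runs (default from the
#'   study config).
#' @param seed seed for the replica noise.
#' @return list of metrics (metabolite %RMSE per band, mean/median g,
#'   mean in-brain lipid integral).
#' @export
evaluate_recon <- function(study, result, reference, with_g = FALSE,
                           n_replicas = NULL, seed = 1) {
  cfg <- study$config
  mask <- study$phantom$brain_mask
  bands <- cfg$evaluation$bands
  maps <- metabolite_maps(result$combined, study$dwell, bands, mask = mask)
  ref_maps <- metabolite_maps(reference$combined, study$dwell, bands,
                              mask = mask)
  rmse <- vapply(names(bands), function(b)
    percent_rmse(maps$maps[[b]], ref_maps$maps[[b]], mask), numeric(1))
  lip <- lipid_map(result$combined, study$dwell, ref_maps$maps$tCr, mask)
  out <- list(
    rmse = as.list(rmse),
    lipid_mean_brain = mean(lip[mask]),
    effective_R = if (is.null(result$pattern)) 1
                  else result$pattern$effective_R)
  if (with_g) {
    n_replicas <- n_replicas %||% cfg$evaluation$n_replicas
    pr <- replica_snr_pair(study, result, reference, n_replicas, seed)
    gmap <- g_factor(pr$snr_full, pr$snr_pi, out$effective_R, mask)
    out$g_mean <- mean(gmap$g[gmap$mask])
    out$g_median <- median(gmap$g[gmap$mask])
    out$g_map <- gmap
  }
  out
}

# pseudo-replica SNR maps of the fully sampled reference and of the
# accelerated reconstruction, both on the first FID time point (the
# water-like high-SNR image), reusing precomputed GRAPPA weights so each
# replica only re-applies them.
replica_snr_pair <- function(study, result, reference, n_replicas, seed) {
  cfg <- study$config
  t1 <- function(ksp) {    # restrict a ring_kspace to its first time point
    out <- ksp
    out$data <- ksp$data[, , , 1, drop = FALSE]
    out$n_spec <- 1L
    out
  }
  full1 <- t1(study$mrsi)
  recon_full <- function(k)
    recon_combined(k, reference$cweights, study$dcf, study$gridder)[, , 1]
  pr_full <- pseudo_replica(recon_full, full1, cfg$noise_sd, n_replicas,
                            seed = seed + 101L)
  pat <- result$pattern
  geom <- config_geom(cfg)
  under1 <- decimate(full1, pat)
  # weights are calibration-only; solve once, apply per replica
  stages <- stage_patterns(pat)
  cur_pat <- pat
  wts <- list(); tgt <- list()
  np <- study$traj$points_per_ring
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    fill <- which(st$measured & !cur_pat$measured)
    targets <- cbind(rep(fill, each = np), rep(seq_len(np), length(fill)))
    wts[[si]] <- solve_weights(study$calib[[result$cweights$source]],
                               cur_pat, geom, targets = targets)
    tgt[[si]] <- targets
    cur_pat <- st
  }
  recon_pi <- function(k) {
    for (si in seq_along(wts))
      k <- apply_weights(k, wts[[si]], targets = tgt[[si]])
    recon_combined(k, result$cweights, study$dcf, study$gridder)[, , 1]
  }
  pr_pi <- pseudo_replica(recon_pi, under1, cfg$noise_sd, n_replicas,
                          seed = seed + 202L)
  list(snr_full = pr_full$snr_map, snr_pi = pr_pi$snr_map,
       pr_full = pr_full, pr_pi = pr_pi)
}
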