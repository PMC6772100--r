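test_that("phantom construction is deterministic and anatomically consistent", {
  p1 <- make_phantom(32, seed = 1)
  p2 <- make_phantom(32, seed = 1)
  expect_identical(p1, p2)
  p3 <- make_phantom(32, seed = 2)
  expect_false(identical(p1$tissue_maps, p3$tissue_maps))

  # lipid rim disjoint from brain; occupancies in [0,1] and subunitary sums
  expect_equal(sum(p1$tissue_maps$lipid > 0 & p1$brain_mask), 0)
  occ <- Reduce(`+`, p1$tissue_maps)
  expect_true(all(occ <= 1 + 1e-12) && all(occ >= 0))
  expect_true(sum(p1$tissue_maps$lipid) > 0)

  # ground-truth maps recompute exactly from occupancy x concentration
  tn <- truth_map(p1, "tNAA")
  manual <- Reduce(`+`, lapply(rownames(p1$metabolite_concs), function(cp)
    p1$tissue_maps[[cp]] * p1$metabolite_concs[cp, "tNAA"]))
  expect_equal(tn, manual)
  # configured GM/WM contrast is recovered
  gm_amp <- unique(tn[p1$tissue_maps$gm == 1])
  wm_amp <- unique(tn[p1$tissue_maps$wm == 1])
  expect_equal(gm_amp, p1$metabolite_concs["gm", "tNAA"])
  expect_equal(wm_amp, p1$metabolite_concs["wm", "tNAA"])
  expect_false(gm_amp == wm_amp)

  expect_error(truth_map(p1, "NAAG"), "known")
})

test_that("FID cube follows the resonance model", {
  ph <- make_phantom(32, seed = 1)
  dwell <- 1 / 2778
  # single resonance at the carrier with no decay: constant FID
  ph0 <- ph
  ph0$resonances <- rbind(ph0$resonances,
                          data.frame(name = "dc", ppm = 4.7, t2star_ms = 1e12))
  ph0$metabolite_concs <- cbind(ph0$metabolite_concs,
                                dc = c(1, 1, 1, 0))
  ph0$t2star_scale[] <- 1
  cube <- simulate_fid_cube(ph0, 16, dwell, resonances = "dc")
  expect_lt(max(Mod(sweep(cube, c(1, 2), cube[, , 1], "-"))), 1e-10)

  # off-carrier resonance with negligible decay peaks at the nearest DFT bin
  ph1 <- ph0
  ph1$resonances$ppm[ph1$resonances$name == "dc"] <- 2.01
  ph1$resonances$t2star_ms[ph1$resonances$name == "dc"] <- 1e12
  n_spec <- 64
  cube <- simulate_fid_cube(ph1, n_spec, dwell, resonances = "dc")
  vox <- which(ph$tissue_maps$wm == 1, arr.ind = TRUE)[1, ]
  spec <- Mod(fid_to_spectra(cube))[vox[1], vox[2], ]
  ax <- ppm_axis(n_spec, dwell)
  f_true <- (2.01 - 4.7) * 297.2
  expect_equal(which.max(spec), which.min(abs(ax$hz - f_true)))

  expect_error(simulate_fid_cube(ph, 32, dwell, resonances = "bogus"),
               "unknown resonance")
})

test_that("two equal resonances split the spectral integral evenly", {
  ph <- make_phantom(32, seed = 1)
  ph$metabolite_concs[, ] <- 0
  ph$metabolite_concs[c("gm", "wm"), c("tNAA", "tCr")] <- 1
  ph$t2star_scale[] <- 1
  ph$resonances$t2star_ms[ph$resonances$name %in% c("tNAA", "tCr")] <- 30
  cube <- simulate_fid_cube(ph, 128, 1 / 2778)
  spec <- Mod(fid_to_spectra(cube))
  ax <- ppm_axis(128, 1 / 2778)
  # equal-width integration windows centered on each resonance
  b1 <- sum(spec[, , abs(ax$ppm - 2.01) <= 0.35])
  b2 <- sum(spec[, , abs(ax$ppm - 3.02) <= 0.35])
  expect_lt(abs(b1 / (b1 + b2) - 0.5), 0.02)
})

test_that("acquisition reduces to the forward transform for a unit coil", {
  ph <- make_phantom(32, seed = 1)
  traj <- make_ring_trajectory(16, 64, 32, 220)
  co <- unit_coils(32)
  dwell <- 1 / 2778
  ksp <- acquire(ph, co, traj, n_spec = 12, dwell = dwell, noise_sd = 0)
  cube <- simulate_fid_cube(ph, 12, dwell)
  direct <- image_to_rings(cube, traj)
  expect_equal(ksp$data[1, , , ], direct)
  expect_true(all(ksp$measured_rings))
  expect_error(acquire(ph, co, traj, 12, dwell, noise_sd = -1), ">= 0")
})

test_that("acquisition noise is seed-deterministic and model is linear", {
  ph <- make_phantom(32, seed = 1)
  traj <- make_ring_trajectory(8, 64, 32, 220)
  co <- make_coil_profiles(32, 4, seed = 2)
  a1 <- acquire(ph, co, traj, 8, 1 / 2778, noise_sd = 0.5, seed = 7)
  a2 <- acquire(ph, co, traj, 8, 1 / 2778, noise_sd = 0.5, seed = 7)
  a3 <- acquire(ph, co, traj, 8, 1 / 2778, noise_sd = 0.5, seed = 8)
  expect_identical(a1$data, a2$data)
  expect_false(identical(a1$data, a3$data))

  # doubling all amplitudes doubles the noiseless k-space exactly
  ph2 <- ph
  ph2$metabolite_concs <- 2 * ph$metabolite_concs
  k1 <- acquire(ph, co, traj, 8, 1 / 2778, noise_sd = 0)
  k2 <- acquire(ph2, co, traj, 8, 1 / 2778, noise_sd = 0)
  expect_equal(k2$data, 2 * k1$data)
})

test_that("calibration modes carry the stated flip-angle scalings", {
  ph <- make_phantom(32, seed = 1)
  traj <- make_ring_trajectory(8, 64, 32, 220)
  co <- make_coil_profiles(32, 4, seed = 2)
  dwell <- 1 / 2778
  imu <- make_calibration(ph, co, traj, "imusical", n_spec = 27,
                          dwell = dwell)
  sta <- make_calibration(ph, co, traj, "static", n_spec = 27,
                          dwell = dwell)
  expect_equal(imu$flip_scale, sin(5 * pi / 180) / sin(42 * pi / 180))
  expect_equal(sta$flip_scale, sin(13 * pi / 180) / sin(42 * pi / 180))
  expect_equal(imu$n_spec, 27L)
  expect_identical(imu$meta$source, "imusical")
  # same head position: identical up to the flip scaling (noiseless)
  expect_equal(imu$data / imu$flip_scale, sta$data / sta$flip_scale,
               tolerance = 1e-12)
})

test_that("head motion rotates the object and degrades coil correlation monotonically", {
  ph <- make_phantom(32, seed = 1)
  expect_identical(apply_motion(ph, 0), ph)
  rt <- apply_motion(apply_motion(ph, 15), -15)
  dice <- 2 * sum(rt$brain_mask & ph$brain_mask) /
    (sum(rt$brain_mask) + sum(ph$brain_mask))
  expect_gt(dice, 0.95)
  expect_equal(sum(rt$tissue_maps$lipid > 0 & rt$brain_mask), 0)

  # per-coil calibration image correlation decreases with rotation angle
  traj <- make_ring_trajectory(16, 64, 32, 220)
  co <- make_coil_profiles(32, 4, seed = 2)
  dcf <- pipe_menon_dcf(traj)
  img_of <- function(deg) {
    cal <- make_calibration(ph, co, traj, "moved", rotation_deg = deg,
                            n_spec = 8, dwell = 1 / 2778)
    s <- aperm(cal$data[, , , 1, drop = FALSE], c(2, 3, 1, 4))
    dim(s) <- c(16, 64, 4)
    grid_to_image(s, traj, dcf)
  }
  ref <- img_of(0)
  ccor <- function(a, b) Mod(sum(Conj(a) * b)) /
    sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
  corr_at <- function(deg) {
    img <- img_of(deg)
    mean(sapply(1:4, function(cc)
      ccor(as.vector(img[, , cc])[ph$brain_mask],
           as.vector(ref[, , cc])[ph$brain_mask])))
  }
  c5 <- corr_at(5); c15 <- corr_at(15)
  expect_gt(c5, c15)
  expect_lt(c15, 0.999)
})

test_that("energy is conserved through the forward model within gridding tolerance", {
  # Parseval-style check: image energy tracks dcf-weighted k-space energy
  traj <- make_ring_trajectory(16, 128, 32, 200)
  dcf <- pipe_menon_dcf(traj)
  x <- ((0:31) - 16) / 16
  g <- exp(-outer(x^2, x^2, "+") / (2 * 0.12^2))
  s <- image_to_rings(array(g + 0i, c(32, 32)), traj)
  e_img <- sum(Mod(g)^2)
  e_k <- sum(dcf$w * Mod(s)^2)
  expect_lt(abs(e_k / e_img - 1), 0.15)
})
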