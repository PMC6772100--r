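test_that("kernel repetition counts match the sliding-segment rule", {
  geom <- grappa_geometry()
  reps <- count_repetitions(geom)
  expect_equal(unname(reps["spatial"]), 39)
  expect_equal(unname(reps["total"]), 819)

  g1 <- grappa_geometry(segment_points = 3, segment_rings = 2,
                        n_time_points = 1)
  expect_equal(unname(count_repetitions(g1)["spatial"]), 1)

  g2 <- grappa_geometry(segment_points = 10, segment_rings = 3,
                        n_time_points = 5)
  reps2 <- count_repetitions(g2)
  # explicit sliding-loop cross-check
  slid <- 0
  for (i in 1:(10 - 3 + 1)) for (j in 1:(3 - 2 + 1)) slid <- slid + 1
  expect_equal(unname(reps2["spatial"]), slid)
  expect_equal(unname(reps2["spatial"]), 16)
  expect_equal(unname(reps2["total"]), 80)
})

test_that("overdetermination rule is a >= threshold on repetitions", {
  expect_true(check_overdetermination(grappa_geometry(), 32))   # 819 >= 192
  expect_false(check_overdetermination(
    grappa_geometry(segment_points = 3, segment_rings = 2,
                    n_time_points = 1), 1))                      # 1 < 6
  # boundary: exactly source_points * coils repetitions passes (>=, not >)
  g <- grappa_geometry(segment_points = 10, segment_rings = 4,
                       n_time_points = 8)                        # 24 * 8 = 192
  expect_equal(unname(count_repetitions(g)["total"]), 192)
  expect_true(check_overdetermination(g, 32))
  expect_false(check_overdetermination(g, 33))
})

test_that("source location follows the nearest-measured-ring convention", {
  geom <- grappa_geometry()
  pat <- make_pattern(32, 2, 0)     # measured rings: 2, 4, ..., 32
  loc <- locate_sources(5, 100, pat, geom, 540)
  expect_equal(loc$source_rings, c(4, 6))
  expect_equal(100 + loc$point_offsets, c(99, 100, 101))
  expect_false(loc$boundary)
  # circular wrap at point 1 (first angular index)
  loc1 <- locate_sources(5, 1, pat, geom, 540)
  expect_equal(ringmrsi:::wrap_point(1 + loc1$point_offsets, 540),
               c(540, 1, 2))
  # k-space boundary: ring 1 has no measured ring below
  locb <- locate_sources(1, 10, pat, geom, 540)
  expect_true(locb$boundary)
  expect_equal(locb$source_rings, c(2, 4))
  # segment ring placements never leave the ring range
  for (r in which(!pat$measured)) {
    l <- locate_sources(r, 1, pat, geom, 540)
    pl <- outer(l$ring_centers, l$ring_offsets, "+")
    expect_true(all(pl >= 1 & pl <= 32))
    expect_true(all(l$ring_centers >= 1 & l$ring_centers <= 32))
  }
  # variable-density core is fully measured: no target falls inside it
  pv <- make_pattern(32, 2, 5)
  expect_true(all(which(!pv$measured) > 5))
  expect_error(locate_sources(2, 1, pat, geom, 540), "measured")
})

test_that("weights recover a planted kernel-local linear model exactly", {
  traj <- make_ring_trajectory(16, 64, 32, 200)
  pp <- planted_pair(traj, n_coils = 3, nt_calib = 27, nt_test = 8,
                     K = 6, seed = 7)
  pat <- make_pattern(16, 2, 0)
  geom <- grappa_geometry()
  w <- solve_weights(pp$calib, pat, geom)
  rec <- apply_weights(decimate(pp$test, pat), w)
  expect_lt(filled_ring_error(rec, pp$test, pat), 1e-8)
  expect_true(all(rec$measured_rings))
  # measured samples pass through untouched
  expect_identical(rec$data[, pat$measured, , ],
                   pp$test$data[, pat$measured, , ])
})

test_that("least-squares weights are invariant under calibration row duplication", {
  traj <- make_ring_trajectory(8, 32, 16, 200)
  pp <- planted_pair(traj, n_coils = 2, nt_calib = 12, nt_test = 4,
                     K = 4, seed = 3)
  pat <- make_pattern(8, 2, 0)
  g1 <- grappa_geometry(segment_points = 7, segment_rings = 4,
                        n_time_points = 6)
  # duplicate each calibration time point
  dup <- pp$calib
  dup$data <- dup$data[, , , rep(seq_len(12), each = 2)]
  dup$n_spec <- 24L
  g2 <- grappa_geometry(segment_points = 7, segment_rings = 4,
                        n_time_points = 12)
  w1 <- solve_weights(pp$calib, pat, g1,
                      targets = cbind(3, 1:4), force = TRUE)
  w2 <- solve_weights(dup, pat, g2,
                      targets = cbind(3, 1:4), force = TRUE)
  for (k in names(w1$weights))
    expect_lt(max(Mod(w1$weights[[k]] - w2$weights[[k]])), 1e-8)
})

test_that("weights depend only on the calibration data", {
  traj <- make_ring_trajectory(8, 32, 16, 200)
  pp <- planted_pair(traj, n_coils = 2, nt_calib = 21, nt_test = 4,
                     K = 4, seed = 5)
  pat <- make_pattern(8, 2, 0)
  geom <- grappa_geometry(segment_points = 9, n_time_points = 21)
  # solve before the undersampled set exists, then corrupt an unrelated
  # dataset and re-solve: identical weights
  w1 <- solve_weights(pp$calib, pat, geom, force = TRUE)
  other <- decimate(pp$test, pat)
  other$data <- other$data * 0
  w2 <- solve_weights(pp$calib, pat, geom, force = TRUE)
  expect_identical(w1$weights, w2$weights)
})

test_that("reconstruction is time-uniform: each FID point filled independently", {
  traj <- make_ring_trajectory(8, 32, 16, 200)
  pp <- planted_pair(traj, n_coils = 2, nt_calib = 21, nt_test = 6,
                     K = 4, seed = 9)
  pat <- make_pattern(8, 2, 0)
  geom <- grappa_geometry(segment_points = 9, n_time_points = 21)
  w <- solve_weights(pp$calib, pat, geom, force = TRUE)
  full <- apply_weights(decimate(pp$test, pat), w)
  # zero every time point except t = 3: the fill at t = 3 is unchanged
  zeroed <- decimate(pp$test, pat)
  zeroed$data[, , , -3] <- 0
  z <- apply_weights(zeroed, w)
  expect_equal(z$data[, , , 3], full$data[, , , 3])
})

test_that("identity pattern and missing-weight lookups are handled", {
  traj <- make_ring_trajectory(8, 32, 16, 200)
  pp <- planted_pair(traj, n_coils = 2, nt_calib = 21, nt_test = 4,
                     K = 4, seed = 2)
  pat <- make_pattern(8, 2, 0)
  geom <- grappa_geometry(segment_points = 9, n_time_points = 21)
  w <- solve_weights(pp$calib, pat, geom,
                     targets = cbind(3, 1:32), force = TRUE)
  expect_error(apply_weights(decimate(pp$test, pat), w),
               "no weights")
  # identity pattern: nothing to fill, output equals input
  idp <- make_pattern(8, 1, 0)
  under <- decimate(pp$test, idp)
  w0 <- solve_weights(pp$calib, idp, geom, force = TRUE)
  expect_identical(apply_weights(under, w0)$data, pp$test$data)
})

test_that("solver contracts: calibration and overdetermination preconditions", {
  traj <- make_ring_trajectory(8, 32, 16, 200)
  pp <- planted_pair(traj, n_coils = 8, nt_calib = 4, nt_test = 4,
                     K = 4, seed = 2)
  pat <- make_pattern(8, 2, 0)
  # underdetermined: 1 spatial rep x 4 time points < 6 x 8 unknowns
  tiny <- grappa_geometry(segment_points = 3, segment_rings = 2,
                          n_time_points = 4)
  expect_error(solve_weights(pp$calib, pat, tiny), "underdetermined")
  expect_s3_class(solve_weights(pp$calib, pat, tiny,
                                targets = cbind(3, 1), force = TRUE),
                  "grappa_weights")
  # calibration must be fully sampled and long enough
  dec <- decimate(pp$calib, pat)
  expect_error(solve_weights(dec, pat, tiny, force = TRUE),
               "fully sampled")
  expect_error(solve_weights(pp$calib, pat,
                             grappa_geometry(n_time_points = 21)),
               "n_time_points")
})

test_that("recursive ladder fills everything and matches the stage patterns", {
  traj <- make_ring_trajectory(16, 64, 32, 200)
  pp <- planted_pair(traj, n_coils = 3, nt_calib = 27, nt_test = 4,
                     K = 6, seed = 13)
  geom <- grappa_geometry()
  # R = 2: recursive identical to the single direct pass
  p2 <- make_pattern(16, 2, 0)
  u2 <- decimate(pp$test, p2)
  rec_r <- reconstruct_recursive(u2, pp$calib, p2, geom, recursive = TRUE)
  rec_d <- reconstruct_recursive(u2, pp$calib, p2, geom, recursive = FALSE)
  expect_equal(rec_r$data, rec_d$data)
  # R = 8 on a planted model: three stages, all rings filled exactly
  p8 <- make_pattern(16, 8, 0)
  rec8 <- reconstruct_recursive(decimate(pp$test, p8), pp$calib, p8, geom)
  expect_true(all(rec8$measured_rings))
  expect_lt(filled_ring_error(rec8, pp$test, p8), 1e-6)
})
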