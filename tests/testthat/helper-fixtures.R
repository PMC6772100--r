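# Shared fixtures, memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# desk-scale simulated study (32x32, 16 rings, 8 coils, 64 spectral points)
desk_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulate_study(mrsi_config("desk"), seed = 1)
  .fixtures$study
}

# reconstructed configurations reused by the acceptance regressions
desk_recons <- function() {
  if (!is.null(.fixtures$recons)) return(.fixtures$recons)
  study <- desk_study()
  pat <- function(R) make_pattern(16, R, 5)
  .fixtures$recons <- list(
    study = study,
    ref_i = run_recon(study, NULL, "imusical"),
    ref_s = run_recon(study, NULL, "static"),
    r2v = run_recon(study, pat(2), "imusical"),
    r4v = run_recon(study, pat(4), "imusical"),
    r4d = run_recon(study, pat(4), "imusical", recursive = FALSE),
    r8v = run_recon(study, pat(8), "imusical"),
    r2m = run_recon(study, pat(2), "moved"))
  .fixtures$recons
}

# coil set with identically-one sensitivity (reduces acquire to the
# forward transform)
unit_coils <- function(matrix_size, n_coils = 1) {
  co <- make_coil_profiles(matrix_size, n_coils, seed = 1)
  co$sens[] <- 1 + 0i
  co
}

# k-space data generated by an exact kernel-local linear model:
# x[c, r, p, t] = sum_k a[c, k] rho_k^r exp(i om_k p) g[t, k].
# Any GRAPPA kernel relating fixed (ring, point) offsets is exactly linear
# on such data, so weights solved on `calib` must reproduce `test`
# verbatim. Modes are drawn with well-spread angular frequencies.
planted_pair <- function(traj, n_coils, nt_calib, nt_test, K, seed) {
  set.seed(seed)
  nr <- traj$n_rings; np <- traj$points_per_ring
  a <- matrix(complex(real = rnorm(n_coils * K),
                      imaginary = rnorm(n_coils * K)), n_coils, K)
  rho <- exp(complex(real = runif(K, -0.15, 0.15),
                     imaginary = runif(K, -pi, pi)))
  om <- runif(K, -pi, pi)
  build <- function(nt) {
    g <- matrix(complex(real = rnorm(nt * K), imaginary = rnorm(nt * K)),
                nt, K)
    data <- array(0i, c(n_coils, nr, np, nt))
    for (k in seq_len(K)) {
      sp <- outer(rho[k]^(seq_len(nr)), exp(1i * om[k] * seq_len(np)))
      for (cc in seq_len(n_coils))
        data[cc, , , ] <- data[cc, , , ] + a[cc, k] * outer(sp, g[, k])
    }
    ringmrsi:::new_ring_kspace(data, traj, 1e-3,
                               meta = list(source = "planted"))
  }
  list(calib = build(nt_calib), test = build(nt_test))
}

rel_l2 <- function(x, ref) sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))

# relative l2 error of the filled (previously missing) rings only
filled_ring_error <- function(recon, truth, pattern) {
  miss <- !pattern$measured
  rel_l2(recon$data[, miss, , ], truth$data[, miss, , ])
}
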