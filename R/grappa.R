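#' Geometry of the through-time/through-k-space GRAPPA kernel
#'
#' The kernel predicts one missing ring sample from `kernel_points`
#' angular neighbors on each of `kernel_rings` measured rings
#' (default 3 x 2 = six source points). Calibration repetitions are
#' harvested by sliding the kernel through a `segment_points x
#' segment_rings` k-space segment centered on the target
#' (`(segment_points - kernel_points + 1) * (segment_rings - kernel_rings
#' + 1)` spatial repetitions, 13 x 3 = 39 at the defaults) and over the
#' first `n_time_points` calibration FID time points, for
#' `39 * 21 = 819` total repetitions at the defaults.
#'
#' @param kernel_points angular source points per source ring (odd).
#' @param kernel_rings source rings (currently 2: nearest measured ring on
#'   each side of the target).
#' @param segment_points,segment_rings segment extent (points x rings).
#' @param n_time_points calibration time points used as through-time
#'   repetitions.
#' @param lambda Tikhonov regularization for the weight solve (default 0,
#'   plain least squares).
#' @return object of class `grappa_geometry`.
#' @export
grappa_geometry <- function(kernel_points = 3, kernel_rings = 2,
                            segment_points = 15, segment_rings = 4,
                            n_time_points = 21, lambda = 0) {
  stopifnot(kernel_points >= 1, kernel_rings >= 1,
            segment_points >= kernel_points, segment_rings >= kernel_rings,
            n_time_points >= 1, lambda >= 0)
  if (kernel_points %% 2 != 1)
    stop("kernel_points must be odd (sources centered on the target angle)")
  if (kernel_rings != 2)
    stop("kernel_rings = 2 (one measured ring on each side) is the supported geometry")
  structure(list(kernel_points = as.integer(kernel_points),
                 kernel_rings = as.integer(kernel_rings),
                 segment_points = as.integer(segment_points),
                 segment_rings = as.integer(segment_rings),
                 n_time_points = as.integer(n_time_points),
                 lambda = lambda),
            class = "grappa_geometry")
}

#' Number of calibration kernel repetitions
#'
#' @param geom a [grappa_geometry()].
#' @return named numeric vector `c(spatial, total)`:
#'   `(segment_points - kernel_points + 1) * (segment_rings - kernel_rings
#'   + 1)` spatial repetitions and `spatial * n_time_points` in total.
#' @export
count_repetitions <- function(geom) {
  stopifnot(inherits(geom, "grappa_geometry"))
  spatial <- (geom$segment_points - geom$kernel_points + 1L) *
             (geom$segment_rings - geom$kernel_rings + 1L)
  c(spatial = spatial, total = spatial * geom$n_time_points)
}

#' Overdetermination rule for the GRAPPA weight solve
#'
#' The number of kernel repetitions must be at least the number of source
#' points times the number of channels
#' (`kernel_points * kernel_rings * n_coils`).
#'
#' @param geom a [grappa_geometry()]; `n_coils` channel count.
#' @return logical.
#' @export
check_overdetermination <- function(geom, n_coils) {
  unname(count_repetitions(geom)["total"]) >=
    geom$kernel_points * geom$kernel_rings * n_coils
}

wrap_point <- function(p, np) ((p - 1L) %% np) + 1L

#' Source and segment geometry for one missing sample
#'
#' For a target on a missing ring, the kernel sources are the nearest
#' measured ring below and above the target (falling back to the two
#' nearest measured rings on the available side at the k-space boundary,
#' flagged) and `kernel_points` angular indices centered on the target's
#' angular index with circular wrap. Also returns the segment footprint
#' used for calibration harvesting: ring placement centers mirroring the
#' kernel's ring offsets (shifted, never wrapped, at ring boundaries) and
#' point placement centers centered on the target angle.
#'
#' @param ring,point 1-based target coordinates (ring must be missing).
#' @param pattern undersampling pattern defining measured rings.
#' @param geom kernel/segment geometry.
#' @param n_points points per ring (for the circular wrap).
#' @return list with `source_rings`, `ring_offsets`, `point_offsets`,
#'   `ring_centers`, `point_centers`, `boundary`.
#' @export
locate_sources <- function(ring, point, pattern, geom, n_points) {
  stopifnot(inherits(pattern, "undersampling_pattern"),
            inherits(geom, "grappa_geometry"))
  nr <- pattern$n_rings
  if (ring < 1 || ring > nr) stop("target ring ", ring, " out of range")
  if (pattern$measured[ring])
    stop("target ring ", ring, " is measured; nothing to reconstruct")
  meas <- which(pattern$measured)
  below <- meas[meas < ring]; above <- meas[meas > ring]
  boundary <- FALSE
  if (length(below) == 0L) {
    if (length(above) < 2L) stop("fewer than two measured rings available")
    src <- sort(above)[1:2]; boundary <- TRUE
  } else if (length(above) == 0L) {
    if (length(below) < 2L) stop("fewer than two measured rings available")
    src <- sort(tail(sort(below), 2L)); boundary <- TRUE
  } else {
    src <- c(max(below), min(above))
  }
  ring_offsets <- src - ring
  h <- (geom$kernel_points - 1L) %/% 2L
  point_offsets <- seq.int(-h, h)
  # calibration placements: ring centers mirror the kernel ring offsets
  n_rc <- geom$segment_rings - geom$kernel_rings + 1L
  cand <- ring + seq.int(0L, n_rc - 1L) - (n_rc - 1L) %/% 2L
  lo <- max(1L, 1L - min(ring_offsets))
  hi <- min(nr, nr - max(ring_offsets))
  if (min(cand) < lo) cand <- cand + (lo - min(cand))
  if (max(cand) > hi) cand <- cand - (max(cand) - hi)
  cand <- unique(pmax(pmin(cand, hi), lo))
  n_pc <- geom$segment_points - geom$kernel_points + 1L
  pcand <- point + seq.int(0L, n_pc - 1L) - (n_pc - 1L) %/% 2L
  list(source_rings = src, ring_offsets = ring_offsets,
       point_offsets = point_offsets,
       ring_centers = cand, point_centers = pcand,
       boundary = boundary)
}

# gather an (n_rep x n_coils) block of calib values at (ring, point, time)
# vectors; data dims (coil, ring, point, time)
gather_block <- function(data_flat, nc, nr, np, rings, points, times) {
  base <- ((rings - 1L) + nr * ((points - 1L) + np * (times - 1L))) * nc
  idx <- outer(base, seq_len(nc), "+")
  matrix(data_flat[idx], length(rings), nc)
}

# design (S) and target (T) matrices for one target location
build_design <- function(calib, loc, geom) {
  nc <- calib$n_coils; nr <- calib$traj$n_rings
  np <- calib$traj$points_per_ring
  nt <- geom$n_time_points
  grid <- expand.grid(pc = loc$point_centers, rc = loc$ring_centers,
                      t = seq_len(nt))
  df <- calib$data
  dim(df) <- NULL
  blocks <- vector("list", length(loc$ring_offsets) * length(loc$point_offsets))
  k <- 0L
  for (dr in loc$ring_offsets) for (dp in loc$point_offsets) {
    k <- k + 1L
    blocks[[k]] <- gather_block(df, nc, nr, np,
                                grid$rc + dr,
                                wrap_point(grid$pc + dp, np),
                                grid$t)
  }
  list(S = do.call(cbind, blocks),
       T = gather_block(df, nc, nr, np, grid$rc,
                        wrap_point(grid$pc, np), grid$t))
}

# complex least squares via SVD (min-norm for rank-deficient systems);
# normal equations with ridge when lambda > 0
solve_lstsq <- function(S, Tm, lambda = 0) {
  if (lambda > 0) {
    SH <- Conj(t(S))
    G <- SH %*% S
    diag(G) <- diag(G) + lambda * mean(Re(diag(G)))
    return(list(W = solve(G, SH %*% Tm), rank_deficient = FALSE))
  }
  sv <- svd(S)
  tol <- max(sv$d) * max(dim(S)) * .Machine$double.eps * 10
  keep <- sv$d > tol
  W <- sv$v[, keep, drop = FALSE] %*%
    ((Conj(t(sv$u[, keep, drop = FALSE])) %*% Tm) / sv$d[keep])
  list(W = W, rank_deficient = sum(keep) < ncol(S))
}

#' Solve tt/tk-GRAPPA weights from a calibration dataset
#'
#' For every missing sample of `pattern` (or the subset in `targets`),
#' harvests the kernel repetitions from the fully sampled calibration
#' k-space across the segment and the first `n_time_points` calibration
#' time points, and solves the per-target complex least-squares problem
#' `W = argmin ||S W - T||` (source matrix rows = repetitions, columns =
#' source coil x kernel position; one target column per coil).
#'
#' Weights depend only on the calibration data, never on the undersampled
#' data they are later applied to.
#'
#' @param calib fully sampled calibration `ring_kspace` with
#'   `n_spec >= geom$n_time_points`.
#' @param pattern undersampling pattern whose missing samples need weights.
#' @param geom kernel/segment geometry (see [grappa_geometry()]).
#' @param targets optional 2-column matrix `(ring, point)` restricting the
#'   solve; default all missing samples.
#' @param force solve even when [check_overdetermination()] fails.
#' @return object of class `grappa_weights`: per-target weight matrices
#'   (`(kernel_points * kernel_rings * n_coils) x n_coils`), source
#'   locations and solve diagnostics.
#' @export
solve_weights <- function(calib, pattern, geom, targets = NULL,
                          force = FALSE) {
  stopifnot(inherits(calib, "ring_kspace"),
            inherits(pattern, "undersampling_pattern"),
            inherits(geom, "grappa_geometry"))
  if (!all(calib$measured_rings))
    stop("calibration dataset must be fully sampled")
  if (calib$n_spec < geom$n_time_points)
    stop("calibration has ", calib$n_spec, " spectral points but geometry ",
         "requires n_time_points = ", geom$n_time_points)
  if (pattern$n_rings != calib$traj$n_rings)
    stop("pattern/calibration ring count mismatch")
  nc <- calib$n_coils
  if (!check_overdetermination(geom, nc) && !force)
    stop("underdetermined solve: ", count_repetitions(geom)["total"],
         " repetitions < ", geom$kernel_points * geom$kernel_rings * nc,
         " unknowns per target coil (use force = TRUE to override)")
  np <- calib$traj$points_per_ring
  if (is.null(targets)) {
    miss <- which(!pattern$measured)
    targets <- cbind(ring = rep(miss, each = np),
                     point = rep(seq_len(np), length(miss)))
  }
  n_t <- nrow(targets)
  wlist <- vector("list", n_t)
  locs <- vector("list", n_t)
  resid <- numeric(n_t); rankdef <- logical(n_t); bflag <- logical(n_t)
  keys <- character(n_t)
  loc_cache <- list()
  for (i in seq_len(n_t)) {
    r <- targets[i, 1]; p <- targets[i, 2]
    ck <- as.character(r)
    loc_r <- loc_cache[[ck]]
    if (is.null(loc_r)) {
      loc_r <- locate_sources(r, 1L, pattern, geom, np)
      loc_cache[[ck]] <- loc_r
    }
    loc <- loc_r
    loc$point_centers <- loc_r$point_centers + (p - 1L)
    d <- build_design(calib, loc, geom)
    sol <- solve_lstsq(d$S, d$T, geom$lambda)
    res <- d$S %*% sol$W - d$T
    nrmT <- sqrt(sum(Mod(d$T)^2))
    resid[i] <- if (nrmT > 0) sqrt(sum(Mod(res)^2)) / nrmT else 0
    rankdef[i] <- sol$rank_deficient
    bflag[i] <- loc$boundary
    keys[i] <- paste0(r, ":", p)
    wlist[[i]] <- sol$W
    locs[[i]] <- list(source_rings = loc$source_rings,
                      point_offsets = loc$point_offsets)
  }
  names(wlist) <- keys; names(locs) <- keys
  structure(list(
    weights = wlist, sources = locs, geom = geom, n_coils = nc,
    pattern = pattern,
    diagnostics = data.frame(ring = targets[, 1], point = targets[, 2],
                             residual = resid, rank_deficient = rankdef,
                             boundary = bflag)
  ), class = "grappa_weights")
}

#' @export
print.grappa_weights <- function(x, ...) {
  cat(sprintf(
    "grappa_weights: %d targets, %d coils, kernel %dx%d, median relative residual %.3g\n",
    length(x$weights), x$n_coils, x$geom$kernel_points,
    x$geom$kernel_rings, median(x$diagnostics$residual)))
  if (any(x$diagnostics$boundary))
    cat("  boundary fallback used for", sum(x$diagnostics$boundary), "targets\n")
  if (any(x$diagnostics$rank_deficient))
    cat("  rank-deficient solves:", sum(x$diagnostics$rank_deficient),
        "(min-norm pseudoinverse)\n")
  invisible(x)
}

#' Apply GRAPPA weights to fill missing rings
#'
#' Fills every missing `(coil, ring, point)` sample for every spectral time
#' point using the same per-target weights across the whole FID; measured
#' samples pass through unchanged. The output is marked fully sampled.
#'
#' @param under undersampled `ring_kspace`.
#' @param weights a [solve_weights()] result covering the missing samples.
#' @param pattern the undersampling pattern of `under`; defaults to the
#'   pattern stored in `weights`.
#' @param targets optional `(ring, point)` matrix restricting application.
#' @return reconstructed `ring_kspace`.
#' @export
apply_weights <- function(under, weights, pattern = NULL, targets = NULL) {
  stopifnot(inherits(under, "ring_kspace"),
            inherits(weights, "grappa_weights"))
  pattern <- pattern %||% weights$pattern
  np <- under$traj$points_per_ring
  nr <- under$traj$n_rings
  nc <- under$n_coils
  nt <- under$n_spec
  if (nc != weights$n_coils)
    stop("data has ", nc, " coils but weights were solved for ",
         weights$n_coils)
  if (is.null(targets)) {
    miss <- which(!pattern$measured)
    targets <- cbind(rep(miss, each = np), rep(seq_len(np), length(miss)))
  }
  data <- under$data
  df <- data; dim(df) <- NULL
  tseq <- seq_len(nt)
  filled <- under$data
  for (i in seq_len(nrow(targets))) {
    r <- targets[i, 1]; p <- targets[i, 2]
    key <- paste0(r, ":", p)
    W <- weights$weights[[key]]
    if (is.null(W))
      stop("no weights available for missing sample ring ", r, " point ", p)
    loc <- weights$sources[[key]]
    cols <- vector("list", length(loc$source_rings) * length(loc$point_offsets))
    k <- 0L
    for (sr in loc$source_rings) for (dp in loc$point_offsets) {
      k <- k + 1L
      sp <- wrap_point(p + dp, np)
      cols[[k]] <- t(matrix(df[
        rep(((sr - 1L) + nr * ((sp - 1L) + np * (tseq - 1L))) * nc,
            each = nc) + seq_len(nc)], nc, nt))
    }
    X <- do.call(cbind, cols)          # nt x (positions*coils)
    filled[, r, p, ] <- t(X %*% W)
  }
  out <- under
  out$data <- filled
  out$measured_rings <- rep(TRUE, nr)
  out$meta$reconstructed <- TRUE
  out
}

#' Reconstruct missing rings by (optionally recursive) tt/tk-GRAPPA
#'
#' Walks the [stage_patterns()] ladder of consecutive two-fold
#' reconstructions (R = 8 -> 4 -> 2 -> full), re-solving weights at each
#' stage against the same calibration set with the same segment, kernel and
#' repetition geometry. With `recursive = FALSE`, a single direct solve
#' from the starting pattern to the full k-space is performed.
#'
#' @param under undersampled `ring_kspace`.
#' @param calib fully sampled calibration `ring_kspace`.
#' @param pattern starting undersampling pattern (`nominal_R` in
#'   `{2, 4, 8}` for the recursive ladder).
#' @param geom kernel/segment geometry.
#' @param recursive use the stage ladder (default TRUE).
#' @return fully sampled reconstructed `ring_kspace`.
#' @export
reconstruct_recursive <- function(under, calib, pattern, geom,
                                  recursive = TRUE) {
  stopifnot(inherits(under, "ring_kspace"))
  np <- under$traj$points_per_ring
  stages <- if (recursive) stage_patterns(pattern)
            else list(full_pattern(pattern$n_rings, pattern$n_full_inner))
  cur_pat <- pattern
  cur <- under
  for (st in stages) {
    fill_rings <- which(st$measured & !cur_pat$measured)
    if (length(fill_rings)) {
      targets <- cbind(rep(fill_rings, each = np),
                       rep(seq_len(np), length(fill_rings)))
      w <- solve_weights(calib, cur_pat, geom, targets = targets)
      cur <- apply_weights(cur, w, cur_pat, targets = targets)
      cur$measured_rings <- st$measured
    }
    cur_pat <- st
  }
  cur$measured_rings <- rep(TRUE, under$traj$n_rings)
  cur
}
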