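#' Construct a ring undersampling pattern
#'
#' The innermost `n_full_inner` rings are always measured (fully sampled
#' core of a variable-density pattern; 0 for constant-density). Of the
#' remaining outer rings, every `nominal_R`-th is kept, starting after
#' skipping `nominal_R - 1` rings, so exactly
#' `floor((n_rings - n_full_inner) / nominal_R)` outer rings are measured.
#' The effective acceleration is the ring-count ratio
#' `n_rings / n_measured` (each ring costs one TR per temporal interleaf,
#' so ring count is proportional to scan time).
#'
#' On 32 rings with a 5-ring core this yields effective R = 1.78 for
#' `nominal_R = 2` and 2.91 for `nominal_R = 4`.
#'
#' @param n_rings total number of rings.
#' @param nominal_R nominal (outer-ring) acceleration factor, >= 1.
#' @param n_full_inner fully sampled innermost rings, `0 <= n_full_inner <
#'   n_rings`.
#' @return object of class `undersampling_pattern` with `measured` (logical
#'   per ring), `nominal_R`, `n_full_inner`, `effective_R` (exact;
#'   two-decimal rounding is applied when printing/reporting).
#' @export
make_pattern <- function(n_rings, nominal_R, n_full_inner = 0) {
  stopifnot(n_rings >= 1, nominal_R >= 1,
            n_full_inner >= 0, n_full_inner < n_rings)
  n_rings <- as.integer(n_rings)
  nominal_R <- as.integer(nominal_R)
  n_full_inner <- as.integer(n_full_inner)
  n_outer <- n_rings - n_full_inner
  if (n_outer %/% nominal_R == 0L)
    stop("nominal_R = ", nominal_R, " leaves no measured ring among the ",
         n_outer, " outer rings")
  measured <- rep(FALSE, n_rings)
  measured[seq_len(n_full_inner)] <- TRUE
  outer_idx <- seq_len(n_outer)
  measured[n_full_inner + outer_idx[outer_idx %% nominal_R == 0L]] <- TRUE
  structure(list(
    n_rings = n_rings, measured = measured, nominal_R = nominal_R,
    n_full_inner = n_full_inner,
    effective_R = n_rings / sum(measured)
  ), class = "undersampling_pattern")
}

#' @export
print.undersampling_pattern <- function(x, ...) {
  cat(sprintf(
    "undersampling_pattern: %d rings, nominal R = %d, %d-ring core, %d measured, effective R = %.2f\n",
    x$n_rings, x$nominal_R, x$n_full_inner, sum(x$measured), x$effective_R))
  invisible(x)
}

full_pattern <- function(n_rings, n_full_inner = 0) {
  p <- make_pattern(n_rings, 1L, n_full_inner)
  p
}

#' Retrospectively undersample ring k-space data
#'
#' Pure restriction: data on rings not measured by `pattern` are zeroed,
#' measured rings are left untouched (no scaling); `measured_rings` is set
#' from the pattern. Idempotent.
#'
#' @param ksp a `ring_kspace`.
#' @param pattern an [make_pattern()] result with matching `n_rings`.
#' @return decimated `ring_kspace`.
#' @export
decimate <- function(ksp, pattern) {
  stopifnot(inherits(ksp, "ring_kspace"),
            inherits(pattern, "undersampling_pattern"))
  if (pattern$n_rings != ksp$traj$n_rings)
    stop("pattern has ", pattern$n_rings, " rings but k-space has ",
         ksp$traj$n_rings)
  out <- ksp
  out$data[, !pattern$measured, , ] <- 0i
  out$measured_rings <- pattern$measured
  out$meta$pattern <- pattern
  out
}

#' Recursion ladder of two-fold reconstruction stages
#'
#' For a nominal acceleration of 2, 4 or 8 returns the ordered list of
#' target patterns of consecutive two-fold reconstructions: R = 8 maps to
#' `[R = 4, R = 2, full]`, R = 4 to `[R = 2, full]`, R = 2 to `[full]`.
#' Each stage's measured ring set strictly contains the previous stage's,
#' and the fully sampled core size is preserved.
#'
#' @param pattern starting [make_pattern()] pattern with
#'   `nominal_R` in `{2, 4, 8}`.
#' @return list of `undersampling_pattern` objects ending with the full
#'   pattern.
#' @export
stage_patterns <- function(pattern) {
  stopifnot(inherits(pattern, "undersampling_pattern"))
  R <- pattern$nominal_R
  if (!R %in% c(2L, 4L, 8L))
    stop("recursion ladder supports nominal_R in {2, 4, 8}, got ", R)
  Rs <- R
  while (Rs[length(Rs)] > 2L) Rs <- c(Rs, Rs[length(Rs)] / 2L)
  stages <- lapply(Rs[-1], function(r)
    make_pattern(pattern$n_rings, r, pattern$n_full_inner))
  c(stages, list(full_pattern(pattern$n_rings, pattern$n_full_inner)))
}
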