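#' Tracking parameters
#'
#' Defaults pin the study protocol: 0.5 mm steps, termination when the
#' interpolated FA at the candidate point drops below 0.25 or the turning
#' ("flip") angle between successive step directions exceeds 45 degrees,
#' one seed per labeled voxel placed at the voxel center, and a safety cap
#' on steps per propagation direction.
#'
#' @param step_mm step length, mm (> 0).
#' @param fa_threshold FA termination threshold, in (0, 1).
#' @param max_angle_deg maximum turning angle per step, degrees, in (0, 90].
#' @param seeds_per_voxel seeds placed per labeled voxel (>= 1).
#' @param max_steps cap on steps per direction (>= 1).
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step_mm = 0.5, fa_threshold = 0.25,
                            max_angle_deg = 45, seeds_per_voxel = 1L,
                            max_steps = 2000L) {
  if (step_mm <= 0) stop_tendtract("bad_params", "step_mm must be > 0")
  if (fa_threshold <= 0 || fa_threshold >= 1) {
    stop_tendtract("bad_params", "fa_threshold must lie in (0, 1)")
  }
  if (max_angle_deg <= 0 || max_angle_deg > 90) {
    stop_tendtract("bad_params", "max_angle_deg must lie in (0, 90]")
  }
  if (max_steps < 1L || seeds_per_voxel < 1L) {
    stop_tendtract("bad_params", "max_steps and seeds_per_voxel must be >= 1")
  }
  structure(list(step_mm = step_mm, fa_threshold = fa_threshold,
                 max_angle_deg = max_angle_deg,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 max_steps = as.integer(max_steps)),
            class = "tracking_params")
}

#' One tensor-deflection (TEND) propagation step
#'
#' Deflects the incoming direction by the local tensor:
#' v_out = normalize(D v_in), sign-aligned to make an acute angle with
#' v_in. With an isotropic tensor the direction passes through unchanged;
#' with a strongly anisotropic tensor it bends toward the principal axis.
#'
#' @param tensor symmetric 3 x 3 diffusion tensor.
#' @param v_in unit direction vector.
#' @return Unit direction vector.
#' @export
tend_step <- function(tensor, v_in) {
  v <- as.vector(tensor %*% v_in)
  n <- vnorm(v)
  if (n < .Machine$double.eps * max(abs(tensor), 1)) {
    stop_tendtract("degenerate_direction", "tensor deflection produced a zero direction")
  }
  v <- v / n
  if (sum(v * v_in) < 0) v <- -v
  v
}

new_streamline <- function(points, fa, parcel = NA_integer_,
                           reasons = c(neg = "none", pos = "none")) {
  structure(list(points = points, fa = fa, parcel = parcel, reasons = reasons),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("streamline: %d points, parcel %s, ends: -%s / +%s\n",
              nrow(x$points), x$parcel, x$reasons[["neg"]], x$reasons[["pos"]]))
  invisible(x)
}

# Propagate one direction from `seed`. Returns list(points, fa, reason)
# where points excludes the seed itself.
propagate <- function(seed, v0, Dflat, fa_flat, dm, affine, params) {
  cos_min <- cos(params$max_angle_deg * pi / 180)
  pts <- matrix(NA_real_, params$max_steps, 3)
  fas <- numeric(params$max_steps)
  p <- seed
  v_prev <- v0
  n_kept <- 0L
  reason <- "max-steps"
  reject_fa <- NA_real_
  reject_angle <- NA_real_
  inv_aff <- solve(affine)
  to_frac <- function(p) (inv_aff %*% c(p, 1))[1:3]
  for (k in seq_len(params$max_steps)) {
    d6 <- interp_at(Dflat, dm, to_frac(p))
    if (is.null(d6)) { reason <- "out-of-bounds"; break }
    v <- tryCatch(tend_step(tensor6_to_mat(d6), v_prev),
                  tendtract_degenerate_direction = function(e) NULL)
    if (is.null(v)) { reason <- "degenerate"; break }
    if (sum(v * v_prev) < cos_min) {
      reason <- "sharp-turn"
      reject_angle <- acos(min(max(sum(v * v_prev), -1), 1)) * 180 / pi
      break
    }
    p_new <- p + params$step_mm * v
    fa_new <- interp_at(fa_flat, dm, to_frac(p_new))
    if (is.null(fa_new)) { reason <- "out-of-bounds"; break }
    if (fa_new < params$fa_threshold) {
      reason <- "low-FA"
      reject_fa <- fa_new
      break
    }
    n_kept <- n_kept + 1L
    pts[n_kept, ] <- p_new
    fas[n_kept] <- fa_new
    p <- p_new
    v_prev <- v
  }
  list(points = pts[seq_len(n_kept), , drop = FALSE],
       fa = fas[seq_len(n_kept)], reason = reason,
       reject_fa = reject_fa, reject_angle = reject_angle)
}

#' Track one streamline from a seed point
#'
#' Bidirectional tensor-deflection propagation: from the seed the tracker
#' follows +e1 and -e1 of the interpolated seed tensor (or +/- `init_dir`
#' when supplied), then concatenates the two half-tracks with the seed
#' appearing once. Each step interpolates the tensor at the current point,
#' deflects the incoming direction ([tend_step()]), and advances by the
#' step length; an end terminates on low FA at the candidate point, on a
#' turning angle above the maximum, on leaving the interpolation hull, or
#' at the step cap. Every retained point carries its interpolated FA.
#'
#' @param seed world point, mm; must lie inside the volume.
#' @param field a [tensor_field()].
#' @param fa a [scalar_map()] of FA on the same grid (computed via
#'   [fa_map()] when omitted).
#' @param params a [tracking_params()].
#' @param init_dir optional unit vector overriding the seed tensor's
#'   principal eigenvector as initial direction.
#' @param parcel optional parcel id stored on the streamline.
#' @return A `streamline`: ordered points (m x 3), per-point FA samples,
#'   parcel id, and a termination reason per end. If the interpolated FA at
#'   the seed is already below threshold the streamline is empty (0 points,
#'   both ends tagged `low-FA`).
#' @export
track_from_seed <- function(seed, field, fa = NULL, params = tracking_params(),
                            init_dir = NULL, parcel = NA_integer_) {
  if (is.null(fa)) fa <- fa_map(field)
  dm <- dim(field$D)[1:3]
  Dflat <- matrix(field$D, prod(dm), 6)
  fa_flat <- matrix(as.vector(fa$values), prod(dm), 1)
  frac <- as.vector(world_to_voxel(seed, field$affine))
  d6 <- interp_at(Dflat, dm, frac)
  if (is.null(d6)) {
    stop_tendtract("out_of_bounds",
                   "seed (%.3f, %.3f, %.3f) mm lies outside the volume",
                   seed[1], seed[2], seed[3])
  }
  fa0 <- interp_at(fa_flat, dm, frac)
  if (fa0 < params$fa_threshold) {
    return(new_streamline(matrix(numeric(0), 0, 3), numeric(0), parcel,
                          c(neg = "low-FA", pos = "low-FA")))
  }
  if (is.null(init_dir)) {
    eg <- eigen(tensor6_to_mat(d6), symmetric = TRUE)
    v0 <- eg$vectors[, 1]
    k <- which.max(abs(v0))
    if (v0[k] < 0) v0 <- -v0
  } else {
    v0 <- normalize(init_dir)
  }
  fwd <- propagate(seed, v0, Dflat, fa_flat, dm, field$affine, params)
  bwd <- propagate(seed, -v0, Dflat, fa_flat, dm, field$affine, params)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(seed, 1, 3), fwd$points)
  fas <- c(rev(bwd$fa), fa0, fwd$fa)
  sl <- new_streamline(pts, fas, parcel, c(neg = bwd$reason, pos = fwd$reason))
  # rejected-candidate diagnostics: the interpolated FA / turning angle that
  # triggered each end's termination, for soundness audits
  sl$end_detail <- list(
    neg = list(fa = bwd$reject_fa, angle = bwd$reject_angle),
    pos = list(fa = fwd$reject_fa, angle = fwd$reject_angle))
  sl
}

# Deterministic in-voxel seed offsets (fractional voxel units, centered on
# 0): the first point is the voxel center; further seeds follow a Halton
# sequence in bases 2, 3, 5 so any seeds-per-voxel count is well spread.
halton_offsets <- function(n) {
  halton1 <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
    r
  }
  if (n == 1L) return(matrix(0, 1, 3))
  off <- t(vapply(seq_len(n - 1L), function(i) {
    c(halton1(i, 2), halton1(i, 3), halton1(i, 5)) - 0.5
  }, numeric(3)))
  rbind(c(0, 0, 0), off)
}

#' Track all seeds of one atlas parcel
#'
#' Seeds are placed in every voxel carrying `parcel_id` (at the voxel
#' center for one seed per voxel, on a deterministic low-discrepancy
#' pattern for more), visited in lexicographic voxel-index order, with one
#' streamline attempt per seed; empty streamlines (seed FA below
#' threshold) are dropped.
#'
#' @param labels integer 3D array of parcel labels (0 = unlabeled).
#' @param parcel_id parcel to seed; must be present in `labels`.
#' @param field a [tensor_field()].
#' @param fa a [scalar_map()] of FA (computed when omitted).
#' @param params a [tracking_params()].
#' @param parcel_name optional tract name stored on the bundle.
#' @param subject_id optional subject identifier.
#' @return An object of class `tract_bundle`: parcel id/name, subject id
#'   and the list of member streamlines.
#' @export
track_parcel <- function(labels, parcel_id, field, fa = NULL,
                         params = tracking_params(), parcel_name = NULL,
                         subject_id = NA_character_) {
  present <- sort(unique(labels[labels > 0]))
  if (!(parcel_id %in% present)) {
    stop_tendtract("bad_parcel",
                   "parcel %d not present in label volume; available: %s",
                   parcel_id, paste(present, collapse = ", "))
  }
  if (is.null(fa)) fa <- fa_map(field)
  vox <- which(labels == parcel_id, arr.ind = TRUE) - 1L
  vox <- vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
  offs <- halton_offsets(params$seeds_per_voxel)
  streamlines <- list()
  for (r in seq_len(nrow(vox))) {
    for (s in seq_len(nrow(offs))) {
      seed <- as.vector(voxel_to_world(vox[r, ] + offs[s, ], field$affine))
      sl <- track_from_seed(seed, field, fa, params, parcel = parcel_id)
      if (nrow(sl$points) > 0L) streamlines[[length(streamlines) + 1L]] <- sl
    }
  }
  structure(list(parcel = as.integer(parcel_id),
                 name = parcel_name %||% paste0("parcel_", parcel_id),
                 subject = subject_id, streamlines = streamlines),
            class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  npts <- sum(vapply(x$streamlines, function(s) nrow(s$points), integer(1)))
  cat(sprintf("tract_bundle '%s' (parcel %d): %d streamlines, %d points\n",
              x$name, x$parcel, length(x$streamlines), npts))
  invisible(x)
}
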