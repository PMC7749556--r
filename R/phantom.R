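#' Fiber-bundle descriptors for diffusion phantoms
#'
#' Bundles are tubes around an analytic centerline: straight segments or
#' circular arcs. Inside a tube the tensor's principal axis follows the
#' local centerline tangent with the stated eigenvalues; the analytic
#' tangent gives tractography tests an exact ground truth.
#'
#' @param center 3-vector, world mm. For `bundle_straight` the segment
#'   midpoint; for `bundle_arc` the center of the circle.
#' @param direction unit 3-vector along a straight bundle.
#' @param half_length half the segment length, mm.
#' @param radius tube radius, mm.
#' @param evals eigenvalues (l1 >= l2 >= l3 > 0) in mm^2/s inside the tube.
#' @param label positive integer parcel id (<= 54) marking the bundle in
#'   the label volume.
#' @param name optional tract name.
#' @return A bundle descriptor (list) consumed by [phantom_spec()].
#' @export
bundle_straight <- function(center, direction, half_length, radius,
                            evals = c(1.7, 0.3, 0.2) * 1e-3,
                            label = 1L, name = NULL) {
  list(kind = "straight", center = as.numeric(center),
       direction = normalize(as.numeric(direction)),
       half_length = half_length, radius = radius,
       evals = sort(as.numeric(evals), decreasing = TRUE),
       label = as.integer(label), name = name)
}

#' @rdname bundle_straight
#' @param circle_radius radius of the arc's circle, mm (curvature radius).
#' @param theta_range angular range of the arc in radians, e.g.
#'   `c(0, pi/2)` for a quarter circle.
#' @param u,v orthonormal 3-vectors spanning the arc's plane; the
#'   centerline is `center + circle_radius * (cos(t) u + sin(t) v)`.
#' @export
bundle_arc <- function(center, circle_radius, theta_range = c(0, pi / 2),
                       u = c(1, 0, 0), v = c(0, 1, 0), radius = 3,
                       evals = c(1.7, 0.3, 0.2) * 1e-3,
                       label = 1L, name = NULL) {
  u <- normalize(as.numeric(u)); v <- as.numeric(v)
  v <- normalize(v - sum(v * u) * u)   # enforce orthonormality
  list(kind = "arc", center = as.numeric(center),
       circle_radius = circle_radius, theta_range = as.numeric(theta_range),
       u = u, v = v, radius = radius,
       evals = sort(as.numeric(evals), decreasing = TRUE),
       label = as.integer(label), name = name)
}

#' Phantom specification
#'
#' Describes a synthetic diffusion scene: grid geometry, fiber bundles
#' embedded in an isotropic background, baseline signal and Rician noise
#' level. Defaults emulate a clinical DTI acquisition: 2.5 mm isotropic
#' voxels, white-matter-like bundle eigenvalues, SNR ~ 30 on the b = 0
#' signal.
#'
#' @param grid integer 3-vector of voxel counts (nx, ny, nz).
#' @param voxel_mm voxel size, mm (isotropic scalar or length 3).
#' @param bundles list of [bundle_straight()] / [bundle_arc()] descriptors.
#' @param background_evals isotropic background eigenvalues, mm^2/s.
#' @param S0 baseline (b = 0) signal.
#' @param sigma Rician noise SD; the default S0/30 is a typical clinical
#'   DTI signal-to-noise ratio.
#' @param seed RNG seed for noise realizations.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(20L, 20L, 20L), voxel_mm = 2.5,
                         bundles = list(),
                         background_evals = c(0.7, 0.7, 0.7) * 1e-3,
                         S0 = 1000, sigma = S0 / 30, seed = 1L) {
  spec <- structure(list(grid = as.integer(grid),
                         voxel_mm = rep(as.numeric(voxel_mm), length.out = 3L),
                         bundles = bundles,
                         background_evals = as.numeric(background_evals),
                         S0 = S0, sigma = sigma, seed = seed),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid) != 3L || any(spec$grid < 1L)) {
    stop_tendtract("bad_spec", "grid must be three positive voxel counts")
  }
  if (any(spec$voxel_mm <= 0)) stop_tendtract("bad_spec", "voxel size must be > 0")
  check_evals <- function(ev, what) {
    if (length(ev) != 3L || any(ev <= 0) || is.unsorted(rev(ev))) {
      stop_tendtract("bad_spec",
                     "%s eigenvalues must satisfy l1 >= l2 >= l3 > 0", what)
    }
  }
  check_evals(spec$background_evals, "background")
  labels <- integer(0)
  for (b in spec$bundles) {
    check_evals(b$evals, sprintf("bundle %d", b$label))
    if (b$radius <= max(spec$voxel_mm) / 2) {
      stop_tendtract("bad_spec",
                     "bundle %d radius %.3g mm must exceed half a voxel (%.3g mm)",
                     b$label, b$radius, max(spec$voxel_mm) / 2)
    }
    if (b$label < 1L || b$label > 54L) {
      stop_tendtract("bad_spec", "parcel labels must be integers in 1..54, got %d", b$label)
    }
    labels <- c(labels, b$label)
  }
  if (anyDuplicated(labels)) {
    stop_tendtract("bad_spec", "duplicate parcel label(s): %s",
                   paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (spec$sigma < 0) stop_tendtract("bad_spec", "sigma must be >= 0")
  invisible(spec)
}

# Distance from points (n x 3, world mm) to a bundle's centerline, plus the
# unit tangent at the nearest centerline point and an in-extent flag.
bundle_geometry <- function(bundle, pts) {
  n <- nrow(pts)
  if (bundle$kind == "straight") {
    rel <- sweep(pts, 2, bundle$center)
    t_par <- as.vector(rel %*% bundle$direction)
    perp <- rel - outer(t_par, bundle$direction)
    dist <- sqrt(rowSums(perp^2))
    inside <- abs(t_par) <= bundle$half_length & dist <= bundle$radius
    tang <- matrix(bundle$direction, n, 3, byrow = TRUE)
    list(inside = inside, tangent = tang)
  } else if (bundle$kind == "arc") {
    w <- c(bundle$u[2] * bundle$v[3] - bundle$u[3] * bundle$v[2],
           bundle$u[3] * bundle$v[1] - bundle$u[1] * bundle$v[3],
           bundle$u[1] * bundle$v[2] - bundle$u[2] * bundle$v[1])
    rel <- sweep(pts, 2, bundle$center)
    a <- as.vector(rel %*% bundle$u)
    b <- as.vector(rel %*% bundle$v)
    h <- as.vector(rel %*% w)
    r_in_plane <- sqrt(a^2 + b^2)
    theta <- atan2(b, a)
    th <- bundle$theta_range
    # normalize angle into [th1, th1 + 2pi) before range test
    theta_n <- (theta - th[1]) %% (2 * pi) + th[1]
    dist <- sqrt((r_in_plane - bundle$circle_radius)^2 + h^2)
    inside <- theta_n >= th[1] & theta_n <= th[2] & dist <= bundle$radius
    tang <- outer(-sin(theta), bundle$u) + outer(cos(theta), bundle$v)
    list(inside = inside, tangent = tang)
  } else {
    stop_tendtract("bad_spec", "unknown bundle kind '%s'", bundle$kind)
  }
}

# Analytic centerline point nearest to p (used by tests as tracking oracle).
centerline_distance <- function(bundle, pts) {
  if (bundle$kind == "straight") {
    rel <- sweep(pts, 2, bundle$center)
    t_par <- as.vector(rel %*% bundle$direction)
    t_par <- pmin(pmax(t_par, -bundle$half_length), bundle$half_length)
    near <- sweep(outer(t_par, bundle$direction), 2, bundle$center, FUN = "+")
    sqrt(rowSums((pts - near)^2))
  } else {
    rel <- sweep(pts, 2, bundle$center)
    a <- as.vector(rel %*% bundle$u)
    b <- as.vector(rel %*% bundle$v)
    theta <- atan2(b, a)
    th <- bundle$theta_range
    span <- th[2] - th[1]
    # wrap into (th1 - (2pi - span)/2, th1 + span + (2pi - span)/2] so points
    # just before the start clamp to the start, not the far end
    off <- (theta - th[1]) %% (2 * pi)
    off[off > span + (2 * pi - span) / 2] <- off[off > span + (2 * pi - span) / 2] - 2 * pi
    theta <- th[1] + pmin(pmax(off, 0), span)
    near <- sweep(bundle$circle_radius *
                    (outer(cos(theta), bundle$u) + outer(sin(theta), bundle$v)),
                  2, bundle$center, FUN = "+")
    sqrt(rowSums((pts - near)^2))
  }
}

#' Build a ground-truth tensor field and parcel label volume
#'
#' Voxels whose centers fall inside a bundle's tube receive that bundle's
#' eigenvalues with the principal axis along the local centerline tangent
#' (the remaining two eigenvectors complete an orthonormal frame built
#' deterministically from the tangent); all other voxels carry the
#' isotropic background tensor. The label volume holds each bundle's
#' parcel id over its voxels and 0 elsewhere. Bundles claiming the same
#' voxel are rejected.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `field` (a [tensor_field()], all tensors
#'   symmetric positive definite), `labels` (integer 3D array) and `spec`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dm <- spec$grid
  nvox <- prod(dm)
  # voxel centers in world mm (0-based indices, affine = diag(voxel) here)
  idx <- arrayInd(seq_len(nvox), dm) - 1L
  pts <- sweep(idx, 2, spec$voxel_mm, FUN = "*")

  Dmat <- matrix(0, nvox, 6)
  bg <- spec$background_evals
  Dmat[, 1] <- bg[1]; Dmat[, 2] <- bg[2]; Dmat[, 3] <- bg[3]
  labels <- integer(nvox)

  for (b in spec$bundles) {
    geo <- bundle_geometry(b, pts)
    ins <- which(geo$inside)
    clash <- ins[labels[ins] != 0L]
    if (length(clash) > 0L) {
      stop_tendtract("overlap",
                     "bundle %d overlaps voxels already labeled %s; bundles must be disjoint",
                     b$label, paste(unique(labels[clash]), collapse = ", "))
    }
    labels[ins] <- b$label
    lam <- b$evals
    for (v in ins) {
      t1 <- geo$tangent[v, ]
      # deterministic orthonormal complement of the tangent
      ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e2 <- normalize(ref - sum(ref * t1) * t1)
      e3 <- c(t1[2] * e2[3] - t1[3] * e2[2],
              t1[3] * e2[1] - t1[1] * e2[3],
              t1[1] * e2[2] - t1[2] * e2[1])
      D <- lam[1] * tcrossprod(t1) + lam[2] * tcrossprod(e2) + lam[3] * tcrossprod(e3)
      Dmat[v, ] <- mat_to_tensor6(D)
    }
  }

  field <- tensor_field(array(Dmat, c(dm, 6L)), voxel_mm = spec$voxel_mm)
  list(field = field, labels = array(labels, dm), spec = spec)
}

#' Simulate diffusion-weighted volumes from a tensor field
#'
#' Applies the monoexponential forward model S = S0 exp(-b g' D g) per
#' voxel and volume, then Rician noise: the reported magnitude is
#' sqrt((S + e1)^2 + e2^2) with e1, e2 ~ Normal(0, sigma^2), the standard
#' magnitude-MRI noise model. `sigma = 0` returns the noiseless signal
#' exactly; results are deterministic for a fixed seed.
#'
#' @param field a [tensor_field()].
#' @param scheme a [gradient_scheme()].
#' @param S0 baseline signal.
#' @param sigma Rician noise SD (>= 0).
#' @param seed RNG seed.
#' @return 4D array (nx, ny, nz, n volumes).
#' @export
simulate_dwi <- function(field, scheme, S0 = 1000, sigma = 0, seed = 1L) {
  validate_gradient_scheme(scheme)
  if (sigma < 0) stop_tendtract("bad_input", "sigma must be >= 0")
  dm <- dim(field$D)
  nvox <- prod(dm[1:3])
  Dmat <- matrix(field$D, nvox, 6)
  b <- scheme$bvals
  g <- scheme$bvecs
  # coefficients of g' D g in the 6-component storage
  C <- rbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  quad <- Dmat %*% C                       # nvox x nvol
  S <- S0 * exp(-sweep(quad, 2, b, FUN = "*"))
  if (sigma > 0) {
    S <- with_seed(seed, {
      e1 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S))
      e2 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S))
      sqrt((S + e1)^2 + e2^2)
    })
  }
  array(S, c(dm[1:3], length(b)))
}
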