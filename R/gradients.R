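#' Diffusion gradient schemes
#'
#' A gradient scheme pairs one b-value with one encoding direction per DWI
#' volume. b = 0 entries carry a zero direction vector; diffusion-weighted
#' entries carry unit-norm directions. The same object drives both the
#' forward signal simulation and the tensor fit.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs numeric matrix (n x 3) of encoding directions; rows with
#'   b > 0 must have unit Euclidean norm, b = 0 rows may be all zero.
#' @return An object of class `gradient_scheme`: a list with elements
#'   `bvals` and `bvecs`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  obj <- structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
                   class = "gradient_scheme")
  validate_gradient_scheme(obj)
  obj
}

#' Validate a gradient scheme
#'
#' Checks the invariants required for tensor fitting: equal lengths of
#' b-values and directions, unit norm (within 1e-6) for every b > 0
#' direction, at least one b = 0 entry, and at least 6 noncollinear
#' diffusion-weighted directions (the minimum that makes the 7-parameter
#' log-linear tensor fit determinate).
#'
#' @param scheme a `gradient_scheme`.
#' @return The scheme, invisibly; errors on violation.
#' @export
validate_gradient_scheme <- function(scheme) {
  bvals <- scheme$bvals
  bvecs <- scheme$bvecs
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3L) {
    stop_tendtract("bad_scheme",
                   "bvals (%d) and bvecs (%d x %d) shapes disagree",
                   length(bvals), nrow(bvecs), ncol(bvecs))
  }
  dw <- bvals > 0
  if (sum(!dw) < 1L) {
    stop_tendtract("bad_scheme", "scheme needs at least one b = 0 entry")
  }
  if (sum(dw) < 6L) {
    stop_tendtract("bad_scheme",
                   "scheme has %d diffusion-weighted directions; >= 6 needed for a tensor fit",
                   sum(dw))
  }
  norms <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop_tendtract("bad_scheme",
                   "b > 0 directions must be unit norm (max deviation %.2e)",
                   max(abs(norms - 1)))
  }
  # Noncollinearity in the sense that matters: the quadratic-form design
  # matrix must have full column rank.
  if (qr(tensor_design_matrix(scheme))$rank < 7L) {
    stop_tendtract("bad_scheme",
                   "directions are collinear/degenerate: tensor design matrix is rank deficient")
  }
  invisible(scheme)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient_scheme: %d volumes (%d b=0, %d diffusion-weighted, b = %s s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}

#' Generate a diffusion encoding scheme by electrostatic repulsion
#'
#' Places `n_dirs` unit vectors on the sphere by minimizing the Coulomb
#' energy of the point set together with its antipodes, the standard way
#' acquisition schemes spread noncollinear directions uniformly. The
#' default geometry is 30 directions at b = 1,000 s/mm^2 plus one b = 0
#' volume. Deterministic for a fixed `seed`.
#'
#' @param n_dirs number of diffusion-weighted directions (>= 6).
#' @param b b-value in s/mm^2 for the weighted volumes.
#' @param n_b0 number of unweighted (b = 0) volumes, listed first.
#' @param seed RNG seed for the initial placement.
#' @param n_iter projected-gradient iterations for the repulsion solve.
#' @return A [gradient_scheme()].
#' @export
make_gradient_scheme <- function(n_dirs = 30L, b = 1000, n_b0 = 1L, seed = 1L,
                                 n_iter = 400L) {
  if (n_dirs < 6L) {
    stop_tendtract("bad_scheme",
                   "n_dirs = %d would leave the tensor under-determined; need >= 6", n_dirs)
  }
  if (n_b0 < 1L) stop_tendtract("bad_scheme", "n_b0 must be >= 1")
  dirs <- with_seed(seed, repulsion_directions(n_dirs, n_iter))
  bvals <- c(rep(0, n_b0), rep(b, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  gradient_scheme(bvals, bvecs)
}

# Minimize sum over unordered pairs of 1/||xi - xj|| + 1/||xi + xj||
# (antipodal symmetry) by projected gradient descent with backtracking.
repulsion_directions <- function(n, n_iter = 400L) {
  x <- matrix(stats::rnorm(n * 3), n, 3)
  x <- x / sqrt(rowSums(x^2))

  energy <- function(x) {
    e <- 0
    for (i in seq_len(n - 1L)) {
      di <- x[(i + 1L):n, , drop = FALSE]
      d1 <- sqrt(rowSums(sweep(di, 2, x[i, ])^2))
      d2 <- sqrt(rowSums(sweep(-di, 2, x[i, ])^2))
      e <- e + sum(1 / d1 + 1 / d2)
    }
    e
  }
  grad <- function(x) {
    g <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      diff1 <- sweep(-x, 2, x[i, ], FUN = "+")   # xi - xj
      diff2 <- sweep(x, 2, x[i, ], FUN = "+")    # xi + xj
      d1 <- sqrt(rowSums(diff1^2)); d1[i] <- Inf
      d2 <- sqrt(rowSums(diff2^2)); d2[i] <- Inf
      g[i, ] <- colSums(diff1 / d1^3) + colSums(diff2 / d2^3)
    }
    g
  }

  step <- 1 / n
  e <- energy(x)
  for (it in seq_len(n_iter)) {
    g <- grad(x)
    # Remove the radial component; only tangential motion changes geometry.
    g <- g - x * rowSums(g * x)
    repeat {
      xn <- x + step * g
      xn <- xn / sqrt(rowSums(xn^2))
      en <- energy(xn)
      if (en < e || step < 1e-12) break
      step <- step / 2
    }
    if (e - en < 1e-12 * abs(e)) { x <- xn; break }
    x <- xn; e <- en
    step <- step * 1.2
  }
  x
}

#' Minimum pairwise angular separation of a direction set
#'
#' Angles are measured between axes (direction and antipode identified),
#' the relevant notion for diffusion encoding.
#'
#' @param bvecs n x 3 matrix of unit vectors.
#' @return Smallest pairwise angle in degrees.
#' @export
min_angular_separation <- function(bvecs) {
  g <- abs(tcrossprod(bvecs))
  diag(g) <- 0
  g[g > 1] <- 1
  acos(max(g)) * 180 / pi
}

#' Read / write FSL-style bval and bvec files
#'
#' The FSL text dialect stores b-values as one whitespace-separated row and
#' directions as three rows (x, y, z components), one column per volume.
#' Non-unit b > 0 columns are renormalized on read with a warning.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return A [gradient_scheme()].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- utils::read.table(bvec_path)
  if (nrow(rows) != 3L) {
    stop_tendtract("bad_scheme", "bvec file must have 3 rows, found %d", nrow(rows))
  }
  bvecs <- t(as.matrix(rows))
  if (nrow(bvecs) != length(bvals)) {
    stop_tendtract("bad_scheme",
                   "bvec has %d columns but bval lists %d volumes",
                   nrow(bvecs), length(bvals))
  }
  dw <- bvals > 0
  norms <- sqrt(rowSums(bvecs^2))
  bad <- dw & abs(norms - 1) > 1e-6
  if (any(bad)) {
    warning(sprintf("%d b > 0 direction(s) were not unit norm; renormalizing", sum(bad)))
    bvecs[bad, ] <- bvecs[bad, ] / norms[bad]
  }
  gradient_scheme(bvals, bvecs)
}

#' @rdname read_bvals_bvecs
#' @param scheme a `gradient_scheme` to write.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  validate_gradient_scheme(scheme)
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  vec_rows <- apply(t(scheme$bvecs), 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  })
  writeLines(vec_rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}
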