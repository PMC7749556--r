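#' Per-voxel diffusion tensor fields
#'
#' A `tensor_field` stores one symmetric diffusion tensor per voxel as its
#' six unique components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s, together
#' with the voxel size and the voxel-to-world affine. Voxel indices are
#' 0-based and the affine maps the *center* of voxel (i, j, k) to world mm.
#'
#' @param D numeric array of dim (nx, ny, nz, 6).
#' @param voxel_mm voxel edge lengths in mm (scalar or length-3).
#' @param affine 4 x 4 voxel-to-world matrix; defaults to a scaled identity
#'   placing voxel (0,0,0) at the world origin.
#' @param mask optional logical array (nx, ny, nz); voxels outside the mask
#'   hold zero tensors and are ignored downstream.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(D, voxel_mm = 2.5, affine = NULL, mask = NULL) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4] == 6L)
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3L)
  if (any(voxel_mm <= 0)) stop_tendtract("bad_field", "voxel size must be > 0")
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
  }
  if (is.null(mask)) mask <- array(TRUE, dim(D)[1:3])
  stopifnot(all(dim(mask) == dim(D)[1:3]))
  structure(list(D = D, voxel_mm = voxel_mm, affine = affine, mask = mask),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("tensor_field: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %d in mask\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              sum(x$mask)))
  invisible(x)
}

#' Scalar maps sharing a tensor field's geometry
#'
#' @param values 3D numeric array (e.g. FA in `[0, 1]` or MD in mm^2/s).
#' @param voxel_mm,affine geometry, as in [tensor_field()].
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, voxel_mm = 2.5, affine = NULL) {
  stopifnot(length(dim(values)) == 3L)
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3L)
  if (is.null(affine)) affine <- diag(c(voxel_mm, 1))
  structure(list(values = values, voxel_mm = voxel_mm, affine = affine),
            class = "scalar_map")
}

# Design matrix of the log-linear tensor model: for volume i with b-value b
# and direction g, ln S_i = ln S0 - b * g' D g, i.e. row
# [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]
# acting on beta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design_matrix <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves the 7-parameter system ln S = ln S0 - b g' D g per voxel by
#' ordinary least squares on log signals (the classical DTI fit); a
#' weighted variant (weights = squared predicted signal, one reweighting
#' pass from the OLS solution) is available with `method = "wls"`.
#' Non-positive signals are clamped to a small positive floor before the
#' log. Voxels with all-zero signal are excluded from the mask and carry a
#' zero tensor rather than raising an error.
#'
#' @param dwi 4D numeric array (nx, ny, nz, nvol).
#' @param scheme the [gradient_scheme()] the data were acquired with; its
#'   length must equal the number of volumes.
#' @param mask optional logical array restricting the fit.
#' @param voxel_mm,affine output geometry (see [tensor_field()]).
#' @param method `"ols"` (default) or `"wls"`.
#' @return A [tensor_field()] with per-voxel attribute array `S0` attached
#'   as element `S0`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL, voxel_mm = 2.5,
                       affine = NULL, method = c("ols", "wls")) {
  method <- match.arg(method)
  validate_gradient_scheme(scheme)
  dm <- dim(dwi)
  if (length(dm) != 4L) stop_tendtract("bad_input", "dwi must be a 4D array")
  if (dm[4] != length(scheme$bvals)) {
    stop_tendtract("bad_input",
                   "dwi has %d volumes but the scheme lists %d entries",
                   dm[4], length(scheme$bvals))
  }
  X <- tensor_design_matrix(scheme)
  if (qr(X)$rank < 7L) {
    stop_tendtract("bad_scheme", "tensor design matrix is rank deficient")
  }

  nvox <- prod(dm[1:3])
  S <- matrix(dwi, nvox, dm[4])            # voxels x volumes
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  fit_mask <- as.vector(mask) & rowSums(abs(S)) > 0

  floor_val <- 1e-6 * max(abs(S), 1)
  B <- matrix(0, nvox, 7)
  if (any(fit_mask)) {
    L <- t(log(pmax(S[fit_mask, , drop = FALSE], floor_val)))  # volumes x voxels
    beta <- qr.coef(qr(X), L)                                  # 7 x voxels
    if (method == "wls") {
      # One reweighting pass: weights are the squared predicted signals,
      # the usual first-order correction for log-transformed noise.
      pred <- X %*% beta
      for (j in seq_len(ncol(beta))) {
        w <- exp(pred[, j])^2
        beta[, j] <- qr.coef(qr(X * sqrt(w)), sqrt(w) * L[, j])
      }
    }
    B[fit_mask, ] <- t(beta)
  }

  D <- array(B[, 2:7], c(dm[1:3], 6L))
  field <- tensor_field(D, voxel_mm = voxel_mm, affine = affine,
                        mask = array(fit_mask, dm[1:3]))
  field$S0 <- array(exp(B[, 1]) * fit_mask, dm[1:3])
  field
}

#' Eigen-decompose a tensor field
#'
#' Per voxel, returns eigenvalues sorted descending and the first
#' (principal) eigenvector with a deterministic sign convention: the
#' largest-magnitude component is made positive.
#'
#' @param field a [tensor_field()].
#' @return A list with 3D arrays `lambda1`, `lambda2`, `lambda3` and a 4D
#'   array `e1` of dim (nx, ny, nz, 3).
#' @export
eigen_decompose <- function(field) {
  dm <- dim(field$D)
  nvox <- prod(dm[1:3])
  Dmat <- matrix(field$D, nvox, 6)
  lam <- matrix(0, nvox, 3)
  e1 <- matrix(0, nvox, 3)
  idx <- which(as.vector(field$mask))
  for (v in idx) {
    eg <- eigen(tensor6_to_mat(Dmat[v, ]), symmetric = TRUE)
    lam[v, ] <- eg$values                  # eigen() sorts descending
    vec <- eg$vectors[, 1]
    k <- which.max(abs(vec))
    if (vec[k] < 0) vec <- -vec
    e1[v, ] <- vec
  }
  list(lambda1 = array(lam[, 1], dm[1:3]),
       lambda2 = array(lam[, 2], dm[1:3]),
       lambda3 = array(lam[, 3], dm[1:3]),
       e1 = array(e1, c(dm[1:3], 3L)))
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#'      sqrt(l1^2 + l2^2 + l3^2), the normalized eigenvalue dispersion:
#' 0 for isotropic diffusion, 1 in the single-axis ("stick") limit.
#' All-zero voxels get FA = 0 (background convention). Vectorized over
#' arrays of any (matching) shape; scale-invariant by construction.
#'
#' @param lambda1,lambda2,lambda3 eigenvalue arrays (or scalars), sorted or
#'   not; the formula is symmetric.
#' @return FA values with the shape of the inputs, in `[0, 1]`.
#' @export
compute_fa <- function(lambda1, lambda2, lambda3) {
  num <- sqrt(0.5) * sqrt((lambda1 - lambda2)^2 +
                          (lambda2 - lambda3)^2 +
                          (lambda1 - lambda3)^2)
  den <- sqrt(lambda1^2 + lambda2^2 + lambda3^2)
  fa <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  pmin(pmax(fa, 0), 1)
}

#' FA map of a tensor field
#'
#' Eigen-decomposes the field, clamps any negative eigenvalues from noisy
#' fits to zero (recorded in the `negative_eigenvalues` attribute as a
#' per-voxel quality flag), and evaluates [compute_fa()].
#'
#' @param field a [tensor_field()].
#' @return A [scalar_map()] of FA with the field's geometry.
#' @export
fa_map <- function(field) {
  eg <- eigen_decompose(field)
  neg <- eg$lambda1 < 0 | eg$lambda2 < 0 | eg$lambda3 < 0
  fa <- compute_fa(pmax(eg$lambda1, 0), pmax(eg$lambda2, 0), pmax(eg$lambda3, 0))
  fa[!field$mask] <- 0
  out <- scalar_map(fa, voxel_mm = field$voxel_mm, affine = field$affine)
  attr(out, "negative_eigenvalues") <- neg
  out
}

#' Mean diffusivity map of a tensor field
#'
#' MD = trace(D)/3 per voxel, in mm^2/s.
#'
#' @param field a [tensor_field()].
#' @return A [scalar_map()].
#' @export
md_map <- function(field) {
  md <- (field$D[, , , 1] + field$D[, , , 2] + field$D[, , , 3]) / 3
  md[!field$mask] <- 0
  scalar_map(md, voxel_mm = field$voxel_mm, affine = field$affine)
}
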