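fa_closed_form <- function(l) {
  sqrt(0.5) * sqrt((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[1] - l[3])^2) /
    sqrt(sum(l^2))
}

test_that("straight-bundle voxels carry the bundle tensor aligned with +x", {
  fx <- straight_fixture()
  ph <- fx$phantom
  inside <- which(ph$labels == 3L)
  expect_gt(length(inside), 10L)
  eg <- eigen_decompose(ph$field)
  e1x <- abs(array(eg$e1, c(prod(dim(ph$labels)), 3))[inside, 1])
  expect_true(all(abs(e1x - 1) < 1e-12))
  fa <- fa_map(ph$field)
  expect_equal(unique(round(fa$values[inside], 10)),
               round(fa_closed_form(c(1.7, 0.3, 0.2) * 1e-3), 10))
  expect_equal(fa_closed_form(c(1.7, 0.3, 0.2) * 1e-3), 0.836, tolerance = 1e-3)
  expect_true(all(fa$values[ph$labels == 0L] < 1e-9))
})

test_that("arc-bundle principal axes follow the analytic tangent within 1 degree", {
  fx <- arc_fixture()
  ph <- fx$phantom
  dm <- dim(ph$labels)
  inside <- which(ph$labels == 2L)
  eg <- eigen_decompose(ph$field)
  e1 <- array(eg$e1, c(prod(dm), 3))[inside, , drop = FALSE]
  idx <- arrayInd(inside, dm) - 1L
  pts <- sweep(idx, 2, ph$field$voxel_mm, "*")
  tang <- tendtract:::bundle_geometry(fx$bundle, pts)$tangent
  cosang <- abs(rowSums(e1 * tang))
  expect_true(all(acos(pmin(cosang, 1)) * 180 / pi < 1))
})

test_that("an empty bundle list yields an all-isotropic, unlabeled phantom", {
  ph <- make_phantom(phantom_spec(grid = c(6, 6, 6), bundles = list()))
  expect_true(all(ph$labels == 0L))
  expect_true(all(abs(fa_map(ph$field)$values) < 1e-12))
  lam <- eigen_decompose(ph$field)
  expect_true(all(abs(lam$lambda1 - 0.7e-3) < 1e-15))
})

test_that("phantom validation rejects overlap, bad radii and bad labels", {
  b1 <- bundle_straight(c(10, 10, 10), c(1, 0, 0), 8, 3, label = 1)
  b2 <- bundle_straight(c(10, 10, 10), c(0, 1, 0), 8, 3, label = 2)
  expect_error(make_phantom(phantom_spec(grid = c(9, 9, 9), bundles = list(b1, b2))),
               class = "tendtract_overlap")
  thin <- bundle_straight(c(10, 10, 10), c(1, 0, 0), 8, 1.0, label = 1)
  expect_error(phantom_spec(grid = c(9, 9, 9), bundles = list(thin)),
               class = "tendtract_bad_spec")
  high <- bundle_straight(c(10, 10, 10), c(1, 0, 0), 8, 3, label = 99)
  expect_error(phantom_spec(grid = c(9, 9, 9), bundles = list(high)),
               class = "tendtract_bad_spec")
})

test_that("the noiseless forward model matches closed-form signals", {
  # single-voxel fields exercised through a tiny grid
  D6 <- c(1.7, 0.3, 0.2, 0, 0, 0) * 1e-3
  field <- tensor_field(array(rep(D6, each = 8), c(2, 2, 2, 6)))
  scheme <- gradient_scheme(c(0, 1000, 1000, 1000, 1000, 1000, 1000, 1000),
                            rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                  c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                                  c(0, 1, 1) / sqrt(2), c(1, 1, 1) / sqrt(3)))
  S <- simulate_dwi(field, scheme, S0 = 1000, sigma = 0)
  expect_equal(S[1, 1, 1, 1], 1000)                          # b=0 baseline
  expect_equal(S[1, 1, 1, 2], 1000 * exp(-1.7), tolerance = 1e-12)
  expect_equal(S[2, 2, 2, 3], 1000 * exp(-0.3), tolerance = 1e-12)

  iso <- tensor_field(array(rep(c(0.7, 0.7, 0.7, 0, 0, 0) * 1e-3, each = 8),
                            c(2, 2, 2, 6)))
  Si <- simulate_dwi(iso, scheme, S0 = 500, sigma = 0)
  dwvals <- Si[1, 1, 1, scheme$bvals > 0]
  expect_true(all(abs(dwvals - 500 * exp(-0.7)) < 1e-9))     # isotropy
})

test_that("Rician noise is reproducible and has the expected zero-signal floor", {
  zero <- tensor_field(array(0, c(12, 12, 12, 6)))
  scheme <- make_gradient_scheme(10, seed = 1)
  S1 <- simulate_dwi(zero, scheme, S0 = 0, sigma = 10, seed = 5)
  S2 <- simulate_dwi(zero, scheme, S0 = 0, sigma = 10, seed = 5)
  expect_identical(S1, S2)
  # E|noise| at S = 0 is sigma * sqrt(pi/2)
  expect_equal(mean(S1), 10 * sqrt(pi / 2), tolerance = 0.01)
  S3 <- simulate_dwi(zero, scheme, S0 = 0, sigma = 0, seed = 5)
  expect_true(all(S3 == 0))
})
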