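test_that("noiseless simulate/fit round trip recovers tensors exactly", {
  fx <- straight_fixture()
  scheme <- make_gradient_scheme(30, seed = 1)
  dwi <- simulate_dwi(fx$phantom$field, scheme, S0 = 1000, sigma = 0)
  for (m in c("ols", "wls")) {
    fit <- fit_tensor(dwi, scheme, method = m)
    rel <- sqrt(sum((fit$D - fx$phantom$field$D)^2)) / sqrt(sum(fx$phantom$field$D^2))
    expect_lt(rel, 1e-8)
  }
})

test_that("isotropic noiseless data recover MD exactly and FA of zero", {
  iso <- tensor_field(array(rep(c(0.7, 0.7, 0.7, 0, 0, 0) * 1e-3, each = 27),
                            c(3, 3, 3, 6)))
  scheme <- make_gradient_scheme(12, seed = 2)
  fit <- fit_tensor(simulate_dwi(iso, scheme, S0 = 800, sigma = 0), scheme)
  expect_equal(as.vector(md_map(fit)$values), rep(0.7e-3, 27), tolerance = 1e-10)
  expect_true(all(fa_map(fit)$values < 1e-7))
})

test_that("under Rician noise at SNR 30 the median recovered FA stays within 0.03", {
  D6 <- c(1.7, 0.3, 0.2, 0, 0, 0) * 1e-3
  truth_fa <- compute_fa(1.7e-3, 0.3e-3, 0.2e-3)
  field <- tensor_field(array(rep(D6, each = 512), c(8, 8, 8, 6)))
  scheme <- make_gradient_scheme(30, seed = 1)
  dwi <- simulate_dwi(field, scheme, S0 = 1000, sigma = 1000 / 30, seed = 11)
  fit <- fit_tensor(dwi, scheme)
  expect_lt(abs(stats::median(fa_map(fit)$values) - truth_fa), 0.03)
})

test_that("fit_tensor validates volume counts and masks dead voxels", {
  scheme <- make_gradient_scheme(8, seed = 1)
  expect_error(fit_tensor(array(1, c(2, 2, 2, 5)), scheme),
               class = "tendtract_bad_input")
  dwi <- simulate_dwi(tensor_field(array(rep(c(1, 1, 1, 0, 0, 0) * 1e-3, each = 8),
                                         c(2, 2, 2, 6))), scheme, S0 = 100)
  dwi[1, 1, 1, ] <- 0
  fit <- fit_tensor(dwi, scheme)
  expect_false(fit$mask[1, 1, 1])
  expect_true(all(fit$D[1, 1, 1, ] == 0))
})

test_that("eigen decomposition sorts, normalizes, fixes signs and reconstructs", {
  f1 <- tensor_field(array(rep(c(3, 2, 1, 0, 0, 0), each = 1), c(1, 1, 1, 6)),
                     voxel_mm = 1)
  eg <- eigen_decompose(f1)
  expect_equal(c(eg$lambda1, eg$lambda2, eg$lambda3), c(3, 2, 1))
  expect_equal(abs(as.vector(eg$e1)), c(1, 0, 0))

  iso <- tensor_field(array(c(2, 2, 2, 0, 0, 0), c(1, 1, 1, 6)), voxel_mm = 1)
  egi <- eigen_decompose(iso)
  expect_equal(sqrt(sum(egi$e1^2)), 1)

  set.seed(21)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A) + diag(3) * 0.1
    f <- tensor_field(array(tendtract:::mat_to_tensor6(S), c(1, 1, 1, 6)),
                      voxel_mm = 1)
    e <- eigen_decompose(f)
    vals <- c(e$lambda1, e$lambda2, e$lambda3)
    full <- eigen(S, symmetric = TRUE)
    recon <- full$vectors %*% diag(full$values) %*% t(full$vectors)
    expect_equal(vals, full$values, tolerance = 1e-12)
    expect_lt(max(abs(recon - S)), 1e-10)
    # sign convention: largest-magnitude component of e1 is positive
    v <- as.vector(e$e1)
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("FA hits its closed-form limits and is scale invariant", {
  expect_equal(compute_fa(1, 1, 1), 0)
  expect_equal(compute_fa(1, 0, 0), 1)
  expect_equal(compute_fa(0, 0, 0), 0)   # background convention
  set.seed(31)
  l <- matrix(runif(3000, 0.05, 3), ncol = 3)
  base <- compute_fa(l[, 1], l[, 2], l[, 3])
  for (c_scale in c(1e-3, 7, 1e4)) {
    expect_equal(compute_fa(c_scale * l[, 1], c_scale * l[, 2], c_scale * l[, 3]),
                 base, tolerance = 1e-12)
  }
  expect_true(all(base >= 0 & base <= 1))
})

test_that("negative eigenvalues are clamped and flagged in the FA map", {
  # an indefinite symmetric matrix can arise from noisy fits
  D6 <- c(1, 1, -0.5, 0, 0, 0)
  f <- tensor_field(array(D6, c(1, 1, 1, 6)), voxel_mm = 1)
  fa <- fa_map(f)
  expect_true(attr(fa, "negative_eigenvalues")[1, 1, 1])
  expect_true(fa$values >= 0 && fa$values <= 1)
})
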