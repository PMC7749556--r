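test_that("tend_step deflects toward the tensor's principal axis", {
  expect_equal(tend_step(diag(3), c(0, 1, 0)), c(0, 1, 0))          # isotropic identity
  v30 <- c(cos(pi / 6), sin(pi / 6), 0)
  expect_equal(tend_step(diag(c(1, 0, 0)), v30), c(1, 0, 0))        # rank-1 projection
  v45 <- c(1, 1, 0) / sqrt(2)
  expect_equal(tend_step(diag(c(2, 1, 1)), v45), c(2, 1, 0) / sqrt(5),
               tolerance = 1e-12)
  # sign alignment: output always makes an acute angle with the input
  out <- tend_step(diag(c(2, 1, 1)), -v45)
  expect_gt(sum(out * -v45), 0)
  expect_error(tend_step(matrix(0, 3, 3), c(1, 0, 0)),
               class = "tendtract_degenerate_direction")
})

test_that("consecutive streamline points are exactly one step apart", {
  fx <- straight_fixture()
  fa <- fa_map(fx$phantom$field)
  for (step in c(0.5, 0.8)) {
    sl <- track_from_seed(c(25, 12.5, 8.75), fx$phantom$field, fa,
                          tracking_params(step_mm = step))
    gaps <- sqrt(rowSums(diff(sl$points)^2))
    expect_true(all(abs(gaps - step) < 1e-9))
  }
})

test_that("tracking a straight bundle spans it and terminates on low FA", {
  fx <- straight_fixture()
  fa <- fa_map(fx$phantom$field)
  sl <- track_from_seed(c(25, 12.5, 8.75), fx$phantom$field, fa, tracking_params())
  # spans most of the 30 mm bundle
  expect_gt(diff(range(sl$points[, 1])), 25)
  # stays within one voxel of the centerline
  expect_lt(max(tendtract:::centerline_distance(fx$bundle, sl$points)), 2.5)
  expect_equal(unname(sl$reasons), c("low-FA", "low-FA"))
  expect_lt(sl$end_detail$neg$fa, 0.25)
  expect_lt(sl$end_detail$pos$fa, 0.25)
  expect_true(all(sl$fa >= 0.25))
})

test_that("seeds in isotropic background yield empty streamlines", {
  fx <- straight_fixture()
  fa <- fa_map(fx$phantom$field)
  sl <- track_from_seed(c(5, 2.5, 2.5), fx$phantom$field, fa, tracking_params())
  expect_equal(nrow(sl$points), 0L)
  expect_equal(unname(sl$reasons), c("low-FA", "low-FA"))
})

test_that("on a constant anisotropic field the track converges to the principal axis", {
  D6 <- c(1.7, 0.3, 0.2, 0, 0, 0) * 1e-3
  f <- tensor_field(array(rep(D6, each = 20^3), c(20, 20, 20, 6)), voxel_mm = 1)
  fa <- fa_map(f)
  sl <- track_from_seed(c(9.5, 9.5, 9.5), f, fa, tracking_params(),
                        init_dir = c(1, 0.3, 0.2) / sqrt(sum(c(1, 0.3, 0.2)^2)))
  n <- nrow(sl$points)
  tail_pts <- sl$points[(n - 5):n, ]
  dirs <- diff(tail_pts) / 0.5
  # straight: successive directions collinear with +/- e1 = x
  expect_lt(max(abs(abs(dirs[, 1]) - 1)), 1e-6)
  expect_lt(max(abs(dirs[, 2:3])), 1e-3)
})

test_that("an abrupt 60-degree fiber junction triggers the turning-angle rule", {
  # two half-spaces of strongly prolate tensors meeting at 60 degrees, on a
  # fine grid so the orientation flips within a single 0.5 mm step
  vox <- 0.5
  dm <- c(40L, 40L, 8L)
  mk6 <- function(ax) {
    e2 <- c(-ax[2], ax[1], 0) / sqrt(sum(ax[1:2]^2)); e3 <- c(0, 0, 1)
    tendtract:::mat_to_tensor6(
      1.7e-3 * tcrossprod(ax) + 5e-5 * tcrossprod(e2) + 5e-5 * tcrossprod(e3))
  }
  D6a <- mk6(c(1, 0, 0)); D6b <- mk6(c(cos(pi / 3), sin(pi / 3), 0))
  D <- array(0, c(dm, 6))
  for (i in seq_len(dm[1])) {
    d6 <- if ((i - 1) * vox < 10) D6a else D6b
    for (k in 1:6) D[i, , , k] <- d6[k]
  }
  f <- tensor_field(D, voxel_mm = vox)
  fa <- fa_map(f)
  sl <- track_from_seed(c(5, 10, 2), f, fa, tracking_params(), init_dir = c(1, 0, 0))
  expect_true("sharp-turn" %in% sl$reasons)
  side <- names(which(sl$reasons == "sharp-turn"))[1]
  expect_gt(sl$end_detail[[side]]$angle, 45)
})

test_that("parcel tracking seeds every labeled voxel deterministically", {
  fx <- straight_fixture()
  fa <- fa_map(fx$phantom$field)
  labeled <- which(fx$phantom$labels == 3L)
  b <- track_parcel(fx$phantom$labels, 3L, fx$phantom$field, fa, tracking_params())
  # all labeled voxel centers lie inside the tube, so all seeds take
  expect_length(b$streamlines, length(labeled))
  b2 <- track_parcel(fx$phantom$labels, 3L, fx$phantom$field, fa, tracking_params())
  expect_identical(all_streamline_points(b), all_streamline_points(b2))
  expect_error(track_parcel(fx$phantom$labels, 7L, fx$phantom$field, fa),
               regexp = "available: 3", class = "tendtract_bad_parcel")
})

test_that("a parcel of isotropic voxels yields an empty bundle", {
  fx <- straight_fixture()
  labels <- fx$phantom$labels
  labels[labels == 3L] <- 0L
  labels[1:2, 1, 1] <- 5L     # background corner
  fa <- fa_map(fx$phantom$field)
  b <- track_parcel(labels, 5L, fx$phantom$field, fa, tracking_params())
  expect_length(b$streamlines, 0L)
})

test_that("doubling seed density barely moves the bundle mean FA", {
  # a wide tube seeded over its resolved core (eroded parcel), so extra
  # sub-voxel seeds sample the same FA plateau rather than the
  # partial-volume rim of the label boundary
  wide <- bundle_straight(center = c(25, 20, 17.5), direction = c(1, 0, 0),
                          half_length = 15, radius = 7.5, label = 3L,
                          name = "body_cc_L")
  ph <- make_phantom(phantom_spec(grid = c(20L, 16L, 14L), voxel_mm = 2.5,
                                  bundles = list(wide), sigma = 0))
  fa <- fa_map(ph$field)
  L <- ph$labels
  core <- array(0L, dim(L))
  dm <- dim(L)
  for (i in 2:(dm[1] - 1)) for (j in 2:(dm[2] - 1)) for (k in 2:(dm[3] - 1)) {
    if (all(L[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)] > 0)) {
      core[i, j, k] <- L[i, j, k]
    }
  }
  expect_gt(sum(core > 0), 20L)
  b1 <- track_parcel(core, 3L, ph$field, fa, tracking_params(seeds_per_voxel = 1L))
  b2 <- track_parcel(core, 3L, ph$field, fa, tracking_params(seeds_per_voxel = 2L))
  expect_length(b2$streamlines, 2L * length(b1$streamlines))
  expect_lt(abs(mean_tract_fa(b1) - mean_tract_fa(b2)), 0.005)
})

test_that("tracking parameter bounds are enforced", {
  expect_error(tracking_params(step_mm = 0), class = "tendtract_bad_params")
  expect_error(tracking_params(fa_threshold = 1), class = "tendtract_bad_params")
  expect_error(tracking_params(max_angle_deg = 95), class = "tendtract_bad_params")
  fx <- straight_fixture()
  expect_error(track_from_seed(c(-10, 0, 0), fx$phantom$field, fa_map(fx$phantom$field)),
               class = "tendtract_out_of_bounds")
})
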