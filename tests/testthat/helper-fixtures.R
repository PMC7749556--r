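# Shared fixtures: analytic phantoms and small statistical datasets, all
# built in code so every test is self-contained.

# Straight tube along +x, radius under one voxel so every point of a
# well-tracked streamline stays within a voxel of the centerline.
straight_fixture <- function(sigma = 0) {
  bundle <- bundle_straight(center = c(25, 12.5, 8.75), direction = c(1, 0, 0),
                            half_length = 15, radius = 1.8,
                            label = 3L, name = "body_cc_L")
  spec <- phantom_spec(grid = c(20L, 10L, 8L), voxel_mm = 2.5,
                       bundles = list(bundle), sigma = sigma)
  list(spec = spec, bundle = bundle, phantom = make_phantom(spec))
}

# Quarter-circle arc, curvature radius 25 mm (10 voxels).
arc_fixture <- function() {
  bundle <- bundle_arc(center = c(15, 15, 8.75), circle_radius = 25,
                       theta_range = c(0, pi / 2), u = c(1, 0, 0),
                       v = c(0, 1, 0), radius = 1.8, label = 2L, name = "arc")
  spec <- phantom_spec(grid = c(26L, 26L, 8L), voxel_mm = 2.5,
                       bundles = list(bundle), sigma = 0)
  list(spec = spec, bundle = bundle, phantom = make_phantom(spec))
}

all_streamline_points <- function(bundle) {
  do.call(rbind, lapply(bundle$streamlines, `[[`, "points"))
}

# Hand-built 9-subject dataset (3 per group) exercising the zero-fill
# covariate pattern; values chosen once, arbitrary but fixed.
tiny_cohort <- function() {
  as_cohort_table(data.frame(
    subject_id = sprintf("S%02d", 1:9),
    group = rep(c("HC", "MDD", "BD"), each = 3),
    age = c(41, 55, 63, 38, 52, 60, 45, 49, 58),
    gender = c(0, 1, 0, 1, 1, 0, 0, 1, 1),
    duration = c(0, 0, 0, 4, 11, 7, 9, 21, 15),
    episodes = c(0, 0, 0, 1, 5, 2, 4, 12, 8),
    fa_body_cc_L = c(0.47, 0.45, 0.44, 0.46, 0.43, 0.45, 0.40, 0.38, 0.41),
    stringsAsFactors = FALSE))
}

# Independent least-squares oracle: explicit normal-equation RSS ratio.
rss_of <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

brute_force_ancova_F <- function(tab, outcome,
                                 covariates = c("age", "gender", "duration", "episodes")) {
  g <- factor(tab$group, levels = c("HC", "MDD", "BD"))
  Xc <- cbind(1, as.matrix(tab[, covariates]))
  Xf <- cbind(Xc[, 1], g == "MDD", g == "BD", Xc[, -1])
  y <- tab[[outcome]]
  rss_f <- rss_of(Xf, y)
  rss_r <- rss_of(Xc, y)
  df2 <- nrow(Xf) - ncol(Xf)
  ((rss_r - rss_f) / 2) / (rss_f / df2)
}
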