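test_that("ellipse features match analytic values and quadrature perimeter", {
  circ <- ellipse_features(2, 2, 0)
  expect_equal(circ$area, pi)
  expect_equal(circ$eccentricity, 0)
  expect_equal(circ$aspect_ratio, 1)
  expect_equal(circ$perimeter, 2 * pi, tolerance = 1e-12)
  expect_equal(ellipse_features(4, 2, 10)$eccentricity, sqrt(0.75))
  expect_error(ellipse_features(1, 2, 0), class = "mdp_parameter_error")

  arc_length <- function(a, b) { # full axes
    f <- function(t) sqrt((a / 2)^2 * sin(t)^2 + (b / 2)^2 * cos(t)^2)
    stats::integrate(f, 0, 2 * pi, rel.tol = 1e-12)$value
  }
  set.seed(30)
  for (i in 1:20) {
    minor <- runif(1, 1, 10); major <- minor * runif(1, 1, 4)
    got <- ellipse_features(major, minor, 0)$perimeter
    expect_equal(got, arc_length(major, minor), tolerance = 1e-4)
  }
})

test_that("mask features recover area, perimeter and moment-ellipse shape", {
  sq <- matrix(0, 14, 14); sq[3:12, 3:12] <- 1
  f <- mask_features(sq, 1)
  expect_equal(f$area, 100)
  expect_equal(f$perimeter, 40)
  expect_equal(f$aspect_ratio, 1, tolerance = 1e-9)

  # rasterized axis-aligned ellipse, semi-axes 20 and 10 px, long axis = x
  xx <- outer(rep(1, 61), -30:30); yy <- outer(-30:30, rep(1, 61))
  ell <- (xx / 20)^2 + (yy / 10)^2 <= 1
  fe <- mask_features(ell, 1)
  expect_lt(min(fe$long_axis_deg, 180 - fe$long_axis_deg), 2)
  expect_equal(fe$eccentricity, sqrt(0.75), tolerance = 0.03)
  # rotation by 90 degrees shifts orientation, preserves area
  fr <- mask_features(t(ell), 1)
  expect_equal(fr$area, fe$area)
  expect_equal((fr$long_axis_deg - fe$long_axis_deg) %% 180, 90, tolerance = 2)
  # translation invariance
  shifted <- matrix(0, 70, 70); shifted[5 + seq_len(61), 7 + seq_len(61)] <- ell
  fs <- mask_features(shifted, 1)
  expect_equal(fs$area, fe$area)
  expect_equal(fs$eccentricity, fe$eccentricity, tolerance = 1e-9)

  expect_error(mask_features(matrix(0, 5, 5)), class = "mdp_mask_error")
  two <- matrix(0, 8, 8); two[2, 2] <- 1; two[7, 7] <- 1
  expect_error(mask_features(two), class = "mdp_mask_error")
})

test_that("shape PCA separates size and circularity structure", {
  set.seed(31)
  n <- 400
  size <- rnorm(n)
  feats <- data.frame(area = 3 * size + 10, perimeter = 7 * size + 30,
                      aspect_ratio = rnorm(n) + 2,
                      eccentricity = runif(n, 0.1, 0.9))
  p <- shape_pca(feats)
  expect_equal(abs(p$loadings["area", 1]), abs(p$loadings["perimeter", 1]),
               tolerance = 1e-8)
  expect_gt(abs(p$loadings["area", 1]), 0.5)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_true(max(abs(crossprod(p$loadings) - diag(4))) < 1e-9)
  # per-column affine rescaling changes nothing
  feats2 <- feats; feats2$area <- feats$area * 100 - 5
  p2 <- shape_pca(feats2)
  expect_equal(p2$variance_fraction, p$variance_fraction, tolerance = 1e-9)
  expect_equal(abs(p2$scores[, 1]), abs(p$scores[, 1]), tolerance = 1e-9)

  iso <- data.frame(area = rnorm(10000), perimeter = rnorm(10000),
                    aspect_ratio = rnorm(10000), eccentricity = rnorm(10000))
  expect_true(all(abs(shape_pca(iso)$variance_fraction - 0.25) < 0.02))

  const <- feats; const$eccentricity <- 0.5
  expect_error(shape_pca(const), class = "mdp_degeneracy_error")
  expect_error(shape_pca(const), "eccentricity")

  p6 <- shape_pca(cbind(feats, long_axis_deg = runif(n, 0, 180)),
                  include_orientation = TRUE)
  expect_equal(length(p6$variance_fraction), 6)
  expect_equal(sum(p6$variance_fraction), 1, tolerance = 1e-9)
})

test_that("spindle/long-axis offsets fold to (-90, 90] with axial means", {
  expect_equal(spindle_axis_offset(45, 45)$offset_deg, 0)
  expect_equal(spindle_axis_offset(10, 170)$offset_deg, 20)
  expect_equal(spindle_axis_offset(170, 10)$offset_deg, -20)
  expect_equal(spindle_axis_offset(100, 5)$offset_deg, -85)
  set.seed(32)
  th <- runif(50, 0, 180)
  o <- spindle_axis_offset(th, th)
  expect_true(all(o$offset_deg == 0))
  expect_equal(o$mean_offset_deg, 0)
  # a uniform small shift is recovered as the mean offset
  o2 <- spindle_axis_offset((th + 7) %% 180, th)
  expect_equal(o2$mean_offset_deg, 7, tolerance = 1e-9)
})

test_that("feature-position association is a calibrated rank test", {
  set.seed(33)
  x <- runif(60)
  expect_equal(feature_position_association(x, x, reps = 99)$statistic, 1)
  # invariant to monotone transforms
  y <- rnorm(60)
  r1 <- feature_position_association(y, x, reps = 0, seed = 1)$statistic
  r2 <- feature_position_association(exp(y), x^3, reps = 0, seed = 1)$statistic
  expect_equal(r1, r2)
  expect_error(feature_position_association(rep(1, 20), runif(20)),
               class = "mdp_degeneracy_error")

  rej <- 0L
  for (r in 1:300) {
    p <- feature_position_association(rnorm(200), runif(200),
                                      reps = 99)$p_value
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 300, 0.015)
  expect_lt(rej / 300, 0.1)
})

test_that("segment variance profiles recover a lateral variance gradient", {
  set.seed(34)
  hits <- 0L
  for (r in 1:10) {
    seg <- rep(1:6, each = 60)
    score <- rnorm(360, sd = 1 + (seg - 1) / 5) # sd 1 -> 2 medial to lateral
    v <- segment_variance_profile(score, seg, reps = 199)
    if (v$monotonicity_rho > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9)
  # equal variances: heterogeneity p not systematically extreme
  ps <- replicate(50, segment_variance_profile(rnorm(240), rep(1:6, each = 40),
                                               reps = 99)$p_value)
  expect_gt(mean(ps <= 0.05), -1e-9) # sanity bound
  expect_lt(mean(ps <= 0.05), 0.2)
  expect_error(segment_variance_profile(rnorm(30), rep(1, 30)),
               class = "mdp_sample_size_error")
  expect_warning(segment_variance_profile(rnorm(33), c(rep(1, 15), rep(2, 16),
                                                       rep(3, 2)), reps = 49),
                 class = "mdp_undersized_segment_warning")
})
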