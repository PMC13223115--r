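random_config <- function(n = 7, scale = 50) {
  landmark_config(matrix(rnorm(3 * n) * scale, n, 3))
}

test_that("centroid size is the root summed squared deviation", {
  expect_equal(centroid_size(rbind(c(0, 0, 0), c(2, 0, 0))), sqrt(2))
  set.seed(40)
  cfg <- random_config()
  brute <- sqrt(sum(vapply(1:3, function(k)
    sum((cfg$points[, k] - mean(cfg$points[, k]))^2), numeric(1))))
  expect_equal(centroid_size(cfg), brute, tolerance = 1e-12)
  for (s in c(0.1, 2, 17)) {
    expect_equal(centroid_size(cfg$points * s), s * centroid_size(cfg),
                 tolerance = 1e-9)
  }
  expect_error(centroid_size(matrix(1, 4, 3)),
               class = "mdp_degenerate_size_error")
})

test_that("ordinary Procrustes removes similarity transforms exactly", {
  set.seed(41)
  cfg <- random_config()
  self <- opa_superimpose(cfg, cfg)
  expect_equal(self$procrustes_distance, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  expect_equal(centroid_size(self$aligned), 1, tolerance = 1e-9)
  expect_equal(unname(colMeans(self$aligned$points)), c(0, 0, 0),
               tolerance = 1e-12)

  for (rep in 1:5) {
    M <- similarity_matrix(random_rotation(), runif(1, 0.5, 2), rnorm(3) * 30)
    moved <- landmark_config(apply_transform(cfg$points, M))
    o <- opa_superimpose(moved, cfg)
    expect_lt(o$procrustes_distance, 1e-9)
    # the stored 4x4 transform reproduces the aligned coordinates
    expect_equal(apply_transform(moved$points, o$transform),
                 o$aligned$points, tolerance = 1e-9)
    # symmetry of the distance
    expect_equal(opa_superimpose(cfg, moved)$procrustes_distance,
                 o$procrustes_distance, tolerance = 1e-9)
  }
})

test_that("reflections are rejected by OPA and handled by mirroring", {
  set.seed(42)
  cfg <- random_config()
  mir <- mirror_landmarks(cfg)
  o <- opa_superimpose(mir, cfg)
  expect_gt(o$procrustes_distance, 0.05)
  expect_equal(det(o$rotation), 1, tolerance = 1e-9)
  # explicit mirroring first recovers the fit
  expect_lt(opa_superimpose(mirror_landmarks(mir), cfg)$procrustes_distance,
            1e-12)
  # mirrored mesh keeps outward orientation (positive volume, watertight)
  g <- make_mdp_mesh(c(2, 1, 1), 2)$mesh
  gm <- mirror_landmarks(g)
  expect_true(gm$watertight)
  expect_equal(mesh_volume(gm), mesh_volume(g), tolerance = 1e-9)
})

test_that("our OPA agrees with an independent Procrustes implementation", {
  skip_if_not_installed("vegan")
  set.seed(43)
  cfg <- random_config()
  M <- similarity_matrix(random_rotation(), 1.3, c(5, -2, 8))
  moved <- landmark_config(apply_transform(cfg$points, M) +
                             matrix(rnorm(21, 0, 2), 7, 3))
  ours <- opa_superimpose(moved, cfg)
  ref <- vegan::procrustes(cfg$points, moved$points, symmetric = TRUE,
                           scale = FALSE)
  expect_equal(ours$procrustes_distance, sqrt(ref$ss), tolerance = 1e-6)
  expect_equal(ours$aligned$points, unclass(ref$Yrot), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mean configurations concentrate on the truth", {
  set.seed(44)
  cfg <- random_config()
  expect_equal(mean_configuration(list(cfg, cfg))$points,
               cfg$points / centroid_size(cfg), tolerance = 1e-12)
  k <- 25
  jittered <- lapply(seq_len(k), function(i)
    landmark_config(cfg$points + matrix(rnorm(21, 0, 2), 7, 3)))
  aligned <- lapply(jittered, function(j) opa_superimpose(j, cfg)$aligned)
  m <- mean_configuration(aligned)
  truth_unit <- sweep(cfg$points, 2, colMeans(cfg$points)) / centroid_size(cfg)
  rms_um <- sqrt(mean((m$points - truth_unit)^2)) * centroid_size(cfg)
  expect_lt(rms_um, 2 * 2 / sqrt(k))
  expect_error(mean_configuration(list(cfg, random_config(n = 6))),
               class = "mdp_schema_error")
})

test_that("thin-plate-spline warps interpolate landmarks exactly", {
  set.seed(45)
  g <- make_mdp_mesh(c(100, 150, 80), 2)$mesh
  src <- random_config(7, 80)
  expect_equal(tps_warp(g, src, src)$vertices, g$vertices, tolerance = 1e-6)
  # pure translation moves every vertex by the same offset
  t0 <- c(13, -4, 9)
  shifted <- tps_warp(g, src, landmark_config(sweep(src$points, 2, -t0)))
  expect_equal(shifted$vertices, sweep(g$vertices, 2, -t0), tolerance = 1e-6)
  # affine targets are reproduced affinely (zero bending)
  A <- matrix(c(1.2, 0.1, 0, -0.05, 0.9, 0.2, 0, 0, 1.1), 3, 3)
  tgt <- landmark_config(src$points %*% A)
  warped <- tps_warp(g, src, tgt)
  expect_equal(warped$vertices, g$vertices %*% A, tolerance = 1e-5)
  # random perturbations: exact interpolation at the landmarks
  tgt2 <- landmark_config(src$points + matrix(rnorm(21, 0, 8), 7, 3))
  w <- mdpcarto:::tps_fit(src$points, tgt2$points)
  expect_lt(max(abs(w(src$points) - tgt2$points)), 1e-6)

  flat <- landmark_config(cbind(matrix(rnorm(14), 7, 2), 0))
  expect_error(tps_warp(g, flat, flat), class = "mdp_conditioning_error")
})

test_that("signed closest-point distances match geometry and brute force", {
  sph0 <- make_mdp_mesh(c(1, 1, 1), 3)$mesh
  self <- closest_point_distances(sph0, sph0)
  expect_true(all(abs(self$values) < 1e-9))
  sph1 <- make_mdp_mesh(c(1.1, 1.1, 1.1), 3)$mesh
  d <- closest_point_distances(sph1, sph0)
  expect_true(all(d$values > 0)) # outside: outward displacement
  expect_equal(mean(d$values), 0.1, tolerance = 0.01)
  expect_true(all(abs(d$values - 0.1) < 0.01))
  d_in <- closest_point_distances(sph0, sph1)
  expect_true(all(d_in$values < 0)) # inside: negative

  set.seed(46)
  ma <- bumpy_mesh(1); mb <- bumpy_mesh(2, base = c(1.2, 0.9, 1))
  got <- points_to_mesh_distance(mb, ma$vertices[1:40, ])
  oracle <- vapply(1:40, function(i) oracle_point_mesh(mb, ma$vertices[i, ]),
                   numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-9)

  holed <- triangle_mesh(sph0$vertices, sph0$faces[-1, ])
  expect_warning(closest_point_distances(sph1, holed),
                 class = "mdp_geometry_warning")
})
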