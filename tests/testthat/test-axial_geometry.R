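test_that("pole pairs map to axial angles matching a direct oracle", {
  expect_equal(pole_pair_to_axial_angle(c(0, 0, 0), c(0, 1, 1), "sagittal"), 45)
  expect_equal(pole_pair_to_axial_angle(c(0, 0, 0), c(0, -1, -1), "sagittal"), 45)
  set.seed(1)
  for (i in 1:1000) {
    p1 <- rnorm(3) * 10; p2 <- rnorm(3) * 10
    d <- p2 - p1
    oracle <- (atan2(d[3], d[2]) * 180 / pi) %% 180
    got <- pole_pair_to_axial_angle(p1, p2, "sagittal")
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_equal(pole_pair_to_axial_angle(p2, p1, "sagittal"), got) # swap
    expect_gte(got, 0); expect_lt(got, 180)
  }
  expect_error(pole_pair_to_axial_angle(c(0, 0, 0), c(1e-9, 0, 0), "sagittal"),
               class = "mdp_degeneracy_error")
})

test_that("angle-to-vector embedding round-trips through projection", {
  expect_equal(axial_angle_to_vector3(0, "sagittal"), c(0, 1, 0))
  expect_equal(axial_angle_to_vector3(90, "sagittal"), c(0, 0, 1),
               tolerance = 1e-12)
  set.seed(2)
  for (plane in c("sagittal", "coronal")) {
    a <- runif(500, 0, 180)
    back <- vapply(a, function(th)
      project_to_plane(axial_angle_to_vector3(th, plane), plane), numeric(1))
    expect_lt(max(abs(back - a)), 1e-9)
  }
})

test_that("2D axial means fold correctly and flag degenerate resultants", {
  expect_equal(axial_mean_2d(c(10, 170))$mean_deg, 0, tolerance = 1e-9)
  m <- axial_mean_2d(c(45, 45, 45))
  expect_equal(m$mean_deg, 45)
  expect_equal(m$resultant_length, 1)
  expect_false(axial_mean_2d(c(0, 90))$defined)
  set.seed(3)
  for (th in runif(20, 0, 180)) { # point mass at any angle
    m <- axial_mean_2d(rep(th, 5))
    expect_equal(m$mean_deg, th, tolerance = 1e-9)
    expect_equal(m$resultant_length, 1, tolerance = 1e-12)
  }
  expect_error(axial_mean_2d(numeric(0)), class = "mdp_empty_input_error")
})

test_that("3D axial means match a spherical grid search and ignore signs", {
  m <- axial_mean_3d(rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, 1)))
  expect_equal(abs(m$axis), c(0, 0, 1))
  expect_equal(m$lambda1, 1)
  iso <- axial_mean_3d(diag(3))
  expect_equal(iso$lambda1, 1 / 3, tolerance = 1e-12)
  expect_false(iso$defined)

  set.seed(4)
  for (rep in 1:3) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    U <- sample_axial_vectors_test(200, axis, 8)
    m <- axial_mean_3d(U)
    g <- oracle_axial_mean_grid(U, step_deg = 1)
    expect_lt(axial_difference(m$axis, g$axis), 1)
    expect_gte(m$lambda1 + 1e-9, g$value) # eigen max >= grid max
    # sign flips of a random subset change nothing
    flip <- sample(c(-1, 1), 200, replace = TRUE)
    m2 <- axial_mean_3d(U * flip)
    expect_lt(axial_difference(m$axis, m2$axis), 1e-9)
    expect_equal(m$lambda1, m2$lambda1, tolerance = 1e-12)
  }
})

test_that("axial differences respect wraparound and orthogonality", {
  expect_equal(axial_difference(30, 10), 20)
  expect_equal(axial_difference(170, 10), 20)
  expect_equal(axial_difference(c(1, 0, 0), c(0, 0, 1)), 90)
  expect_equal(axial_difference(10, 170), axial_difference(170, 10))
  expect_error(axial_difference(10, c(1, 0, 0)), class = "mdp_type_error")
})

test_that("similarity transforms preserve pairwise axial structure", {
  cells <- cells_with_angles(c(10, 50, 120, 170),
                             positions = matrix(rnorm(12), 4, 3))
  expect_equal(as.data.frame(apply_similarity_to_cells(cells, diag(4))),
               as.data.frame(cells))

  # 90 degree rotation about x maps the anterior axis to dorsal
  Rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  one <- cells_with_angles(0) # axis (0,1,0)
  rot <- apply_similarity_to_cells(one, similarity_matrix(Rx))
  expect_equal(abs(cell_axes_3d(rot)[1, ]), c(0, 0, 1), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:5) {
    M <- similarity_matrix(random_rotation(), runif(1, 0.5, 2), rnorm(3) * 20)
    before <- cell_axes_3d(cells)
    after <- cell_axes_3d(apply_similarity_to_cells(cells, M))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(axial_difference(before[i, ], before[j, ]),
                   axial_difference(after[i, ], after[j, ]),
                   tolerance = 1e-6)
    }
  }
  expect_error(apply_similarity_to_cells(cells, matrix(0, 4, 4)),
               class = "mdp_transform_error")
})

test_that("a global rotation rotates the 3D axial mean with it", {
  set.seed(6)
  U <- sample_axial_vectors_test(100, c(0, 1, 0), 5)
  m0 <- axial_mean_3d(U)
  for (rep in 1:5) {
    R <- random_rotation()
    m1 <- axial_mean_3d(t(R %*% t(U)))
    expect_lt(axial_difference(as.numeric(R %*% m0$axis), m1$axis), 1e-6)
    expect_equal(m0$lambda1, m1$lambda1, tolerance = 1e-9)
  }
})
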