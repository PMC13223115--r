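test_that("ellipsoid meshes match analytic area, volume and landmarks", {
  g <- make_mdp_mesh(c(100, 150, 80), 3)
  expect_true(g$mesh$watertight)
  expect_equal(unname(g$landmarks$points[1, ]), c(100, 0, 0))
  expect_equal(g$landmarks$names[1], "lateral")
  expect_equal(nrow(g$landmarks$points), 7)
  # anteromedial landmark lies on the ellipsoid surface
  am <- g$landmarks$points[7, ]
  expect_equal(sum(am^2 / c(100, 150, 80)^2), 1, tolerance = 1e-9)

  unit <- make_mdp_mesh(c(1, 1, 1), 3)$mesh
  expect_equal(mesh_area(unit), 4 * pi, tolerance = 0.02)
  vol_true <- 4 * pi * 100 * 150 * 80 / 3
  expect_equal(mesh_volume(g$mesh), vol_true, tolerance = 0.02)
  expect_error(make_mdp_mesh(c(1, 1, 1), 0), class = "mdp_parameter_error")
})

test_that("interior sampling is uniform, contained and seed-deterministic", {
  s <- make_mdp_mesh(c(1, 1, 1), 3)$mesh
  p <- sample_cells(s, 500, seed = 42)
  expect_true(all(sqrt(rowSums(p^2)) < 1))
  expect_identical(sample_cells(s, 500, seed = 42), p)
  expect_false(identical(sample_cells(s, 500, seed = 43), p))

  big <- sample_cells(s, 20000, seed = 7)
  frac <- mean(sqrt(rowSums(big^2)) < 0.5)
  se <- sqrt(0.125 * 0.875 / 20000)
  expect_lt(abs(frac - 0.125), 3 * se + 0.01) # 1% slack for mesh faceting

  holed <- triangle_mesh(s$vertices, s$faces[-1, ])
  expect_error(sample_cells(holed, 10, 1), class = "mdp_geometry_error")
})

test_that("division axes concentrate on the preferred axis as kappa grows", {
  s <- make_mdp_mesh(c(300, 150, 100), 2)$mesh
  pos <- sample_cells(s, 400, seed = 2)
  tight <- gradient_spec(kappa_medial = 1e6, kappa_lateral = 1e6,
                         rate_medial = 1, rate_lateral = 1)
  cells <- assign_behaviours(pos, tight, seed = 3)
  dev <- apply(cell_axes_3d(cells), 1,
               function(u) axial_difference(u, c(0, 1, 0)))
  expect_lt(max(dev), 1)
  expect_error(gradient_spec(kappa_medial = -1), class = "mdp_parameter_error")
})

test_that("kappa zero gives axially uniform in-plane angles", {
  s <- make_mdp_mesh(c(300, 150, 100), 2)$mesh
  pos <- sample_cells(s, 300, seed = 4)
  iso <- gradient_spec(kappa_medial = 0, kappa_lateral = 0,
                       rate_medial = 1, rate_lateral = 1)
  rejections <- 0L
  for (r in 1:100) {
    cells <- assign_behaviours(pos, iso, seed = 1000 + r)
    th <- apply(cell_axes_3d(cells), 1, project_to_plane, plane = "sagittal")
    k <- kuiper_uniformity(th, method = "asymptotic")
    if (k$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 10) # non-rejection in >= 90% of replicates
})

test_that("the mitotic-rate gradient is recovered laterally", {
  s <- make_mdp_mesh(c(300, 150, 100), 2)$mesh
  pos <- sample_cells(s, 2000, seed = 5)
  gs <- gradient_spec(rate_medial = 0.05, rate_lateral = 0.25)
  part <- segment_partition(data.frame(nucleus_x = pos[, 1]), 6)
  wins <- 0L
  for (r in 1:100) {
    cells <- assign_behaviours(pos, gs, seed = 2000 + r,
                               extent_x = range(s$vertices[, 1]))
    f <- tapply(cells$is_mitotic, part$segment_index, mean)
    if (f[["6"]] > f[["1"]]) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("replicates are similarity copies with recoverable transforms", {
  base <- make_specimen(n_cells = 60, n_subdiv = 2, seed = 9)
  idrep <- make_replicates(base, 1, seed = 1, jitter_sd = 0,
                           transforms = list(diag(4)))[[1]]
  expect_equal(idrep$mesh$vertices, base$mesh$vertices)
  expect_equal(idrep$landmarks$points, base$landmarks$points)
  expect_equal(idrep$cells$nucleus_x, base$cells$nucleus_x)

  reps <- make_replicates(base, 3, seed = 11, jitter_sd = 0)
  for (r in reps) {
    M <- r$transform_truth
    s_drawn <- det(M[1:3, 1:3])^(1 / 3)
    d0 <- as.matrix(dist(base$landmarks$points))
    d1 <- as.matrix(dist(r$landmarks$points))
    expect_equal(d1, d0 * s_drawn, tolerance = 1e-9)
    expect_true(s_drawn >= 0.9 && s_drawn <= 1.1)
    # OPA recovers the drawn rotation within 1 degree
    o <- opa_superimpose(r$landmarks, base$landmarks)
    R_est <- t(o$rotation)            # aligned-row convention back to row form
    R_true <- M[1:3, 1:3] / s_drawn
    ang <- acos(min(1, (sum(diag(R_est %*% t(R_true))) - 1) / 2)) * 180 / pi
    expect_lt(ang, 1)
  }
})

test_that("identical seeds give bit-identical specimens", {
  a <- make_specimen(n_cells = 120, n_subdiv = 2, seed = 77)
  b <- make_specimen(n_cells = 120, n_subdiv = 2, seed = 77)
  expect_identical(a$cells, b$cells)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
})
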