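test_that("ball queries are exact at the boundary and match brute force", {
  two <- rbind(c(0, 0, 0), c(199, 0, 0))
  expect_equal(find_neighbours(two, 200), list(2L, 1L))
  two[2, 1] <- 201
  expect_equal(find_neighbours(two, 200), list(integer(0), integer(0)))

  set.seed(10)
  for (rep in 1:3) {
    pos <- matrix(runif(3000, 0, 500), ncol = 3)
    expect_identical(find_neighbours(pos, 120), brute_ball_query(pos, 120))
  }
  expect_error(find_neighbours(two, 0), class = "mdp_parameter_error")
})

test_that("alignment scores contrast a cell with its neighbourhood mean", {
  pos <- rbind(matrix(0.1 * seq_len(30), 10, 3), c(0, 0, 0))
  for (focal in c(30, 90)) {
    cells <- cells_with_angles(c(rep(0, 10), focal), positions = pos)
    sc <- alignment_scores(cells, radius_um = 200, mode = "2d")
    expect_equal(sc$score_deg[11], focal, tolerance = 1e-9)
  }
  # with all cells on one axis every defined score is exactly 0
  cells <- cells_with_angles(rep(37, 12),
                             positions = matrix(runif(36, 0, 50), 12, 3))
  sc3 <- alignment_scores(cells, radius_um = 200, mode = "3d")
  expect_true(all(sc3$defined))
  expect_true(all(sc3$score_deg == 0))
})

test_that("scores are invariant to global rotation and axis sign flips", {
  set.seed(11)
  spec <- make_specimen(n_cells = 300, n_subdiv = 2, seed = 12)
  sc0 <- alignment_scores(spec$cells, 200, "3d")
  M <- similarity_matrix(random_rotation(), 1, c(5, 5, 5))
  sc1 <- alignment_scores(apply_similarity_to_cells(spec$cells, M), 200, "3d")
  expect_equal(sc1$score_deg, sc0$score_deg, tolerance = 1e-6)
  # flip a random subset of pole pairs
  cells <- as.data.frame(spec$cells)
  flip <- which(cells$is_mitotic)[c(TRUE, FALSE)]
  tmp <- cells[flip, c("pole1_x", "pole1_y", "pole1_z")]
  cells[flip, c("pole1_x", "pole1_y", "pole1_z")] <-
    cells[flip, c("pole2_x", "pole2_y", "pole2_z")]
  cells[flip, c("pole2_x", "pole2_y", "pole2_z")] <- tmp
  sc2 <- alignment_scores(validate_cell_table(cells), 200, "3d")
  expect_equal(sc2$score_deg, sc0$score_deg, tolerance = 1e-9)
})

test_that("undefined neighbourhood means are flagged, never dropped", {
  # an isolated cell and a cell whose neighbours cancel after doubling
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5000, 0, 0))
  cells <- cells_with_angles(c(45, 0, 90, 10), positions = pos)
  sc <- alignment_scores(cells, radius_um = 200, mode = "2d")
  expect_equal(nrow(sc), 4)              # nothing dropped
  expect_false(sc$defined[1])            # neighbours 0 and 90 cancel
  expect_false(sc$defined[4])            # no neighbours
  expect_equal(sc$n_neighbours[4], 0)
  cells$plane[2] <- "coronal"
  expect_error(alignment_scores(validate_cell_table(cells), 200, "2d"),
               class = "mdp_plane_mixing_error")
})

test_that("segment partition uses equal-width bins with a closed last edge", {
  cells <- data.frame(nucleus_x = c(5, 15, 25, 35, 45, 55))
  p <- segment_partition(cells, 6)
  expect_equal(p$segment_index, 1:6)
  expect_equal(length(p$bin_edges), 7)
  # a cell exactly on the maximal edge falls in segment k
  expect_equal(segment_partition(data.frame(nucleus_x = c(0, 30, 60)),
                                 6)$segment_index[3], 6L)
  expect_error(segment_partition(data.frame(nucleus_x = rep(1, 5)), 6),
               class = "mdp_degenerate_extent_error")

  set.seed(12)
  u <- data.frame(nucleus_x = runif(6000))
  counts <- tabulate(segment_partition(u, 6)$segment_index, 6)
  sdv <- sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 1000) < 4 * sdv))
})

test_that("local mitotic index reports fractions and flags empty balls", {
  pos <- matrix(runif(30, 0, 10), 10, 3)
  cells <- data.frame(nucleus_x = pos[, 1], nucleus_y = pos[, 2],
                      nucleus_z = pos[, 3],
                      is_mitotic = c(TRUE, TRUE, rep(FALSE, 8)))
  res <- local_mitotic_index(cells, rbind(c(5, 5, 5), c(1e6, 0, 0)), 1e4)
  expect_equal(res$index[1], 0.2)
  expect_true(is.na(res$index[2]))
  expect_equal(res$n_in_ball[2], 0)

  # homogeneous rate: mean relative index near 1
  set.seed(13)
  pos <- matrix(runif(15000, 0, 300), 5000, 3)
  cells <- data.frame(nucleus_x = pos[, 1], nucleus_y = pos[, 2],
                      nucleus_z = pos[, 3],
                      is_mitotic = runif(5000) < 0.1)
  q <- matrix(runif(150, 50, 250), 50, 3)
  rel <- local_mitotic_index(cells, q, 100)$relative_index
  expect_gt(mean(rel), 0.9)
  expect_lt(mean(rel), 1.1)
})

test_that("distant cells affect only their own records", {
  pos <- rbind(matrix(runif(30, 0, 50), 10, 3), c(1e5, 1e5, 1e5))
  th <- c(runif(10, 0, 180), 90)
  sc_with <- alignment_scores(cells_with_angles(th, pos), 200, "2d")
  sc_without <- alignment_scores(cells_with_angles(th[1:10],
                                                   pos[1:10, , drop = FALSE]),
                                 200, "2d")
  expect_equal(sc_with$score_deg[1:10], sc_without$score_deg)
})
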