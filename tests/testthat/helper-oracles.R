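# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's optimized code paths.

# O(n^2) closed-ball neighbour query via the full distance matrix.
brute_ball_query <- function(positions, radius) {
  d <- as.matrix(stats::dist(positions))
  lapply(seq_len(nrow(positions)), function(i) {
    j <- unname(which(d[i, ] <= radius))
    sort(j[j != i])
  })
}

# Scalar point-to-triangle distance by an independent construction:
# distance to the supporting plane if the foot lies inside (barycentric via
# cross-product areas), else the minimum over the three edge segments.
oracle_point_triangle <- function(p, a, b, c) {
  seg <- function(p, s0, s1) {
    d <- s1 - s0
    t <- sum((p - s0) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (s0 + t * d))^2))
  }
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sum(n * n)
  if (nn < 1e-300) return(min(seg(p, a, b), seg(p, b, c), seg(p, c, a)))
  tpl <- sum((p - a) * n) / nn
  foot <- p - tpl * n
  area2 <- function(x, y, z) {
    cr <- c((y - x)[2] * (z - x)[3] - (y - x)[3] * (z - x)[2],
            (y - x)[3] * (z - x)[1] - (y - x)[1] * (z - x)[3],
            (y - x)[1] * (z - x)[2] - (y - x)[2] * (z - x)[1])
    sum(cr * n) / nn
  }
  w1 <- area2(foot, b, c); w2 <- area2(foot, c, a); w3 <- area2(foot, a, b)
  if (w1 >= 0 && w2 >= 0 && w3 >= 0) return(abs(tpl) * sqrt(nn))
  min(seg(p, a, b), seg(p, b, c), seg(p, c, a))
}

oracle_point_mesh <- function(mesh, p) {
  f <- mesh$faces; v <- mesh$vertices
  min(vapply(seq_len(nrow(f)), function(k)
    oracle_point_triangle(p, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ]),
    numeric(1)))
}

# Grid-search axial mean: argmax over a ~1 degree spherical grid of the mean
# squared projection sum((u . a)^2).
oracle_axial_mean_grid <- function(U, step_deg = 1) {
  th <- seq(0, 90, by = step_deg) * pi / 180          # polar from +z
  ph <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  grid <- cbind(sin(rep(th, each = length(ph))) * cos(ph),
                sin(rep(th, each = length(ph))) * sin(ph),
                cos(rep(th, each = length(ph))))
  proj <- (grid %*% t(U))^2
  s <- rowMeans(proj)
  list(axis = grid[which.max(s), ], value = max(s))
}

# Greedy matching oracle: repeatedly take the globally closest unused
# (pole, nucleus) pair within the cap.
oracle_greedy_match <- function(P, N, cap) {
  d <- outer(seq_len(nrow(P)), seq_len(nrow(N)), Vectorize(function(i, j)
    sqrt(sum((P[i, ] - N[j, ])^2))))
  pairs <- list()
  repeat {
    if (all(!is.finite(d)) || min(d, na.rm = TRUE) > cap) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1]] <- c(ij, d[ij[1], ij[2]])
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  do.call(rbind, pairs)
}

# Crude concentrated axis sampler for oracle tests (independent of the
# package's generative scheme): Gaussian perturbation of the axis, normalized.
sample_axial_vectors_test <- function(n, axis, concentration) {
  g <- matrix(rnorm(3 * n, sd = 1 / sqrt(concentration)), n, 3)
  u <- sweep(g, 2, axis, `+`)
  u / sqrt(rowSums(u^2))
}

# A small non-symmetric watertight test mesh: jittered subdivided icosphere.
bumpy_mesh <- function(seed = 1, n_subdiv = 2, base = c(1, 1, 1), bump = 0.1) {
  g <- make_mdp_mesh(base, n_subdiv)$mesh
  set.seed(seed)
  r <- 1 + runif(nrow(g$vertices), -bump, bump)
  triangle_mesh(g$vertices * r, g$faces)
}

# Cell table with prescribed sagittal axial angles (used all over the 2d tests).
cells_with_angles <- function(theta_deg, positions = NULL, plane = "sagittal") {
  n <- length(theta_deg)
  if (is.null(positions)) positions <- matrix(0, n, 3)
  u <- t(vapply(theta_deg, axial_angle_to_vector3, numeric(3), plane = plane))
  validate_cell_table(data.frame(
    cell_id = sprintf("c%03d", seq_len(n)), specimen_id = "t", plane = plane,
    pole1_x = positions[, 1] - 3 * u[, 1], pole1_y = positions[, 2] - 3 * u[, 2],
    pole1_z = positions[, 3] - 3 * u[, 3],
    pole2_x = positions[, 1] + 3 * u[, 1], pole2_y = positions[, 2] + 3 * u[, 2],
    pole2_z = positions[, 3] + 3 * u[, 3],
    nucleus_x = positions[, 1], nucleus_y = positions[, 2],
    nucleus_z = positions[, 3],
    is_mitotic = TRUE, stringsAsFactors = FALSE))
}
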