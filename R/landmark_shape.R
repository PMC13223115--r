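# Landmark-based shape analysis: ordinary Procrustes superimposition onto an
# atlas, mean configurations, thin-plate-spline atlas morphing, and signed
# closest-point distances between surface meshes.

#' Centroid size of a landmark configuration
#'
#' `sqrt(sum_i ||p_i - centroid||^2)`, the standard Procrustes size measure.
#'
#' @param config a `landmark_config` or an `n x 3` matrix.
#' @return centroid size (micrometres).
#' @export
centroid_size <- function(config) {
  p <- if (inherits(config, "landmark_config")) config$points else rbind(config)
  cs <- sqrt(sum(sweep(p, 2, colMeans(p))^2))
  if (cs <= 1e-12)
    stop_mdp("mdp_degenerate_size_error", "coincident landmarks (size 0)")
  cs
}

#' Ordinary Procrustes superimposition onto a reference
#'
#' Translates both configurations to a common centroid, scales both to unit
#' centroid size, and rotates the configuration onto the reference by the SVD
#' solution with determinant correction (reflections disallowed). Mirrored
#' specimens must be reflected explicitly first (see [mirror_landmarks()]).
#'
#' @param config a `landmark_config` (or matrix) to superimpose.
#' @param reference the target `landmark_config` (or matrix), same landmark
#'   count and order.
#' @return list with `aligned` (`landmark_config`, centroid at origin, unit
#'   centroid size), `transform` (4x4 matrix mapping original coordinates to
#'   aligned space), `rotation` (3x3), `procrustes_distance` (root sum of
#'   squared residuals to the scaled reference).
#' @export
opa_superimpose <- function(config, reference) {
  X <- if (inherits(config, "landmark_config")) config$points else rbind(config)
  Y <- if (inherits(reference, "landmark_config")) reference$points else rbind(reference)
  if (nrow(X) != nrow(Y))
    stop_mdp("mdp_schema_error", "landmark counts differ (%d vs %d)",
             nrow(X), nrow(Y))
  cX <- colMeans(X); cY <- colMeans(Y)
  sX <- centroid_size(X); sY <- centroid_size(Y)
  Xs <- sweep(X, 2, cX) / sX
  Ys <- sweep(Y, 2, cY) / sY
  if (qr(Xs)$rank < 3 || qr(Ys)$rank < 3)
    warn_mdp("mdp_conditioning_warning", "rank-deficient (collinear/coplanar) configuration")
  sv <- svd(crossprod(Xs, Ys))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)  # row convention: aligned = Xs %*% R
  aligned <- Xs %*% R
  nms <- if (inherits(config, "landmark_config")) config$names else NULL
  # column-vector 4x4: p' = t(R) ((p - cX) / sX)
  M <- diag(4)
  M[1:3, 1:3] <- t(R) / sX
  M[1:3, 4] <- -as.numeric(t(R) %*% cX) / sX
  list(aligned = landmark_config(aligned, nms),
       transform = M,
       rotation = t(R),
       procrustes_distance = sqrt(sum((aligned - Ys)^2)))
}

#' Mirror a configuration or mesh across the mediolateral axis
#'
#' Flips the x (mediolateral) coordinate, turning a right prominence into a
#' left-compatible configuration before superimposition (ordinary Procrustes
#' here never reflects).
#'
#' @param obj a `landmark_config`, [triangle_mesh()], or `n x 3` matrix.
#' @return the mirrored object (mesh face winding is reversed to keep
#'   outward orientation).
#' @export
mirror_landmarks <- function(obj) {
  if (inherits(obj, "landmark_config")) {
    p <- obj$points; p[, 1] <- -p[, 1]
    landmark_config(p, obj$names)
  } else if (inherits(obj, "triangle_mesh")) {
    v <- obj$vertices; v[, 1] <- -v[, 1]
    triangle_mesh(v, obj$faces[, c(1, 3, 2)])
  } else {
    p <- rbind(obj); p[, 1] <- -p[, 1]; p
  }
}

#' Mean of superimposed landmark configurations
#'
#' Coordinate-wise arithmetic mean of configurations already aligned to a
#' common reference, re-scaled to unit centroid size.
#'
#' @param configs list of `landmark_config`s (or matrices), all superimposed
#'   on the same reference.
#' @return a `landmark_config` of unit centroid size.
#' @export
mean_configuration <- function(configs) {
  mats <- lapply(configs, function(cfg)
    if (inherits(cfg, "landmark_config")) cfg$points else rbind(cfg))
  if (length(unique(vapply(mats, nrow, integer(1)))) != 1)
    stop_mdp("mdp_schema_error", "mixed landmark counts")
  if (length(mats) < 2)
    stop_mdp("mdp_sample_size_error", "need >= 2 configurations")
  m <- Reduce(`+`, mats) / length(mats)
  m <- m / centroid_size(m)
  nms <- if (inherits(configs[[1]], "landmark_config")) configs[[1]]$names else NULL
  landmark_config(m, nms)
}

# Fit 3D thin-plate-spline coefficients (kernel U(r) = r) mapping source
# landmarks exactly onto targets. Returns a function warping an n x 3 matrix.
tps_fit <- function(source, target, lambda = 0) {
  S <- rbind(source); Tg <- rbind(target)
  k <- nrow(S)
  if (k < 4) stop_mdp("mdp_parameter_error", "TPS needs >= 4 landmarks")
  if (qr(sweep(S, 2, colMeans(S)))$rank < 3)
    stop_mdp("mdp_conditioning_error", "coplanar landmarks: TPS system singular")
  K <- as.matrix(stats::dist(S))  # U(r) = r
  P <- cbind(1, S)
  L <- rbind(cbind(K + lambda * diag(k), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Tg, matrix(0, 4, 3))
  coefs <- solve(L, rhs)
  W <- coefs[1:k, , drop = FALSE]
  A <- coefs[(k + 1):(k + 4), , drop = FALSE]
  function(pts) {
    pts <- rbind(pts)
    D2 <- outer(rowSums(pts^2), rep(1, k)) +
          outer(rep(1, nrow(pts)), rowSums(S^2)) -
          2 * pts %*% t(S)
    D <- sqrt(pmax(D2, 0)) # clamp tiny negatives at coincident points
    cbind(1, pts) %*% A + D %*% W
  }
}

#' Thin-plate-spline warp of a mesh between landmark configurations
#'
#' 3D TPS with kernel `U(r) = r` and an affine part; interpolation is exact
#' at the landmarks (residual below 1e-6 um) and the mesh topology is
#' unchanged. Used to morph an atlas mesh to a mean landmark configuration.
#'
#' @param mesh the [triangle_mesh()] to warp.
#' @param source_landmarks landmarks in mesh space (`landmark_config` or
#'   matrix, >= 4 non-coplanar points).
#' @param target_landmarks corresponding target landmarks.
#' @return the warped [triangle_mesh()].
#' @export
tps_warp <- function(mesh, source_landmarks, target_landmarks) {
  S <- if (inherits(source_landmarks, "landmark_config"))
    source_landmarks$points else rbind(source_landmarks)
  Tg <- if (inherits(target_landmarks, "landmark_config"))
    target_landmarks$points else rbind(target_landmarks)
  if (nrow(S) != nrow(Tg))
    stop_mdp("mdp_schema_error", "landmark counts differ")
  warp <- tps_fit(S, Tg)
  triangle_mesh(warp(mesh$vertices), mesh$faces)
}

#' Signed closest-point distances between two meshes
#'
#' For every vertex of `mesh_a`, the exact minimum distance to any triangle
#' of `mesh_b`, signed by watertight containment: positive outside `mesh_b`
#' (outward displacement), negative inside. If `mesh_b` is not watertight the
#' unsigned field is returned with a warning. Direction matters: this is the
#' A-to-B map.
#'
#' @param mesh_a query mesh (field lives on its vertices).
#' @param mesh_b target mesh.
#' @return a `surface_field` of per-vertex signed distances on `mesh_a`.
#' @export
closest_point_distances <- function(mesh_a, mesh_b) {
  d <- points_to_mesh_distance(mesh_b, mesh_a$vertices)
  if (mesh_b$watertight) {
    inside <- points_in_mesh(mesh_b, mesh_a$vertices)
    d <- ifelse(inside, -d, d)
  } else {
    warn_mdp("mdp_geometry_warning",
             "mesh_b not watertight: returning unsigned distances")
  }
  surface_field(d, coverage = rep(1L, length(d)), element_kind = "vertex")
}
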