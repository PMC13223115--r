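# Surface cartography: scalar fields on meshes, per-vertex neighbourhood
# averages of cell behaviours, nested isomorphic depth shells, and ray-cast
# positional mitotic orientation.

#' Scalar surface field
#'
#' One value per mesh vertex (or face) plus a coverage count (how many cells
#' contributed). A value is undefined (`NA`) exactly when coverage is zero.
#'
#' @param values numeric values (`NA` = undefined).
#' @param coverage integer contribution counts, same length.
#' @param element_kind `"vertex"` or `"face"`.
#' @return a `surface_field` object.
#' @export
surface_field <- function(values, coverage = NULL,
                          element_kind = c("vertex", "face")) {
  element_kind <- match.arg(element_kind)
  if (is.null(coverage)) coverage <- as.integer(!is.na(values))
  if (length(values) != length(coverage))
    stop_mdp("mdp_dimension_error", "values/coverage length mismatch")
  structure(list(values = as.numeric(values), coverage = as.integer(coverage),
                 element_kind = element_kind),
            class = "surface_field")
}

#' @export
print.surface_field <- function(x, ...) {
  cat(sprintf("surface_field (%s): %d elements, %d defined\n",
              x$element_kind, length(x$values), sum(!is.na(x$values))))
  invisible(x)
}

#' Neighbourhood average of cell values at each mesh vertex
#'
#' At every vertex, the unweighted mean of the defined `values` of all cells
#' within the closed Euclidean ball of `radius_um`; vertices with no covered
#' cells are undefined. The vector variant (`values` an `n x 3` axis matrix)
#' returns the per-vertex axial mean axis and its concentration `lambda1`.
#'
#' @param mesh a [triangle_mesh()].
#' @param positions `n x 3` cell positions (micrometres).
#' @param values numeric vector (scalar field) or `n x 3` matrix (axial
#'   vector field).
#' @param radius_um ball radius.
#' @return a `surface_field` on vertices; for the vector variant, a list
#'   with `axes` (`n_vertex x 3`, `NA` rows undefined), `lambda1` field and
#'   `coverage`.
#' @export
vertex_field_average <- function(mesh, positions, values, radius_um = 200) {
  if (radius_um <= 0) stop_mdp("mdp_parameter_error", "radius must be > 0")
  positions <- rbind(positions)
  V <- mesh$vertices
  r2 <- radius_um^2
  vector_mode <- is.matrix(values) && ncol(values) == 3
  nvert <- nrow(V)
  if (vector_mode) {
    axes <- matrix(NA_real_, nvert, 3)
    lam <- rep(NA_real_, nvert)
    cov <- integer(nvert)
    for (i in seq_len(nvert)) {
      d2 <- (positions[, 1] - V[i, 1])^2 + (positions[, 2] - V[i, 2])^2 +
            (positions[, 3] - V[i, 3])^2
      idx <- which(d2 <= r2)
      cov[i] <- length(idx)
      if (!length(idx)) next
      m <- axial_mean_3d(values[idx, , drop = FALSE])
      lam[i] <- m$lambda1
      if (m$defined) axes[i, ] <- m$axis
    }
    list(axes = axes, lambda1 = surface_field(lam, cov, "vertex"),
         coverage = cov)
  } else {
    out <- rep(NA_real_, nvert)
    cov <- integer(nvert)
    for (i in seq_len(nvert)) {
      d2 <- (positions[, 1] - V[i, 1])^2 + (positions[, 2] - V[i, 2])^2 +
            (positions[, 3] - V[i, 3])^2
      idx <- which(d2 <= r2 & !is.na(values))
      cov[i] <- length(idx)
      if (length(idx)) out[i] <- mean(values[idx])
    }
    surface_field(out, cov, "vertex")
  }
}

#' Nested isomorphic depth shells
#'
#' Copies of the mesh scaled about its volume centroid by each factor in
#' `scales`; all shells share the source topology (same vertex and face
#' counts and connectivity), emulating successive tissue depths.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param scales strictly decreasing factors in `(0, 1]`, starting at 1.
#' @return a `shell_set`: list with `shells` (list of meshes, outermost
#'   first) and `scales`.
#' @export
nested_shells <- function(mesh, scales = c(1.0, 0.8, 0.6, 0.4)) {
  if (!mesh$watertight)
    stop_mdp("mdp_geometry_error", "shells require a watertight mesh")
  if (any(scales <= 0) || any(scales > 1) || any(diff(scales) >= 0) ||
      scales[1] != 1)
    stop_mdp("mdp_parameter_error",
             "scales must start at 1 and be strictly decreasing in (0, 1]")
  ctr <- mesh_centroid(mesh)
  shells <- lapply(scales, function(s) {
    triangle_mesh(sweep(mesh$vertices, 2, ctr) * s +
                    matrix(ctr, nrow(mesh$vertices), 3, byrow = TRUE),
                  mesh$faces)
  })
  structure(list(shells = shells, scales = scales), class = "shell_set")
}

#' Assign cells to depth bands between nested shells
#'
#' Zero-based bands: band `i` lies between shell `i` and shell `i + 1`
#' (outermost shell = 0); the innermost band (`length(scales) - 1`) is the
#' interior of the last shell. Cells outside the outermost shell are assigned
#' band 0 and counted in a warning.
#'
#' @param positions `n x 3` cell positions.
#' @param shell_set output of [nested_shells()].
#' @return integer band index per cell (0-based).
#' @export
assign_depth <- function(positions, shell_set) {
  positions <- rbind(positions)
  n <- nrow(positions)
  band <- integer(n)
  outside <- !points_in_mesh(shell_set$shells[[1]], positions)
  if (any(outside))
    warn_mdp("mdp_geometry_warning",
             "%d cell(s) outside the outermost shell assigned band 0",
             sum(outside))
  for (k in seq_along(shell_set$shells)[-1]) {
    inside_k <- points_in_mesh(shell_set$shells[[k]], positions)
    band[inside_k & !outside] <- k - 1L
  }
  band
}

#' Ray-cast positional mitotic orientation
#'
#' For each mitotic cell, rays are cast from its position along both
#' directions of its division axis (divisions are bidirectional) and the
#' first surface intersection in each direction increments the hit count of
#' the struck face, so total hits equal twice the number of cells cast. The
#' frequency field normalizes counts by face area and total hits. Cells on or
#' outside the surface are skipped and counted.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param positions `n x 3` mitotic cell positions strictly inside the mesh.
#' @param axes `n x 3` division axis per cell (sign-arbitrary).
#' @return a `hit_field`: list with `counts` (per face), `total_hits`,
#'   `frequency` (per face, counts / (area * total)), `n_cast`, `n_skipped`.
#' @export
raycast_positional_orientation <- function(mesh, positions, axes) {
  if (!mesh$watertight)
    stop_mdp("mdp_geometry_error", "ray casting requires a watertight mesh")
  positions <- rbind(positions); axes <- rbind(axes)
  inside <- points_in_mesh(mesh, positions)
  n_skip <- sum(!inside)
  if (n_skip) mdp_log("raycast", "skipped %d cell(s) on/outside the surface",
                      n_skip)
  counts <- integer(nrow(mesh$faces))
  n_cast <- 0L
  for (i in which(inside)) {
    u <- axes[i, ] / sqrt(sum(axes[i, ]^2))
    ok <- TRUE
    hit_faces <- integer(2)
    for (s in 1:2) {
      hits <- ray_mesh_hits(mesh, positions[i, ], if (s == 1) u else -u)
      if (nrow(hits) == 0) { ok <- FALSE; break }
      hit_faces[s] <- hits$face[1]
    }
    if (!ok) { n_skip <- n_skip + 1L; next }
    counts[hit_faces[1]] <- counts[hit_faces[1]] + 1L
    counts[hit_faces[2]] <- counts[hit_faces[2]] + 1L
    n_cast <- n_cast + 1L
  }
  if (n_cast == 0L)
    stop_mdp("mdp_empty_field_error", "no successful ray casts")
  total <- 2L * n_cast
  structure(list(counts = counts, total_hits = total,
                 frequency = counts / (face_areas(mesh) * total),
                 n_cast = n_cast, n_skipped = n_skip),
            class = "hit_field")
}
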