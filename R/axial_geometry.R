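# Axial (orientation-without-direction) angle and vector mathematics.
#
# Division axes have no head or tail: theta and theta + 180 are the same
# angle, u and -u the same axis. In-plane angles live in [0, 180) degrees.
#
# Coordinate and angle conventions (right-handed, micrometres):
#   +x lateral, +y anterior (rostral), +z dorsal.
#   sagittal plane = (y, z), normal x: 0 deg = anterior (+y), increasing
#     toward dorsal (+z).
#   coronal plane = (x, z), normal y: 0 deg = dorsal (+z), increasing toward
#     lateral (+x). (Anterior is out of plane for coronal sections, so the
#     dorsal direction serves as the in-plane reference.)

fold180 <- function(deg) deg %% 180

plane_axes <- function(plane) {
  switch(plane,
    sagittal = list(ref = c(0, 1, 0), orth = c(0, 0, 1), inplane = c(2L, 3L)),
    coronal  = list(ref = c(0, 0, 1), orth = c(1, 0, 0), inplane = c(1L, 3L)),
    stop_mdp("mdp_parameter_error", "unknown plane '%s'", plane))
}

#' Axial angle of a spindle pole pair in an imaging plane
#'
#' The division axis is the line through the two spindle poles; its in-plane
#' angle is measured from the plane's reference direction (anterior for
#' sagittal, dorsal for coronal) and folded to `[0, 180)` degrees, so swapping
#' or negating the poles leaves the result unchanged.
#'
#' @param pole1,pole2 length-3 pole coordinates (micrometres).
#' @param plane `"sagittal"` or `"coronal"`.
#' @param cell_id optional id used in degeneracy error messages.
#' @return axial angle in degrees in `[0, 180)`.
#' @export
#' @examples
#' pole_pair_to_axial_angle(c(0, 0, 0), c(0, 1, 1), "sagittal") # 45
pole_pair_to_axial_angle <- function(pole1, pole2, plane, cell_id = "?") {
  ax <- plane_axes(plane)
  d <- as.numeric(pole2) - as.numeric(pole1)
  comp_ref <- sum(d * ax$ref)
  comp_orth <- sum(d * ax$orth)
  if (sqrt(comp_ref^2 + comp_orth^2) <= 1e-6)
    stop_mdp("mdp_degeneracy_error",
             "in-plane component degenerate for cell %s", cell_id)
  fold180(atan2(comp_orth, comp_ref) * 180 / pi)
}

#' Embed a 2D axial angle as a 3D unit axis
#'
#' @param theta_deg axial angle in degrees.
#' @param plane `"sagittal"` or `"coronal"`.
#' @return unit 3-vector (sign-arbitrary) lying in the stated plane.
#' @export
axial_angle_to_vector3 <- function(theta_deg, plane) {
  ax <- plane_axes(plane)
  r <- theta_deg * pi / 180
  cos(r) * ax$ref + sin(r) * ax$orth
}

#' Project a 3D axis into an imaging plane as an axial angle
#'
#' @param u length-3 axis vector (need not be unit; sign-arbitrary).
#' @param plane `"sagittal"` or `"coronal"`.
#' @return axial angle in degrees in `[0, 180)`.
#' @export
project_to_plane <- function(u, plane) {
  ax <- plane_axes(plane)
  comp_ref <- sum(u * ax$ref)
  comp_orth <- sum(u * ax$orth)
  if (sqrt(comp_ref^2 + comp_orth^2) <= 1e-9)
    stop_mdp("mdp_degeneracy_error", "axis is normal to the %s plane", plane)
  fold180(atan2(comp_orth, comp_ref) * 180 / pi)
}

#' Axial mean of 2D angles by angle doubling
#'
#' Angles are doubled onto the full circle, the circular mean resultant is
#' computed, and the mean is halved back. The mean is flagged undefined when
#' the doubled resultant length is below `1e-3` (e.g. two orthogonal axes).
#'
#' @param theta_deg numeric vector of axial angles in degrees.
#' @return list with `mean_deg`, `resultant_length` (R-bar on doubled angles)
#'   and `defined`.
#' @export
#' @examples
#' axial_mean_2d(c(10, 170))$mean_deg # 0
axial_mean_2d <- function(theta_deg) {
  if (length(theta_deg) < 1) stop_mdp("mdp_empty_input_error", "no angles")
  z <- exp(2i * theta_deg * pi / 180)
  m <- mean(z)
  rbar <- Mod(m)
  list(mean_deg = fold180(Arg(m) / 2 * 180 / pi),
       resultant_length = rbar,
       defined = rbar >= 1e-3)
}

#' Axial mean of 3D axes via the orientation tensor
#'
#' The mean axis is the leading eigenvector of the scatter tensor
#' `T = mean(u u')`; its eigenvalue `lambda1` (in `[1/3, 1]`) measures
#' concentration. The mean is flagged undefined when the two leading
#' eigenvalues are within `1e-3` (no unique axis). Sign flips of any input
#' leave the result unchanged by construction.
#'
#' @param U numeric `n x 3` matrix of axis vectors (rows; sign-arbitrary).
#' @return list with `axis` (unit 3-vector), `lambda1`, `defined`.
#' @export
axial_mean_3d <- function(U) {
  U <- rbind(U)
  if (nrow(U) < 1) stop_mdp("mdp_empty_input_error", "no axes")
  U <- U / sqrt(rowSums(U^2))
  T <- crossprod(U) / nrow(U)
  e <- eigen(T, symmetric = TRUE)
  axis <- e$vectors[, 1]
  list(axis = axis / sqrt(sum(axis^2)),
       lambda1 = e$values[1],
       defined = (e$values[1] - e$values[2]) >= 1e-3)
}

#' Axial angular difference
#'
#' For two 2D axial angles: `min(d, 180 - d)` with `d = |a - b| mod 180`.
#' For two 3D axes: `acos(|u . m|)` in degrees. Both lie in `[0, 90]` and are
#' symmetric in their arguments.
#'
#' @param a,b either two angles in degrees (2D) or two length-3 axis vectors.
#' @return difference in degrees in `[0, 90]`.
#' @export
#' @examples
#' axial_difference(170, 10) # 20
axial_difference <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) stop_mdp("mdp_type_error", "mixed 2D/3D axial input")
  if (la == 1) {
    d <- abs(a - b) %% 180
    min(d, 180 - d)
  } else if (la == 3) {
    ua <- a / sqrt(sum(a^2)); ub <- b / sqrt(sum(b^2))
    acos(pmin(1, abs(sum(ua * ub)))) * 180 / pi
  } else stop_mdp("mdp_type_error", "axial input must be an angle or 3-vector")
}

#' Build a 4x4 similarity transform
#'
#' Column-vector convention: `p' = R %*% (s * p) + t`.
#'
#' @param rotation 3x3 rotation (optionally a reflection).
#' @param scale positive scalar.
#' @param translation length-3 vector.
#' @return a 4x4 matrix.
#' @export
similarity_matrix <- function(rotation = diag(3), scale = 1,
                              translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation * scale
  m[1:3, 4] <- translation
  m
}

#' Apply a 4x4 transform to points (column-vector convention)
#' @param points `n x 3` matrix.
#' @param matrix a 4x4 transform.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(points, matrix) {
  points <- rbind(points)
  t(matrix[1:3, 1:3] %*% t(points) + matrix[1:3, 4])
}

#' Draw a rotation matrix uniformly from SO(3)
#' @param n ignored; one matrix is returned.
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(n = 1) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Transform a cell table by a similarity transform
#'
#' Positions (poles and nuclei) are transformed fully; division axes, being
#' directions, are rotated (and possibly reflected) but not translated or
#' scaled, which the pole-pair representation gives automatically. Pairwise
#' axial differences between cells are preserved exactly.
#'
#' @param cells a `cell_table`.
#' @param matrix a 4x4 similarity transform (`p' = A p + t`, `A = s R`).
#' @return the transformed `cell_table`; ellipse orientation columns are
#'   dropped (in-plane ellipse fits do not survive a 3D rotation) with a log
#'   note, and `plane` is set to `"none3d"` unless the rotation is identity.
#' @export
apply_similarity_to_cells <- function(cells, matrix) {
  A <- matrix[1:3, 1:3]
  dt <- det(A)
  if (abs(dt) < 1e-12)
    stop_mdp("mdp_transform_error", "singular transform")
  out <- as.data.frame(cells)
  for (pref in c("pole1", "pole2", "nucleus")) {
    cols <- paste0(pref, c("_x", "_y", "_z"))
    out[cols] <- apply_transform(as.matrix(out[cols]), matrix)
  }
  s <- abs(dt)^(1 / 3)
  R <- A / s
  pure_rotation <- max(abs(R - diag(3))) < 1e-12
  if (!pure_rotation) {
    if ("ellipse_theta_deg" %in% names(out)) {
      out$ellipse_theta_deg <- NA_real_
      mdp_log("transform", "ellipse orientations dropped (non-identity rotation)")
    }
    out$plane <- "none3d"
  }
  validate_cell_table(out)
}

#' 3D division axes of the mitotic cells in a table
#' @param cells a `cell_table`.
#' @return `n_mitotic x 3` matrix of unit axes, rownames = cell ids.
#' @export
cell_axes_3d <- function(cells) {
  m <- cells[cells$is_mitotic, , drop = FALSE]
  d <- cbind(m$pole2_x - m$pole1_x, m$pole2_y - m$pole1_y,
             m$pole2_z - m$pole1_z)
  n <- sqrt(rowSums(d^2))
  if (any(n <= 1e-9))
    stop_mdp("mdp_degeneracy_error", "zero-length pole pair for cell %s",
             m$cell_id[n <= 1e-9][1])
  u <- d / n
  rownames(u) <- m$cell_id
  u
}
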