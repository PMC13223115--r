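# Synthetic-tissue generator.
#
# Emulates the statistical structure of the mandibular-prominence data the
# analysis is designed for: a closed ellipsoidal tissue mesh with 7 analytic
# landmarks, cells uniform in its interior, a mediolateral gradient of
# division-axis concentration (medial aligned to the anterior axis, lateral
# isotropic), a mediolateral gradient of mitotic rate (lateral high), and
# nuclear-ellipse shape variance increasing laterally. All randomness flows
# from one integer seed.

#' Ground-truth mediolateral gradients for a synthetic specimen
#'
#' Each parameter is linearly interpolated along the normalized mediolateral
#' coordinate `u` in `[0, 1]` (`0` = medial edge, `1` = lateral edge).
#'
#' @param kappa_medial,kappa_lateral axial concentration of division axes
#'   about the preferred axis (dimensionless, >= 0; `0` = isotropic).
#' @param rate_medial,rate_lateral mitotic fraction in `[0, 1]`.
#' @param shape_sd_medial,shape_sd_lateral log-scale SD of the nuclear aspect
#'   ratio (>= 0).
#' @param preferred_axis `"anterior"` or a custom 3-vector.
#' @return a `gradient_spec` list.
#' @export
gradient_spec <- function(kappa_medial = 30, kappa_lateral = 0.5,
                          rate_medial = 0.05, rate_lateral = 0.25,
                          shape_sd_medial = 0.1, shape_sd_lateral = 0.2,
                          preferred_axis = "anterior") {
  if (kappa_medial < 0 || kappa_lateral < 0)
    stop_mdp("mdp_parameter_error", "kappa must be >= 0")
  rates <- c(rate_medial, rate_lateral)
  if (any(rates < 0) || any(rates > 1))
    stop_mdp("mdp_parameter_error", "rates must lie in [0, 1]")
  if (shape_sd_medial < 0 || shape_sd_lateral < 0)
    stop_mdp("mdp_parameter_error", "shape_sd must be >= 0")
  structure(list(kappa_medial = kappa_medial, kappa_lateral = kappa_lateral,
                 rate_medial = rate_medial, rate_lateral = rate_lateral,
                 shape_sd_medial = shape_sd_medial,
                 shape_sd_lateral = shape_sd_lateral,
                 preferred_axis = preferred_axis),
            class = "gradient_spec")
}

preferred_axis_vector <- function(truth) {
  if (identical(truth$preferred_axis, "anterior")) c(0, 1, 0)
  else {
    v <- as.numeric(unlist(truth$preferred_axis))
    v / sqrt(sum(v^2))
  }
}

# Unit icosahedron subdivided n times, vertices projected to the unit sphere.
icosphere <- function(n_subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0,  1, phi, 0, -1, -phi, 0,  1, -phi, 0,
                0, -1, phi,  0, 1, phi,  0, -1, -phi, 0, 1, -phi,
                phi, 0, -1,  phi, 0, 1, -phi, 0, -1, -phi, 0, 1),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12,
                2,6,10, 6,12,5, 12,11,3, 11,8,7, 8,2,9,
                4,10,5, 4,5,3, 4,3,7, 4,7,9, 4,9,10,
                5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
              ncol = 3, byrow = TRUE)
  for (it in seq_len(n_subdiv)) {
    midcache <- new.env(hash = TRUE)
    vlist <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midcache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (vlist[i, ] + vlist[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist <<- rbind(vlist, m)
      idx <- nrow(vlist)
      midcache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vlist; f <- nf
  }
  list(vertices = v, faces = f)
}

#' Build an ellipsoidal tissue mesh with 7 analytic landmarks
#'
#' A subdivided icosphere scaled anisotropically by `semi_axes`, giving a
#' watertight triangulated ellipsoid standing in for a mandibular-prominence
#' surface. Seven landmarks are placed at analytically known surface points:
#' the six semi-axis poles (+x lateral, -x medial, +y anterior, -y posterior,
#' +z dorsal, -z ventral) and the surface point in the antero-medial
#' direction `(-1, 1, 0)` from the centre.
#'
#' @param semi_axes positive length-3 semi-axes (micrometres);
#'   `(x, y, z)` = (mediolateral, anteroposterior, dorsoventral).
#' @param n_subdiv icosphere subdivision level (>= 1).
#' @return list with `mesh` (a [triangle_mesh()]) and `landmarks`
#'   (a `landmark_config` of 7 named points).
#' @export
make_mdp_mesh <- function(semi_axes = c(300, 150, 100), n_subdiv = 3) {
  if (n_subdiv < 1) stop_mdp("mdp_parameter_error", "n_subdiv must be >= 1")
  if (any(semi_axes <= 0)) stop_mdp("mdp_parameter_error", "semi_axes must be > 0")
  ico <- icosphere(n_subdiv)
  verts <- sweep(ico$vertices, 2, semi_axes, `*`)
  mesh <- triangle_mesh(verts, ico$faces)
  surf_point <- function(dir) {
    dir / sqrt(sum(dir^2 / semi_axes^2))
  }
  pts <- rbind(
    lateral       = c(semi_axes[1], 0, 0),
    medial        = c(-semi_axes[1], 0, 0),
    anterior      = c(0, semi_axes[2], 0),
    posterior     = c(0, -semi_axes[2], 0),
    dorsal        = c(0, 0, semi_axes[3]),
    ventral       = c(0, 0, -semi_axes[3]),
    anteromedial  = surf_point(c(-1, 1, 0))
  )
  list(mesh = mesh, landmarks = landmark_config(pts, rownames(pts)))
}

#' Sample cell positions uniformly inside a watertight mesh
#'
#' Rejection sampling from the axis-aligned bounding box with a ray-parity
#' containment test; deterministic given `seed`.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param n number of cells (>= 1).
#' @param seed integer seed.
#' @return `n x 3` matrix of positions (micrometres).
#' @export
sample_cells <- function(mesh, n, seed) {
  if (!mesh$watertight)
    stop_mdp("mdp_geometry_error", "sampling requires a watertight mesh")
  stopifnot(n >= 1)
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  out <- matrix(numeric(0), ncol = 3)
  set.seed(seed)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 2.2) + 16
    cand <- cbind(stats::runif(m, lo[1], hi[1]),
                  stats::runif(m, lo[2], hi[2]),
                  stats::runif(m, lo[3], hi[3]))
    keep <- points_in_mesh(mesh, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Draw n unit axes about `axis` with concentration kappa:
# polar deviation |wrapped-normal(0, sd = 1/sqrt(kappa))|, azimuth uniform.
# kappa below 1e-8 is the isotropic limit and draws uniformly on the sphere.
sample_axial_vectors <- function(n, axis, kappa) {
  axis <- axis / sqrt(sum(axis^2))
  out <- matrix(NA_real_, n, 3)
  iso <- kappa < 1e-8
  if (any(iso)) {
    k <- sum(iso)
    g <- matrix(stats::rnorm(3 * k), k, 3)
    out[iso, ] <- g / sqrt(rowSums(g^2))
  }
  if (any(!iso)) {
    k <- sum(!iso)
    sd_rad <- 1 / sqrt(kappa[!iso])
    dev <- stats::rnorm(k, 0, sd_rad)
    dev <- abs(((dev + pi) %% (2 * pi)) - pi)  # wrap then fold to [0, pi]
    psi <- stats::runif(k, 0, 2 * pi)
    # orthonormal frame around the preferred axis
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    out[!iso, ] <- outer(cos(dev), axis) +
      outer(sin(dev) * cos(psi), e1) + outer(sin(dev) * sin(psi), e2)
  }
  out
}

#' Assign mitotic status, division axes and nuclear ellipses to cells
#'
#' The normalized mediolateral coordinate `u` of each cell (0 = medial edge of
#' the tissue extent, 1 = lateral) linearly interpolates the gradient
#' parameters. Mitosis is Bernoulli with rate `rate(u)`; mitotic cells get a
#' 3D axial division vector about the preferred axis with concentration
#' `kappa(u)`, realized as a pole pair of fixed 6 um separation centred on
#' the nucleus, and a nuclear ellipse (minor axis fixed at 5 um, aspect ratio
#' lognormal with median 1.3 and log-SD `shape_sd(u)`, orientation = the
#' sagittal in-plane angle of the division axis plus wrapped-normal noise of
#' SD 20 degrees). Non-mitotic cells carry coincident poles and no ellipse.
#'
#' @param positions `n x 3` matrix of nuclear positions (micrometres).
#' @param truth a [gradient_spec()].
#' @param seed integer seed.
#' @param specimen_id specimen label for the table.
#' @param extent_x optional `c(min, max)` mediolateral extent defining `u`
#'   (defaults to the range of the positions' x coordinates).
#' @return a validated `cell_table`.
#' @export
assign_behaviours <- function(positions, truth, seed, specimen_id = "synthetic",
                              extent_x = NULL) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(extent_x)) extent_x <- range(positions[, 1])
  u <- (positions[, 1] - extent_x[1]) / max(extent_x[2] - extent_x[1], 1e-12)
  u <- pmin(pmax(u, 0), 1)
  lerp <- function(a, b) a + u * (b - a)
  rate <- lerp(truth$rate_medial, truth$rate_lateral)
  kappa <- lerp(truth$kappa_medial, truth$kappa_lateral)
  shape_sd <- lerp(truth$shape_sd_medial, truth$shape_sd_lateral)
  set.seed(seed)
  is_mitotic <- stats::runif(n) < rate
  pole1 <- positions; pole2 <- positions
  major <- rep(NA_real_, n); minor <- rep(NA_real_, n); theta <- rep(NA_real_, n)
  m <- which(is_mitotic)
  if (length(m)) {
    axes <- sample_axial_vectors(length(m), preferred_axis_vector(truth),
                                 kappa[m])
    pole1[m, ] <- positions[m, , drop = FALSE] - 3 * axes
    pole2[m, ] <- positions[m, , drop = FALSE] + 3 * axes
    minor[m] <- 5
    ar <- stats::rlnorm(length(m), meanlog = log(1.3),
                        sdlog = pmax(shape_sd[m], 1e-12))
    ar <- pmax(ar, 1 / ar)  # fold: aspect ratio is major/minor >= 1
    major[m] <- 5 * ar
    base_theta <- vapply(seq_along(m), function(i) {
      tryCatch(project_to_plane(axes[i, ], "sagittal"),
               error = function(e) stats::runif(1, 0, 180))
    }, numeric(1))
    noise <- stats::rnorm(length(m), 0, 20)
    noise <- ((noise + 180) %% 360) - 180
    theta[m] <- fold180(base_theta + noise)
  }
  df <- data.frame(
    cell_id = sprintf("%s_c%05d", specimen_id, seq_len(n)),
    specimen_id = specimen_id,
    plane = "none3d",
    pole1_x = pole1[, 1], pole1_y = pole1[, 2], pole1_z = pole1[, 3],
    pole2_x = pole2[, 1], pole2_y = pole2[, 2], pole2_z = pole2[, 3],
    nucleus_x = positions[, 1], nucleus_y = positions[, 2],
    nucleus_z = positions[, 3],
    is_mitotic = is_mitotic,
    ellipse_major_um = major, ellipse_minor_um = minor,
    ellipse_theta_deg = theta,
    stringsAsFactors = FALSE
  )
  validate_cell_table(df)
}

#' Generate one complete synthetic specimen
#'
#' @param n_cells number of cells.
#' @param semi_axes ellipsoid semi-axes (micrometres).
#' @param n_subdiv mesh subdivision level.
#' @param truth a [gradient_spec()].
#' @param seed integer seed; all randomness derives from it.
#' @param specimen_id label.
#' @return a `synthetic_specimen`: list with `mesh`, `landmarks`, `cells`,
#'   `truth`, `seed`.
#' @export
make_specimen <- function(n_cells = 7500, semi_axes = c(300, 150, 100),
                          n_subdiv = 3, truth = gradient_spec(), seed = 1L,
                          specimen_id = "synthetic") {
  geom <- make_mdp_mesh(semi_axes, n_subdiv)
  pos <- sample_cells(geom$mesh, n_cells, stage_seed(seed, "positions"))
  cells <- assign_behaviours(pos, truth, stage_seed(seed, "behaviours"),
                             specimen_id = specimen_id,
                             extent_x = range(geom$mesh$vertices[, 1]))
  structure(list(mesh = geom$mesh, landmarks = geom$landmarks, cells = cells,
                 truth = truth, seed = as.integer(seed)),
            class = "synthetic_specimen")
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf("synthetic_specimen '%s': %d cells (%d mitotic), seed %d\n",
              x$cells$specimen_id[1], nrow(x$cells), sum(x$cells$is_mitotic),
              x$seed))
  invisible(x)
}

#' Generate similarity-transformed replicates of a specimen
#'
#' Each replicate applies a random similarity transform (rotation uniform on
#' SO(3), scale uniform in `[0.9, 1.1]`, translation uniform in `[-50, 50]` um
#' per axis) to the mesh, cells and landmarks, then adds isotropic Gaussian
#' jitter (default SD 2 um) to the landmarks only. The drawn transform is
#' stored per replicate as ground truth.
#'
#' @param specimen a `synthetic_specimen`.
#' @param k number of replicates (>= 1).
#' @param seed integer seed.
#' @param jitter_sd landmark jitter SD in micrometres.
#' @param transforms optional list of explicit 4x4 matrices (length `k`),
#'   bypassing the random draw (e.g. `list(diag(4))` for an identity check).
#' @return list of `k` `synthetic_specimen`s, each with a `transform_truth`
#'   element (the 4x4 matrix applied).
#' @export
make_replicates <- function(specimen, k, seed = 1L, jitter_sd = 2,
                            transforms = NULL) {
  stopifnot(k >= 1)
  set.seed(stage_seed(seed, "replicates"))
  lapply(seq_len(k), function(i) {
    M <- if (!is.null(transforms)) transforms[[i]] else {
      similarity_matrix(rotation = random_rotation(),
                        scale = stats::runif(1, 0.9, 1.1),
                        translation = stats::runif(3, -50, 50))
    }
    lp <- apply_transform(specimen$landmarks$points, M)
    if (jitter_sd > 0)
      lp <- lp + matrix(stats::rnorm(length(lp), 0, jitter_sd), nrow(lp), 3)
    rep <- structure(list(
      mesh = triangle_mesh(apply_transform(specimen$mesh$vertices, M),
                           specimen$mesh$faces),
      landmarks = landmark_config(lp, specimen$landmarks$names),
      cells = apply_similarity_to_cells(specimen$cells, M),
      truth = specimen$truth,
      seed = specimen$seed,
      transform_truth = M
    ), class = "synthetic_specimen")
    rep$cells$specimen_id <- sprintf("%s_rep%d", specimen$cells$specimen_id[1], i)
    rep$cells$cell_id <- sub(specimen$cells$specimen_id[1],
                             rep$cells$specimen_id[1], rep$cells$cell_id,
                             fixed = TRUE)
    rep
  })
}
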