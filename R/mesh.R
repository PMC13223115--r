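#' Triangle mesh container
#'
#' A minimal triangle-mesh class: an `n x 3` vertex matrix in micrometres and
#' an `m x 3` integer face matrix of 1-based vertex indices. A mesh is flagged
#' watertight when every undirected edge is shared by exactly two faces.
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (micrometres).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `watertight`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3)
    stop_mdp("mdp_format_error", "vertices must have 3 columns")
  if (any(is.na(vertices)))
    stop_mdp("mdp_integrity_error", "NaN/NA vertex coordinate")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop_mdp("mdp_format_error", "face indices out of range")
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces,
                 watertight = is_watertight(faces)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, watertight = %s\n",
              nrow(x$vertices), nrow(x$faces), x$watertight))
  invisible(x)
}

# Every undirected edge must appear in exactly 2 faces.
is_watertight <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Surface area of a triangle mesh
#' @param mesh a [triangle_mesh()].
#' @return total area in square micrometres.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Per-face areas
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of face areas.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Signed volume of a watertight mesh
#'
#' Signed tetrahedron decomposition against the origin (divergence theorem);
#' positive for outward-oriented faces.
#' @param mesh a [triangle_mesh()].
#' @return enclosed volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

#' Volume centroid of a watertight mesh
#' @param mesh a [triangle_mesh()].
#' @return length-3 centroid of the enclosed volume.
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  vol <- sum(det6) / 6
  ctr <- colSums((p1 + p2 + p3) / 4 * det6) / 6 / vol
  as.numeric(ctr)
}

#' Read a triangle mesh from PLY (ASCII) or OBJ
#'
#' Format is chosen by file extension. Only triangular faces are accepted.
#'
#' @param path file path ending in `.ply` or `.obj`.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop_mdp("mdp_io_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path)
  else if (ext == "obj") read_obj(path)
  else stop_mdp("mdp_format_error", "unsupported mesh format: .%s", ext)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop_mdp("mdp_format_error", "not a PLY file: %s", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop_mdp("mdp_format_error", "PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop_mdp("mdp_format_error", "only ASCII PLY is supported")
  # parse element counts and vertex property names in order
  elems <- list(); cur <- NULL
  for (h in hdr) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = character(0))
    } else if (tok[1] == "property" && !is.null(cur) && tok[2] != "list") {
      elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop_mdp("mdp_format_error", "PLY must declare vertex and face elements")
  nv <- elems$vertex$n; nf <- elems$face$n
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vlines <- body[seq_len(nv)]
  flines <- body[nv + seq_len(nf)]
  vdat <- matrix(scan(text = vlines, quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- elems$vertex$props[seq_len(ncol(vdat))]
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  fdat <- lapply(strsplit(trimws(flines), "\\s+"), as.numeric)
  cnts <- vapply(fdat, `[`, numeric(1), 1)
  if (any(cnts != 3))
    stop_mdp("mdp_format_error", "non-triangular PLY face (vertex count %d)",
             max(cnts))
  faces <- t(vapply(fdat, function(r) r[2:4], numeric(3))) + 1
  mesh <- triangle_mesh(verts, faces)
  extra <- setdiff(colnames(vdat), c("x", "y", "z"))
  if (length(extra)) mesh$vertex_attributes <- vdat[, extra, drop = FALSE]
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- matrix(scan(text = gsub("^v\\s+", "", vlines), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ftok <- strsplit(gsub("^f\\s+", "", trimws(flines)), "\\s+")
  if (any(lengths(ftok) != 3))
    stop_mdp("mdp_format_error", "non-triangular OBJ face")
  faces <- t(vapply(ftok, function(tk) {
    as.integer(vapply(strsplit(tk, "/"), `[`, character(1), 1))
  }, integer(3)))
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh to PLY (ASCII) or OBJ
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path ending in `.ply` or `.obj`.
#' @param vertex_values optional numeric per-vertex scalar written as a
#'   `quality` property (PLY only); `NA` written as the sentinel `-9999`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, vertex_values = NULL) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             "comment units micrometres; sentinel -9999 marks undefined quality",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z")
    if (!is.null(vertex_values)) {
      if (length(vertex_values) != nrow(v))
        stop_mdp("mdp_dimension_error",
                 "vertex_values length %d != vertex count %d",
                 length(vertex_values), nrow(v))
      hdr <- c(hdr, "property float quality")
      vv <- ifelse(is.na(vertex_values), -9999, vertex_values)
      vl <- sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3], vv)
    } else {
      vl <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    }
    hdr <- c(hdr, sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    fl <- sprintf("3 %d %d %d", f[, 1] - 1, f[, 2] - 1, f[, 3] - 1)
    writeLines(c(hdr, vl, fl), path)
  } else if (ext == "obj") {
    vl <- sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(vl, fl), path)
  } else stop_mdp("mdp_format_error", "unsupported mesh format: .%s", ext)
  invisible(path)
}
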