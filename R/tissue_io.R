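# Interchange formats: delimited cell tables, FCSV landmark files, scalar
# surface fields (PLY + sidecar table), and the synthetic-specimen bundle.

cell_table_required <- c("cell_id", "specimen_id", "plane",
                         "pole1_x", "pole1_y", "pole1_z",
                         "pole2_x", "pole2_y", "pole2_z",
                         "nucleus_x", "nucleus_y", "nucleus_z",
                         "is_mitotic")
cell_table_optional <- c("ellipse_major_um", "ellipse_minor_um",
                         "ellipse_theta_deg")

#' Validate a cell table
#'
#' Checks the documented schema: required columns present; `cell_id` unique;
#' plane one of `sagittal`, `coronal`, `none3d`; pole pairs distinct on
#' mitotic rows; ellipse axes positive with major >= minor where present.
#' All failures name the offending column or cell.
#'
#' @param df a data.frame of cell records (coordinates in micrometres).
#' @return the validated data.frame, with class `cell_table` prepended.
#' @export
validate_cell_table <- function(df) {
  miss <- setdiff(cell_table_required, names(df))
  if (length(miss))
    stop_mdp("mdp_schema_error", "missing required column(s): %s",
             paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop_mdp("mdp_integrity_error", "duplicate cell_id: %s",
             df$cell_id[duplicated(df$cell_id)][1])
  bad_plane <- !df$plane %in% c("sagittal", "coronal", "none3d")
  if (any(bad_plane))
    stop_mdp("mdp_schema_error", "invalid plane label for cell %s",
             df$cell_id[bad_plane][1])
  df$is_mitotic <- as.logical(df$is_mitotic)
  mit <- which(df$is_mitotic)
  if (length(mit)) {
    d <- abs(df$pole1_x[mit] - df$pole2_x[mit]) +
         abs(df$pole1_y[mit] - df$pole2_y[mit]) +
         abs(df$pole1_z[mit] - df$pole2_z[mit])
    if (any(d == 0))
      stop_mdp("mdp_integrity_error",
               "pole1 == pole2 on mitotic cell %s", df$cell_id[mit[d == 0]][1])
  }
  if (all(c("ellipse_major_um", "ellipse_minor_um") %in% names(df))) {
    has <- !is.na(df$ellipse_major_um) & !is.na(df$ellipse_minor_um)
    bad <- has & (df$ellipse_minor_um <= 0 |
                  df$ellipse_major_um < df$ellipse_minor_um)
    if (any(bad))
      stop_mdp("mdp_integrity_error",
               "ellipse axes invalid (need major >= minor > 0) for cell %s",
               df$cell_id[bad][1])
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Read a delimited cell table
#'
#' @param path CSV or TSV file with the documented header schema; coordinates
#'   are taken as micrometres.
#' @param dialect `"csv"` or `"tsv"`.
#' @return a validated `cell_table` data.frame, row order preserved.
#' @export
read_cell_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mdp("mdp_io_error", "no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = if (dialect == "csv") "," else "\t",
                          stringsAsFactors = FALSE)
  df <- validate_cell_table(df)
  mdp_log("ingest", "read %d cells (%d mitotic) from %s",
          nrow(df), sum(df$is_mitotic), path)
  df
}

#' Write a cell table to CSV
#' @param cells a `cell_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landmark configuration
#'
#' Supports 3D Slicer markups fiducial files (`fcsv`: comment header lines
#' starting with `#`, columns `id,x,y,z,...,label`) and plain CSV with columns
#' `name,x,y,z`. Unknown FCSV columns are ignored.
#'
#' @param path file path.
#' @param fmt `"fcsv"` or `"csv"`.
#' @param expected_n expected landmark count (default 7); a mismatch is a
#'   schema error.
#' @return a `landmark_config`: list with `points` (n x 3 matrix, micrometres)
#'   and `names`.
#' @export
read_landmarks <- function(path, fmt = c("fcsv", "csv"), expected_n = 7) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop_mdp("mdp_io_error", "no such file: %s", path)
  if (fmt == "fcsv") {
    lines <- readLines(path)
    cols_line <- grep("^#\\s*columns\\s*=", lines, value = TRUE)
    body <- lines[!grepl("^#", lines)]
    body <- body[nzchar(trimws(body))]
    cols <- if (length(cols_line)) {
      strsplit(sub("^#\\s*columns\\s*=\\s*", "", cols_line[1]), ",")[[1]]
    } else c("id", "x", "y", "z", "label")
    df <- utils::read.table(text = body, sep = ",", stringsAsFactors = FALSE,
                            col.names = make.names(cols, unique = TRUE),
                            fill = TRUE)
    known <- c("id", "x", "y", "z", "label")
    unk <- setdiff(cols, known)
    if (length(unk))
      mdp_log("landmarks", "ignoring %d unknown FCSV column(s): %s",
              length(unk), paste(unk, collapse = ","))
    pts <- as.matrix(df[, c("x", "y", "z")])
    nms <- if ("label" %in% names(df)) as.character(df$label) else as.character(df$id)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    pts <- as.matrix(df[, c("x", "y", "z")])
    nms <- as.character(df$name)
  }
  if (!is.null(expected_n) && nrow(pts) != expected_n)
    stop_mdp("mdp_schema_error", "expected %d landmarks, found %d in %s",
             expected_n, nrow(pts), path)
  if (any(is.na(pts)))
    stop_mdp("mdp_integrity_error", "NaN/NA landmark coordinate in %s", path)
  landmark_config(pts, nms)
}

#' Construct a landmark configuration
#' @param points numeric `n x 3` matrix (micrometres).
#' @param names optional landmark names (defaults `L1..Ln`).
#' @return a `landmark_config` object.
#' @export
landmark_config <- function(points, names = NULL) {
  points <- rbind(points)
  if (ncol(points) != 3) stop_mdp("mdp_schema_error", "landmarks must be n x 3")
  if (any(is.na(points))) stop_mdp("mdp_integrity_error", "NaN landmark")
  if (is.null(names)) names <- paste0("L", seq_len(nrow(points)))
  dimnames(points) <- NULL
  structure(list(points = points, names = as.character(names)),
            class = "landmark_config")
}

#' Write landmarks as a Slicer-style FCSV file
#' @param lm a `landmark_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  hdr <- c("# Markups fiducial file version = 4.11",
           "# CoordinateSystem = LPS",
           "# columns = id,x,y,z,label")
  p <- lm$points
  rows <- sprintf("%d,%.17g,%.17g,%.17g,%s", seq_len(nrow(p)),
                  p[, 1], p[, 2], p[, 3], lm$names)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a scalar surface field
#'
#' Serializes a per-vertex (or per-face) scalar field as a PLY `quality`
#' attribute (vertex fields only) plus a sidecar delimited table of element
#' index, value and coverage count. Undefined values use the sentinel `-9999`,
#' documented in the PLY header comment and the sidecar header.
#'
#' @param mesh the [triangle_mesh()] the field lives on.
#' @param field a `surface_field` (see [surface_field()]).
#' @param path output PLY path; the sidecar table is written to
#'   `paste0(path, ".csv")`.
#' @return `path`, invisibly.
#' @export
write_field <- function(mesh, field, path) {
  n_elem <- if (field$element_kind == "vertex") nrow(mesh$vertices) else nrow(mesh$faces)
  if (length(field$values) != n_elem)
    stop_mdp("mdp_dimension_error", "field length %d != %s count %d",
             length(field$values), field$element_kind, n_elem)
  if (field$element_kind == "vertex") {
    write_mesh(mesh, path, vertex_values = field$values)
  } else {
    write_mesh(mesh, path)
  }
  side <- data.frame(element = seq_len(n_elem) - 1L,
                     value = ifelse(is.na(field$values), -9999, field$values),
                     coverage = field$coverage)
  con <- file(paste0(path, ".csv"), "w")
  writeLines(sprintf("# element_kind=%s; sentinel=-9999 marks undefined values",
                     field$element_kind), con)
  utils::write.csv(side, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read a scalar surface field written by [write_field()]
#' @param path the PLY path given to [write_field()].
#' @return list with `mesh` and `field` (a `surface_field`).
#' @export
read_field <- function(path) {
  mesh <- read_mesh(path)
  side <- utils::read.csv(paste0(path, ".csv"), comment.char = "#")
  kind_line <- readLines(paste0(path, ".csv"), n = 1)
  kind <- sub(".*element_kind=([a-z]+);.*", "\\1", kind_line)
  vals <- side$value
  vals[vals == -9999] <- NA_real_
  list(mesh = mesh,
       field = surface_field(vals, side$coverage, kind))
}

#' Write a synthetic-specimen bundle to a directory
#'
#' Writes `mesh.ply`, `landmarks.fcsv`, `cells.csv` and `truth.json`.
#' @param specimen a `synthetic_specimen` (see [make_specimen()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(specimen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(specimen$mesh, file.path(dir, "mesh.ply"))
  write_landmarks(specimen$landmarks, file.path(dir, "landmarks.fcsv"))
  write_cell_table(specimen$cells, file.path(dir, "cells.csv"))
  jsonlite::write_json(c(specimen$truth, list(seed = specimen$seed)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a synthetic-specimen bundle written by [write_bundle()]
#' @param dir bundle directory.
#' @return a `synthetic_specimen`.
#' @export
read_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  seed <- truth$seed; truth$seed <- NULL
  structure(list(
    mesh = read_mesh(file.path(dir, "mesh.ply")),
    landmarks = read_landmarks(file.path(dir, "landmarks.fcsv"), "fcsv"),
    cells = validate_cell_table(utils::read.csv(file.path(dir, "cells.csv"),
                                                stringsAsFactors = FALSE)),
    truth = do.call(gradient_spec, truth),
    seed = seed
  ), class = "synthetic_specimen")
}
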