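# Neighbourhood alignment: ball queries, mitotic alignment scores,
# mediolateral segment partition, and the local mitotic index.

#' Exact fixed-radius neighbour lists
#'
#' Closed-ball Euclidean query (boundary included) accelerated by a uniform
#' grid of cell size `radius`: only the 27 surrounding grid cells of a point
#' can contain its neighbours. The focal point is excluded from its own list.
#'
#' @param positions `n x 3` matrix (micrometres).
#' @param radius_um ball radius (> 0).
#' @return list of `n` integer vectors of neighbour row indices.
#' @export
find_neighbours <- function(positions, radius_um) {
  if (radius_um <= 0) stop_mdp("mdp_parameter_error", "radius must be > 0")
  positions <- rbind(positions)
  n <- nrow(positions)
  if (n == 0) return(list())
  lo <- apply(positions, 2, min)
  key <- floor(sweep(positions, 2, lo) / radius_um)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(n), kstr)
  r2 <- radius_um^2
  lapply(seq_len(n), function(i) {
    k <- key[i, ]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      b <- buckets[[paste(k[1] + dx, k[2] + dy, k[3] + dz)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (!length(cand)) return(integer(0))
    d2 <- (positions[cand, 1] - positions[i, 1])^2 +
          (positions[cand, 2] - positions[i, 2])^2 +
          (positions[cand, 3] - positions[i, 3])^2
    sort(cand[d2 <= r2])
  })
}

#' Mitotic alignment scores
#'
#' For each mitotic cell, the axial angular difference (degrees, 0-90)
#' between its division axis and the mean division axis of all mitotic cells
#' within `radius_um` of it (focal cell excluded by default). Low scores mean
#' a cell divides like its neighbours. Cells with no neighbours or an
#' undefined neighbourhood mean get `NA` scores, flagged, never dropped.
#'
#' @param cells a `cell_table`; only mitotic rows are used.
#' @param radius_um neighbourhood radius (micrometres).
#' @param mode `"3d"` (axes from pole pairs) or `"2d"` (in-plane angles; all
#'   cells must share one plane).
#' @param include_focal include the focal cell in its own neighbourhood mean
#'   (default `FALSE`; see Details).
#' @return data.frame with `cell_id`, `n_neighbours`, `score_deg`, `defined`.
#' @details The focal cell is excluded from its own neighbourhood mean so the
#'   score is a genuine cell-versus-neighbours contrast; including it biases
#'   every score toward zero. The switch is logged in the output attributes.
#' @export
alignment_scores <- function(cells, radius_um = 200, mode = c("3d", "2d"),
                             include_focal = FALSE) {
  mode <- match.arg(mode)
  mit <- cells[cells$is_mitotic, , drop = FALSE]
  pos <- as.matrix(mit[, c("nucleus_x", "nucleus_y", "nucleus_z")])
  nb <- find_neighbours(pos, radius_um)
  if (mode == "3d") {
    axes <- cell_axes_3d(cells)
    score_fun <- function(i, idx) {
      m <- axial_mean_3d(axes[idx, , drop = FALSE])
      if (!m$defined) return(NA_real_)
      axial_difference(axes[i, ], m$axis)
    }
  } else {
    planes <- unique(mit$plane)
    if (length(planes) != 1 || planes == "none3d")
      stop_mdp("mdp_plane_mixing_error",
               "2d mode needs a single common plane, found: %s",
               paste(planes, collapse = ", "))
    th <- vapply(seq_len(nrow(mit)), function(i) {
      pole_pair_to_axial_angle(
        c(mit$pole1_x[i], mit$pole1_y[i], mit$pole1_z[i]),
        c(mit$pole2_x[i], mit$pole2_y[i], mit$pole2_z[i]),
        planes, mit$cell_id[i])
    }, numeric(1))
    score_fun <- function(i, idx) {
      m <- axial_mean_2d(th[idx])
      if (!m$defined) return(NA_real_)
      axial_difference(th[i], m$mean_deg)
    }
  }
  score <- rep(NA_real_, nrow(mit))
  nnb <- integer(nrow(mit))
  for (i in seq_len(nrow(mit))) {
    idx <- nb[[i]]
    nnb[i] <- length(idx)
    if (include_focal) idx <- c(idx, i)
    if (length(idx) == 0) next
    score[i] <- score_fun(i, idx)
  }
  out <- data.frame(cell_id = mit$cell_id, n_neighbours = nnb,
                    score_deg = score, defined = !is.na(score),
                    stringsAsFactors = FALSE)
  attr(out, "radius_um") <- radius_um
  attr(out, "mode") <- mode
  attr(out, "include_focal") <- include_focal
  out
}

#' Equal-width mediolateral segment partition
#'
#' Bins the cells' mediolateral (x) coordinate into `k` equal-width segments
#' over the occupied extent `[min(x), max(x)]`; bins are right-open except the
#' last, which is closed, and segment 1 is the medial (low-x) extreme.
#'
#' @param cells a `cell_table` (or any data.frame with `nucleus_x`).
#' @param k number of segments (>= 1).
#' @return list with `segment_index` (integer per cell, 1..k) and
#'   `bin_edges` (length k+1).
#' @export
segment_partition <- function(cells, k = 6) {
  stopifnot(k >= 1)
  x <- cells$nucleus_x
  if (length(x) == 0) stop_mdp("mdp_empty_input_error", "no cells")
  r <- range(x)
  if (diff(r) <= 0)
    stop_mdp("mdp_degenerate_extent_error",
             "all cells share one mediolateral coordinate")
  edges <- seq(r[1], r[2], length.out = k + 1)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), k)
  list(segment_index = as.integer(idx), bin_edges = edges)
}

#' Local mitotic index at query points
#'
#' The fraction of nuclei within `radius_um` of each query point that are
#' mitotic; `NA` where the ball is empty. The relative index divides by the
#' global mitotic fraction, so 1 means the tissue-average proliferation rate.
#'
#' @param all_cells a `cell_table` including non-mitotic nuclei.
#' @param query_points `m x 3` matrix.
#' @param radius_um ball radius (micrometres).
#' @return data.frame with `n_in_ball`, `n_mitotic`, `index`,
#'   `relative_index`.
#' @export
local_mitotic_index <- function(all_cells, query_points, radius_um = 200) {
  if (radius_um <= 0) stop_mdp("mdp_parameter_error", "radius must be > 0")
  query_points <- rbind(query_points)
  pos <- as.matrix(all_cells[, c("nucleus_x", "nucleus_y", "nucleus_z")])
  mit <- all_cells$is_mitotic
  r2 <- radius_um^2
  res <- t(vapply(seq_len(nrow(query_points)), function(i) {
    d2 <- (pos[, 1] - query_points[i, 1])^2 +
          (pos[, 2] - query_points[i, 2])^2 +
          (pos[, 3] - query_points[i, 3])^2
    inb <- d2 <= r2
    c(sum(inb), sum(mit[inb]))
  }, numeric(2)))
  idx <- ifelse(res[, 1] > 0, res[, 2] / res[, 1], NA_real_)
  global <- mean(mit)
  data.frame(n_in_ball = res[, 1], n_mitotic = res[, 2], index = idx,
             relative_index = idx / global)
}

#' Per-segment summary of alignment and proliferation
#'
#' Complete-case aggregation: undefined scores stay out of the means but are
#' counted.
#'
#' @param cells a `cell_table`.
#' @param scores output of [alignment_scores()] for the same table.
#' @param k number of mediolateral segments.
#' @return data.frame, one row per segment: counts, mitotic index, mean and
#'   SD of defined alignment scores.
#' @export
segment_summary <- function(cells, scores, k = 6) {
  part <- segment_partition(cells, k)
  seg_all <- part$segment_index
  mit_rows <- which(cells$is_mitotic)
  seg_of_score <- seg_all[mit_rows][match(scores$cell_id, cells$cell_id[mit_rows])]
  do.call(rbind, lapply(seq_len(k), function(s) {
    in_seg <- seg_all == s
    sc <- scores$score_deg[seg_of_score == s]
    data.frame(segment = s,
               n_cells = sum(in_seg),
               n_mitotic = sum(cells$is_mitotic[in_seg]),
               mitotic_index = mean(cells$is_mitotic[in_seg]),
               n_scored = sum(!is.na(sc)),
               mean_score_deg = mean(sc, na.rm = TRUE),
               sd_score_deg = stats::sd(sc, na.rm = TRUE))
  }))
}
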