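# Nuclear shape morphometrics: the five per-nucleus geometric features
# (area, perimeter, aspect ratio, eccentricity, long-axis orientation),
# their PCA, the spindle-vs-long-axis orientation offset, feature-position
# association, and per-segment variance profiling.

#' Nuclear shape features of a fitted ellipse
#'
#' Analytic features of an ellipse with full axes `major_um >= minor_um`:
#' area `pi a b / 4` (on full axes), perimeter by Ramanujan's second
#' approximation, aspect ratio `major/minor` (>= 1), eccentricity
#' `sqrt(1 - (minor/major)^2)`, and orientation folded to `[0, 180)`.
#'
#' @param major_um,minor_um full major/minor axis lengths (micrometres).
#' @param theta_deg long-axis orientation in degrees.
#' @return data.frame with `area`, `perimeter`, `aspect_ratio`,
#'   `eccentricity`, `long_axis_deg`.
#' @export
#' @examples
#' ellipse_features(2, 2, 0)$area # pi
ellipse_features <- function(major_um, minor_um, theta_deg) {
  if (any(minor_um <= 0) || any(major_um < minor_um))
    stop_mdp("mdp_parameter_error", "need major >= minor > 0")
  a <- major_um / 2; b <- minor_um / 2
  h <- ((a - b) / (a + b))^2
  data.frame(
    area = pi * a * b,
    perimeter = pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h))),
    aspect_ratio = major_um / minor_um,
    eccentricity = sqrt(1 - (minor_um / major_um)^2),
    long_axis_deg = fold180(theta_deg)
  )
}

# 4-connected components of a logical matrix; returns integer labels.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (d in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= ncol(mask)) {
          q <- (d[2] - 1L) * nr + d[1]
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Nuclear shape features from a binary mask
#'
#' CellProfiler-style raster features: area = pixel count times pixel area;
#' perimeter = crack length (count of exposed pixel edges) times pixel size;
#' aspect ratio, eccentricity and orientation from the second-central-moment
#' equivalent ellipse. Orientation is the long-axis angle from the image
#' x axis (columns), folded to `[0, 180)`.
#'
#' @param mask logical or 0/1 matrix with exactly one 4-connected foreground
#'   component.
#' @param pixel_size_um pixel edge length (micrometres).
#' @return data.frame as in [ellipse_features()].
#' @export
mask_features <- function(mask, pixel_size_um = 1) {
  mask <- mask > 0
  if (!any(mask)) stop_mdp("mdp_mask_error", "empty mask")
  lab <- label_components(mask)
  if (max(lab) != 1L)
    stop_mdp("mdp_mask_error", "mask has %d connected components", max(lab))
  idx <- which(mask, arr.ind = TRUE)
  # x along columns, y along rows, pixel centres
  x <- idx[, 2] * pixel_size_um
  y <- idx[, 1] * pixel_size_um
  npix <- nrow(idx)
  area <- npix * pixel_size_um^2
  # crack perimeter: each foreground pixel edge not shared with foreground
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  up    <- pad[1:nrow(mask), 2:(ncol(mask) + 1), drop = FALSE]
  down  <- pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1), drop = FALSE]
  left  <- pad[2:(nrow(mask) + 1), 1:ncol(mask), drop = FALSE]
  right <- pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2), drop = FALSE]
  perim <- sum(core & !up) + sum(core & !down) +
           sum(core & !left) + sum(core & !right)
  perimeter <- perim * pixel_size_um
  mu20 <- stats::var(x) * (npix - 1) / npix + pixel_size_um^2 / 12
  mu02 <- stats::var(y) * (npix - 1) / npix + pixel_size_um^2 / 12
  mu11 <- stats::cov(x, y) * (npix - 1) / npix
  tr <- mu20 + mu02
  dd <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + dd) / 2; l2 <- (tr - dd) / 2
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  data.frame(
    area = area,
    perimeter = perimeter,
    aspect_ratio = sqrt(l1 / max(l2, 1e-300)),
    eccentricity = sqrt(max(0, 1 - l2 / max(l1, 1e-300))),
    long_axis_deg = fold180(theta)
  )
}

#' PCA of nuclear shape features
#'
#' Columns are z-scored (mean 0, SD 1, denominator `n - 1`) and the
#' correlation matrix eigendecomposed. Loading signs are fixed so each
#' component's largest-magnitude loading is positive. By default the PCA uses
#' the four linear features (area, perimeter, aspect ratio, eccentricity);
#' the axial orientation can be folded in as a doubled-angle sine/cosine pair
#' with `include_orientation = TRUE`.
#'
#' @param features data.frame holding the feature columns (e.g. from
#'   [ellipse_features()]); n >= 6 rows.
#' @param include_orientation add `cos(2 theta)`, `sin(2 theta)` columns for
#'   `long_axis_deg`.
#' @return list with `loadings` (p x p), `scores` (n x p),
#'   `variance_fraction` (length p, non-increasing, sums to 1).
#' @export
shape_pca <- function(features, include_orientation = FALSE) {
  cols <- c("area", "perimeter", "aspect_ratio", "eccentricity")
  X <- as.matrix(features[, cols])
  if (include_orientation) {
    r <- features$long_axis_deg * pi / 90  # doubled angle in radians
    X <- cbind(X, orient_cos = cos(r), orient_sin = sin(r))
  }
  if (nrow(X) < 6) stop_mdp("mdp_sample_size_error", "PCA needs n >= 6")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_mdp("mdp_degeneracy_error", "zero-variance feature: %s",
             colnames(X)[sds == 0][1])
  Z <- scale(X)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- Z %*% L
  list(loadings = L, scores = scores,
       variance_fraction = e$values / sum(e$values))
}

#' Signed spindle-versus-long-axis orientation offset
#'
#' Per cell, the signed axial difference (spindle minus nuclear long axis)
#' folded to `(-90, 90]` degrees; the summary mean is computed on doubled
#' angles and halved back, so it respects axial wraparound.
#'
#' @param spindle_deg spindle (division) axial angles, degrees.
#' @param long_axis_deg nuclear long-axis axial angles, degrees.
#' @return list with `offset_deg` (per cell, `NA` where either input is
#'   missing), `mean_offset_deg`, `n`.
#' @export
#' @examples
#' spindle_axis_offset(10, 170)$offset_deg # +20
spindle_axis_offset <- function(spindle_deg, long_axis_deg) {
  d <- spindle_deg - long_axis_deg
  off <- d %% 180
  off <- ifelse(off > 90, off - 180, off)
  ok <- !is.na(off)
  z <- mean(exp(2i * off[ok] * pi / 180))
  mean_off <- Arg(z) / 2 * 180 / pi
  list(offset_deg = off, mean_offset_deg = mean_off, n = sum(ok))
}

#' Association between a nuclear feature and mediolateral position
#'
#' Spearman rank correlation with a seeded permutation p-value (two-sided,
#' +1 convention).
#'
#' @param feature numeric feature values (n >= 10).
#' @param position mediolateral coordinates, same length.
#' @param reps permutation replicates.
#' @param seed optional seed.
#' @return list with `statistic` (rho), `p_value`, `method`, `n`.
#' @export
feature_position_association <- function(feature, position, reps = 999,
                                         seed = NULL) {
  ok <- stats::complete.cases(feature, position)
  feature <- feature[ok]; position <- position[ok]
  n <- length(feature)
  if (n < 10) stop_mdp("mdp_sample_size_error", "needs n >= 10")
  if (stats::sd(feature) == 0 || stats::sd(position) == 0)
    stop_mdp("mdp_degeneracy_error", "constant input")
  rho <- stats::cor(feature, position, method = "spearman")
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  for (r in seq_len(reps)) {
    if (abs(stats::cor(feature, sample(position), method = "spearman")) >=
        abs(rho) - 1e-12) cnt <- cnt + 1L
  }
  list(statistic = rho, p_value = (1 + cnt) / (reps + 1),
       method = "permutation", n = n)
}

#' Per-segment variance profile of PC scores
#'
#' For one PC score vector: the variance within each mediolateral segment,
#' a permutation test of variance heterogeneity (statistic = range of
#' per-segment variances under segment-label permutation), and the Spearman
#' correlation between segment index and variance as a monotonicity summary.
#' Segments with fewer than `min_n` cells are dropped with a warning.
#'
#' @param score numeric PC scores, one per cell.
#' @param segment integer segment index per cell (1 = most medial).
#' @param reps permutation replicates.
#' @param seed optional seed.
#' @param min_n minimum cells per segment (default 3).
#' @return list with `segment_variance` (named by segment), `statistic`
#'   (variance range), `p_value`, `monotonicity_rho`.
#' @export
segment_variance_profile <- function(score, segment, reps = 999, seed = NULL,
                                     min_n = 3) {
  tab <- table(segment)
  keep_seg <- as.integer(names(tab)[tab >= min_n])
  if (length(keep_seg) < length(tab))
    warn_mdp("mdp_undersized_segment_warning",
             "dropped %d segment(s) with < %d cells",
             length(tab) - length(keep_seg), min_n)
  if (length(keep_seg) < 2)
    stop_mdp("mdp_sample_size_error", "need >= 2 segments with >= %d cells",
             min_n)
  ok <- segment %in% keep_seg
  score <- score[ok]; segment <- segment[ok]
  seg_var <- tapply(score, segment, stats::var)
  obs <- diff(range(seg_var))
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  for (r in seq_len(reps)) {
    sv <- tapply(score, sample(segment), stats::var)
    if (diff(range(sv)) >= obs - 1e-12) cnt <- cnt + 1L
  }
  rho <- stats::cor(as.numeric(names(seg_var)), as.numeric(seg_var),
                    method = "spearman")
  list(segment_variance = seg_var, statistic = obs,
       p_value = (1 + cnt) / (reps + 1), monotonicity_rho = rho)
}
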