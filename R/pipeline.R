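# End-to-end pipeline over synthetic specimens: generation, superimposition
# into a common atlas space, alignment scoring, circular inference, nuclear
# morphometrics, shape comparison and surface cartography. Every stage is a
# thin composition of the module functions; all randomness derives from one
# seed via stage_seed().

#' Compose an OPA result into a reference-space (micrometre) transform
#'
#' [opa_superimpose()] maps a specimen to the unit-centroid-size frame of the
#' reference. For cell-level analysis in physical units, the aligned
#' configuration is scaled back by the reference's centroid size and
#' translated to its centroid, i.e. specimens are expressed in the atlas's
#' own micrometre coordinates.
#'
#' @param opa result of [opa_superimpose()].
#' @param reference the reference `landmark_config` used there.
#' @return a 4x4 similarity transform.
#' @export
opa_to_reference_transform <- function(opa, reference) {
  Y <- if (inherits(reference, "landmark_config")) reference$points else rbind(reference)
  similarity_matrix(diag(3), centroid_size(Y), colMeans(Y)) %*% opa$transform
}

#' Run the full demonstration pipeline on synthetic tissue
#'
#' Generates one base specimen plus similarity-transformed replicates
#' (4 specimens total), superimposes all onto the base atlas by ordinary
#' Procrustes, pools cells in atlas space, and emits the figure-level
#' analyses: per-segment rose histograms and Kuiper tests, alignment-score
#' segment summaries, a medial-versus-lateral Watson comparison, nuclear
#' shape features with PCA, spindle/long-axis offsets and
#' variance-by-position profiles, a second synthetic "age" with mean shapes,
#' TPS-morphed atlas and signed displacement map, alignment and relative
#' proliferation surface fields, depth-shell summaries, and the ray-cast
#' positional orientation map. All tables are written as CSV/JSON under
#' `out_dir`; rerunning with the same seed reproduces them byte for byte.
#'
#' @param out_dir output directory (created).
#' @param seed global integer seed.
#' @param config a [run_config()].
#' @param n_cells cells per specimen.
#' @param n_replicates similarity-transformed replicates of the base.
#' @param truth a [gradient_spec()] (the defaults are the study conditions).
#' @return the manifest (named list of stage outputs and file paths),
#'   invisibly; also written as `manifest.json`.
#' @export
run_demo <- function(out_dir, seed = 1L, config = run_config(seed = seed),
                     n_cells = 7500, n_replicates = 3,
                     truth = gradient_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, config_hash = config_hash(config),
                   stages = list(), warnings = character(0))
  fail <- function(stage, e) {
    stop_mdp("mdp_stage_error", "stage '%s' failed: %s (completed: %s)",
             stage, conditionMessage(e),
             paste(names(manifest$stages), collapse = ", "))
  }
  path <- function(...) file.path(out_dir, ...)

  ## -- synth ---------------------------------------------------------------
  stage <- "synth"
  tryCatch({
    base <- make_specimen(n_cells = n_cells, truth = truth,
                          seed = stage_seed(seed, "synth"),
                          specimen_id = "spec1")
    reps <- make_replicates(base, n_replicates,
                            seed = stage_seed(seed, "replicates"))
    specimens <- c(list(base), reps)
    write_bundle(base, path("base_bundle"))
    manifest$stages$synth <- list(n_specimens = length(specimens),
                                  n_cells = n_cells)
  }, error = function(e) fail(stage, e))

  ## -- ingest: pole-nucleus pairing report ---------------------------------
  stage <- "ingest"
  tryCatch({
    mit <- base$cells[base$cells$is_mitotic, ]
    mid <- cbind((mit$pole1_x + mit$pole2_x) / 2,
                 (mit$pole1_y + mit$pole2_y) / 2,
                 (mit$pole1_z + mit$pole2_z) / 2)
    rownames(mid) <- mit$cell_id
    nuc <- as.matrix(base$cells[, c("nucleus_x", "nucleus_y", "nucleus_z")])
    rownames(nuc) <- base$cells$cell_id
    pairing <- match_poles_to_nuclei(mid, nuc, max_dist_um = 10)
    utils::write.csv(pairing$matches, path("pairing.csv"), row.names = FALSE)
    manifest$stages$ingest <- list(matched = nrow(pairing$matches),
                                   unmatched = length(pairing$unmatched_poles))
  }, error = function(e) fail(stage, e))

  ## -- align: superimpose onto the base atlas, pool, score -----------------
  stage <- "align"
  tryCatch({
    pooled <- base$cells
    for (r in reps) {
      opa <- opa_superimpose(r$landmarks, base$landmarks)
      M <- opa_to_reference_transform(opa, base$landmarks)
      tc <- apply_similarity_to_cells(r$cells, M)
      pooled <- rbind(pooled, tc[, names(pooled)])
    }
    pooled <- validate_cell_table(pooled)
    scores <- alignment_scores(pooled, config$neighbourhood_radius_um, "3d")
    seg <- segment_summary(pooled, scores, config$n_segments)
    utils::write.csv(scores, path("alignment_scores.csv"), row.names = FALSE)
    utils::write.csv(seg, path("segment_summary.csv"), row.names = FALSE)
    manifest$stages$align <- list(n_pooled = nrow(pooled),
                                  n_scored = sum(scores$defined))
  }, error = function(e) fail(stage, e))

  ## -- stats: rose histograms, Kuiper per segment, Watson medial/lateral ---
  stage <- "stats"
  tryCatch({
    mit <- pooled[pooled$is_mitotic, ]
    axes <- cell_axes_3d(pooled)
    sag <- vapply(seq_len(nrow(axes)),
                  function(i) project_to_plane(axes[i, ], "sagittal"),
                  numeric(1))
    part <- segment_partition(pooled, config$n_segments)
    seg_of_mit <- part$segment_index[match(mit$cell_id, pooled$cell_id)]
    stats_rows <- lapply(seq_len(config$n_segments), function(s) {
      th <- sag[seg_of_mit == s]
      if (length(th) < 4)
        return(data.frame(segment = s, n = length(th), V = NA, p = NA))
      kt <- kuiper_uniformity(th, reps = config$permutation_reps,
                              seed = stage_seed(seed, paste0("kuiper", s)))
      data.frame(segment = s, n = kt$n, V = kt$statistic, p = kt$p_value)
    })
    kuiper_tab <- do.call(rbind, stats_rows)
    rose <- sapply(seq_len(config$n_segments), function(s)
      rose_histogram(sag[seg_of_mit == s], config$rose_bin_deg))
    colnames(rose) <- paste0("segment", seq_len(config$n_segments))
    med <- sag[seg_of_mit <= config$n_segments / 2]
    lat <- sag[seg_of_mit > config$n_segments / 2]
    wt <- watson_u2_two_sample(med, lat, reps = config$permutation_reps,
                               seed = stage_seed(seed, "watson"))
    utils::write.csv(kuiper_tab, path("kuiper_by_segment.csv"), row.names = FALSE)
    utils::write.csv(cbind(bin_lower_deg = as.integer(rownames(rose)), rose),
                     path("rose_by_segment.csv"), row.names = FALSE)
    jsonlite::write_json(wt, path("watson_medial_lateral.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$stats <- list(kuiper_rejections_0.05 =
                                    sum(kuiper_tab$p < 0.05, na.rm = TRUE),
                                  watson_p = wt$p_value)
  }, error = function(e) fail(stage, e))

  ## -- nuclei: shape features, PCA, offsets, variance profile --------------
  stage <- "nuclei"
  tryCatch({
    has_ell <- mit[!is.na(mit$ellipse_major_um), ]
    feats <- ellipse_features(has_ell$ellipse_major_um,
                              has_ell$ellipse_minor_um,
                              has_ell$ellipse_theta_deg)
    pca <- shape_pca(feats)
    sag_ell <- sag[match(has_ell$cell_id, mit$cell_id)]
    off <- spindle_axis_offset(sag_ell, has_ell$ellipse_theta_deg)
    assoc_ecc <- feature_position_association(
      feats$eccentricity, has_ell$nucleus_x, reps = config$permutation_reps,
      seed = stage_seed(seed, "assoc_ecc"))
    seg_of_ell <- part$segment_index[match(has_ell$cell_id, pooled$cell_id)]
    varprof <- segment_variance_profile(pca$scores[, 1], seg_of_ell,
                                        reps = config$permutation_reps,
                                        seed = stage_seed(seed, "varprof"))
    utils::write.csv(cbind(cell_id = has_ell$cell_id, feats,
                           PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                           offset_deg = off$offset_deg),
                     path("nuclear_features.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      variance_fraction = pca$variance_fraction,
      loadings = as.data.frame(pca$loadings),
      mean_offset_deg = off$mean_offset_deg,
      eccentricity_position = assoc_ecc,
      pc1_variance_profile = list(
        segment_variance = as.numeric(varprof$segment_variance),
        p_value = varprof$p_value,
        monotonicity_rho = varprof$monotonicity_rho)),
      path("nuclear_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$nuclei <- list(n_nuclei = nrow(feats),
                                   pc1_fraction = pca$variance_fraction[1])
  }, error = function(e) fail(stage, e))

  ## -- atlas: second age, mean shapes, TPS morph, displacement map ---------
  stage <- "atlas"
  tryCatch({
    # an older "age": the same tissue grown anisotropically (antero-medial
    # outgrowth), as a second ground-truth mean shape
    age2 <- make_mdp_mesh(semi_axes = c(320, 195, 110), n_subdiv = 3)
    reps2 <- make_replicates(
      structure(list(mesh = age2$mesh, landmarks = age2$landmarks,
                     cells = base$cells, truth = truth, seed = base$seed),
                class = "synthetic_specimen"),
      n_replicates, seed = stage_seed(seed, "age2reps"))
    aligned1 <- lapply(reps, function(r)
      opa_superimpose(r$landmarks, base$landmarks)$aligned)
    aligned2 <- lapply(reps2, function(r)
      opa_superimpose(r$landmarks, base$landmarks)$aligned)
    mean1 <- mean_configuration(aligned1)
    mean2 <- mean_configuration(aligned2)
    base_unit <- opa_superimpose(base$landmarks, base$landmarks)
    atlas_mesh_unit <- triangle_mesh(
      apply_transform(base$mesh$vertices, base_unit$transform),
      base$mesh$faces)
    morph1 <- tps_warp(atlas_mesh_unit, base_unit$aligned, mean1)
    morph2 <- tps_warp(atlas_mesh_unit, base_unit$aligned, mean2)
    disp <- closest_point_distances(morph1, morph2)
    write_mesh(morph1, path("age1_mean_mesh.ply"))
    write_mesh(morph2, path("age2_mean_mesh.ply"))
    write_field(morph1, disp, path("displacement_age1_to_age2.ply"))
    jsonlite::write_json(list(mean_age1 = as.data.frame(mean1$points),
                              mean_age2 = as.data.frame(mean2$points)),
                         path("mean_configurations.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$atlas <- list(
      mean_abs_displacement = mean(abs(disp$values)))
  }, error = function(e) fail(stage, e))

  ## -- map: surface fields, shells, ray casting ----------------------------
  stage <- "map"
  tryCatch({
    mit_pos <- as.matrix(mit[, c("nucleus_x", "nucleus_y", "nucleus_z")])
    score_of_mit <- scores$score_deg[match(mit$cell_id, scores$cell_id)]
    fld_align <- vertex_field_average(base$mesh, mit_pos, score_of_mit,
                                      config$neighbourhood_radius_um)
    lmi <- local_mitotic_index(pooled, base$mesh$vertices,
                               config$neighbourhood_radius_um)
    fld_prolif <- surface_field(lmi$relative_index, lmi$n_in_ball, "vertex")
    write_field(base$mesh, fld_align, path("alignment_map.ply"))
    write_field(base$mesh, fld_prolif, path("proliferation_map.ply"))
    shells <- nested_shells(base$mesh, config$shell_scales)
    band <- assign_depth(mit_pos, shells)
    band_summary <- do.call(rbind, lapply(sort(unique(band)), function(b) {
      data.frame(band = b, n = sum(band == b),
                 mean_score_deg = mean(score_of_mit[band == b], na.rm = TRUE))
    }))
    hits <- raycast_positional_orientation(base$mesh, mit_pos,
                                           cell_axes_3d(mit))
    utils::write.csv(band_summary, path("depth_band_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(face = seq_along(hits$counts),
                                hits = hits$counts,
                                frequency = hits$frequency),
                     path("raycast_hits.csv"), row.names = FALSE)
    manifest$stages$map <- list(total_hits = hits$total_hits,
                                n_cast = hits$n_cast)
  }, error = function(e) fail(stage, e))

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  mdp_log("demo", "pipeline complete: %d stages, outputs in %s",
          length(manifest$stages), out_dir)
  invisible(manifest)
}
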