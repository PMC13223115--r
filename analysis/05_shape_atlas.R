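#!/usr/bin/env Rscript
# Stage 5 -- shape change between developmental stages: a second synthetic
# "age" grown antero-medially, per-age mean landmark configurations from
# Procrustes-aligned replicates, thin-plate-spline morphing of the atlas mesh
# to each mean, and the signed closest-point displacement map between the two
# morphed surfaces (positive = outward displacement at the later age).
suppressMessages(library(mdpcarto))

seed <- as.integer(Sys.getenv("MDP_SEED", "1"))
base <- read_bundle("results/specimens/spec1")

age2 <- make_mdp_mesh(semi_axes = c(320, 195, 110), n_subdiv = 3)
age2_spec <- structure(list(mesh = age2$mesh, landmarks = age2$landmarks,
                            cells = base$cells, truth = base$truth,
                            seed = base$seed), class = "synthetic_specimen")
reps1 <- make_replicates(base, 3, seed = stage_seed(seed, "age1reps"))
reps2 <- make_replicates(age2_spec, 3, seed = stage_seed(seed, "age2reps"))

aligned1 <- lapply(reps1, function(r)
  opa_superimpose(r$landmarks, base$landmarks)$aligned)
aligned2 <- lapply(reps2, function(r)
  opa_superimpose(r$landmarks, base$landmarks)$aligned)
mean1 <- mean_configuration(aligned1)
mean2 <- mean_configuration(aligned2)

base_unit <- opa_superimpose(base$landmarks, base$landmarks)
atlas_unit <- triangle_mesh(
  apply_transform(base$mesh$vertices, base_unit$transform), base$mesh$faces)
morph1 <- tps_warp(atlas_unit, base_unit$aligned, mean1)
morph2 <- tps_warp(atlas_unit, base_unit$aligned, mean2)
disp <- closest_point_distances(morph1, morph2)

write_mesh(morph1, "results/age1_mean_mesh.ply")
write_mesh(morph2, "results/age2_mean_mesh.ply")
write_field(morph1, disp, "results/displacement_age1_to_age2.ply")
jsonlite::write_json(list(mean_age1 = as.data.frame(mean1$points),
                          mean_age2 = as.data.frame(mean2$points)),
                     "results/mean_configurations.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("displacement map (age1 -> age2, unit centroid size): mean %.4f, range [%.4f, %.4f]\n",
            mean(disp$values), min(disp$values), max(disp$values)))
cat(sprintf("outward-displaced vertices: %d of %d\n",
            sum(disp$values > 0), length(disp$values)))
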