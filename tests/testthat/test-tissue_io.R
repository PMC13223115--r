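toy_cells <- function() {
  data.frame(
    cell_id = c("a", "b", "c"), specimen_id = "s1", plane = "sagittal",
    pole1_x = c(0, 1, 0), pole1_y = c(0, 0, 0), pole1_z = c(0, 0, 0),
    pole2_x = c(0, 1, 0), pole2_y = c(1, 2, 0), pole2_z = c(1, 0, 0),
    nucleus_x = c(0, 1, 5), nucleus_y = c(0.5, 1, 5), nucleus_z = c(0.5, 0, 5),
    is_mitotic = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
}

test_that("cell tables read, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy_cells(), f, row.names = FALSE)
  tab <- read_cell_table(f, "csv")
  expect_s3_class(tab, "cell_table")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$is_mitotic), 2)
  expect_equal(tab$cell_id, c("a", "b", "c")) # row order preserved

  # full-bundle round trip, field by field
  spec <- make_specimen(n_cells = 80, n_subdiv = 2, seed = 5)
  d <- withr::local_tempdir()
  write_bundle(spec, d)
  back <- read_bundle(d)
  expect_equal(as.data.frame(back$cells), as.data.frame(spec$cells),
               tolerance = 1e-8)
  expect_equal(back$truth$kappa_medial, spec$truth$kappa_medial)
  expect_equal(back$seed, spec$seed)
})

test_that("cell-table schema violations are named errors", {
  bad <- toy_cells(); bad$pole2_y[1] <- 0; bad$pole2_z[1] <- 0 # == pole1
  expect_error(validate_cell_table(bad), class = "mdp_integrity_error")
  expect_error(validate_cell_table(bad), "cell a")
  bad2 <- toy_cells(); bad2$plane <- NULL
  expect_error(validate_cell_table(bad2), class = "mdp_schema_error")
  expect_error(validate_cell_table(bad2), "plane")
  bad3 <- rbind(toy_cells(), toy_cells()[1, ])
  expect_error(validate_cell_table(bad3), class = "mdp_integrity_error")
  bad4 <- toy_cells()
  bad4$ellipse_major_um <- c(2, 5, NA); bad4$ellipse_minor_um <- c(3, 1, NA)
  expect_error(validate_cell_table(bad4), class = "mdp_integrity_error")
})

test_that("meshes round-trip through PLY and OBJ and report watertightness", {
  g <- make_mdp_mesh(c(1, 1, 1), 1)$mesh # icosphere: 42 vertices, 80 faces
  expect_equal(nrow(g$vertices), 42)
  expect_equal(nrow(g$faces), 80)
  expect_true(g$watertight)
  holed <- triangle_mesh(g$vertices, g$faces[-1, ])
  expect_false(holed$watertight)

  spec_mesh <- make_mdp_mesh(c(300, 150, 100), 2)$mesh
  for (ext in c(".ply", ".obj")) {
    f <- withr::local_tempfile(fileext = ext)
    write_mesh(spec_mesh, f)
    back <- read_mesh(f)
    expect_lt(max(abs(back$vertices - spec_mesh$vertices)), 1e-6)
    expect_identical(back$faces, spec_mesh$faces)
  }
})

test_that("landmark files round-trip and are schema checked", {
  set.seed(3)
  lm <- landmark_config(matrix(rnorm(21) * 100, 7, 3),
                        names = paste0("pt", 1:7))
  f <- withr::local_tempfile(fileext = ".fcsv")
  write_landmarks(lm, f)
  back <- read_landmarks(f, "fcsv")
  expect_lt(max(abs(back$points - lm$points)), 1e-9)
  expect_equal(back$names, lm$names)

  six <- landmark_config(matrix(rnorm(18), 6, 3))
  f2 <- withr::local_tempfile(fileext = ".fcsv")
  write_landmarks(six, f2)
  expect_error(read_landmarks(f2, "fcsv"), class = "mdp_schema_error")
  writeLines(c("# columns = id,x,y,z,label",
               "1,0,NaN,0,a", "2,1,0,0,b", "3,0,1,0,c", "4,0,0,1,d",
               "5,1,1,0,e", "6,0,1,1,f", "7,1,0,1,g"), f2)
  expect_error(read_landmarks(f2, "fcsv"), class = "mdp_integrity_error")
})

test_that("surface fields round-trip with an explicit undefined sentinel", {
  g <- make_mdp_mesh(c(1, 1, 1), 1)$mesh
  f <- withr::local_tempfile(fileext = ".ply")

  const <- surface_field(rep(1, nrow(g$vertices)),
                         rep(1L, nrow(g$vertices)), "vertex")
  write_field(g, const, f)
  expect_true(all(read_field(f)$field$values == 1))

  set.seed(7)
  vals <- rnorm(nrow(g$vertices))
  vals[c(2, 9, 40)] <- NA
  fld <- surface_field(vals, as.integer(!is.na(vals)), "vertex")
  write_field(g, fld, f)
  sidecar <- readLines(paste0(f, ".csv"))
  expect_equal(sum(grepl(",-9999,", sidecar)), 3)
  back <- read_field(f)
  expect_identical(is.na(back$field$values), is.na(vals))
  expect_lt(max(abs(back$field$values - vals), na.rm = TRUE), 1e-6)

  short <- surface_field(1:5, rep(1L, 5), "vertex")
  expect_error(write_field(g, short, f), class = "mdp_dimension_error")
})
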