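test_that("an all-zero preset yields an empty truth table", {
  empty <- stage_preset("empty", malignant_intensity = 0)
  truth <- sample_cell_positions(empty, mini_geom(), rng_seed = 1)
  expect_equal(nrow(truth), 0L)
  expect_true(all(c("x_um", "y_um", "phenotype", marker_channels()) %in%
                    names(truth)))
})

test_that("placement is deterministic in the seed and stable in structure", {
  geom <- mini_geom()
  p <- mini_preset()
  a1 <- sample_cell_positions(p, geom, rng_seed = 42)
  a2 <- sample_cell_positions(p, geom, rng_seed = 42)
  b <- sample_cell_positions(p, geom, rng_seed = 43)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  # different seed: different coordinates, same malignant count, and the
  # planted vicinity density still meets the target to within cell rounding
  expect_false(isTRUE(all.equal(a1$x_um, b$x_um[seq_len(nrow(a1))])))
  expect_identical(sum(a1$phenotype == "malignant"),
                   sum(b$phenotype == "malignant"))
  for (truth in list(a1, b)) {
    va <- attr(truth, "vicinity_area_mm2")
    refs <- truth[truth$phenotype == "malignant", ]
    cnt <- brute_count_in_vicinity(truth, refs, 75)
    cd4 <- sum(cnt[c("exhausted", "cd4_effector")], na.rm = TRUE)
    expect_lt(abs(cd4 / va - 450), 1.5 / va)
    expect_lt(abs(cnt[["cd8_t"]] / va - 150), 1.5 / va)
    expect_lt(abs(cnt[["nk"]] / va - 300), 1.5 / va)
  }
})

test_that("stage presets plant the printed vicinity densities", {
  geom <- field_geometry()
  ps <- stage_presets()
  cases <- list(
    tumor = c(cd4 = 453, cd8 = 85, nk = 354),
    plaque = c(cd4 = 269, cd8 = 57, nk = 255)
  )
  for (pn in names(cases)) {
    truth <- sample_cell_positions(ps[[pn]], geom, rng_seed = 5)
    va <- attr(truth, "vicinity_area_mm2")
    refs <- truth[truth$phenotype == "malignant", ]
    cnt <- count_in_vicinity(truth, refs, vicinity_params())
    cd4 <- sum(cnt[c("exhausted", "cd4_effector")])
    want <- cases[[pn]]
    expect_lt(abs(cd4 / va - want[["cd4"]]), 1.5 / va)
    expect_lt(abs(cnt[["cd8_t"]] / va - want[["cd8"]]), 1.5 / va)
    expect_lt(abs(cnt[["nk"]] / va - want[["nk"]]), 1.5 / va)
    expect_identical(sum(truth$phenotype == "malignant"),
                     ps[[pn]]$malignant_intensity)
  }
})

test_that("planted marker vectors are consistent with the phenotype rules", {
  for (s in 1:3) {
    truth <- sample_cell_positions(mini_preset(), mini_geom(), rng_seed = s)
    got <- classify_phenotypes(truth[, marker_channels(), with = FALSE])
    expect_identical(got, truth$phenotype)
  }
})

test_that("a geometrically infeasible density raises an error naming the phenotype", {
  tiny <- field_geometry(64L, 64L, 0.5)
  jam <- stage_preset("jam", malignant_intensity = 1,
                      compartment_targets = c(cd8 = 2e5),
                      cluster_sd_um = 5, n_foci = 1)
  expect_error(sample_cell_positions(jam, tiny, rng_seed = 1),
               "infeasible.*cd8_t")
})

test_that("a cell-free noiseless rendering is flat background", {
  geom <- mini_geom()
  empty <- sample_cell_positions(stage_preset("empty", 0), geom, rng_seed = 1)
  img <- render_field(empty, geom,
                      render_params(background_level = 0.2, noise_sd = 0,
                                    illumination_gradient_amplitude = 0),
                      rng_seed = 1)
  expect_named(img, default_panel())
  for (ch in names(img)) expect_true(all(img[[ch]] == 0.2))
})

test_that("a single stained cell lights only its own channels", {
  geom <- mini_geom()
  cell <- data.frame(x_um = 60, y_um = 70, phenotype = "x",
                     CD3 = 1L, CD4 = 0L, CD8 = 0L, CD56 = 0L,
                     GZMB = 0L, TOX = 0L, BTLA = 0L)
  img <- render_field(cell, geom, quiet_render(), rng_seed = 1)
  # centroid pixel (1-based): index = um / um_per_px + 0.5
  ci <- 70 / 0.5 + 0.5; cj <- 60 / 0.5 + 0.5
  for (ch in c("CD3", "DAPI")) {
    x <- img[[ch]]
    # the blurred disk is symmetric, so the centre ties with its mirror
    # pixels up to float rounding
    expect_equal(x[round(ci), round(cj)], max(x), tolerance = 1e-12)
    expect_gt(max(x), 0)
  }
  for (ch in setdiff(default_panel(), c("CD3", "DAPI")))
    expect_true(all(img[[ch]] == 0))
})

test_that("an unknown marker column is rejected with the panel listed", {
  cell <- data.frame(x_um = 10, y_um = 10, phenotype = "x", CD99 = 1L)
  expect_error(render_field(cell, mini_geom(), rng_seed = 1), "CD99")
  expect_error(render_field(cell, mini_geom(), rng_seed = 1), "CD3")
})

test_that("nuclei planted at touching distance merge into one foreground component", {
  geom <- mini_geom()
  cells <- data.frame(x_um = c(60, 66), y_um = c(60, 60), phenotype = "x",
                      CD3 = 0L, CD4 = 0L, CD8 = 0L, CD56 = 0L,
                      GZMB = 0L, TOX = 0L, BTLA = 0L)
  img <- render_field(cells, geom,
                      render_params(noise_sd = 0, peak_jitter = 0,
                                    illumination_gradient_amplitude = 0),
                      rng_seed = 1)
  mask <- bradley_threshold(img$DAPI)
  # flood fill from one planted centre must reach the other
  reach <- flood_reach(mask, round(60 / 0.5 + 0.5), round(60 / 0.5 + 0.5))
  expect_true(reach[round(60 / 0.5 + 0.5), round(66 / 0.5 + 0.5)])
})

test_that("dataset writing round-trips bit-identically from its manifest", {
  geom <- mini_geom()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m <- generate_dataset(mini_preset(), n_fields = 3, base_seed = 9,
                        out_dir = d1, geom = geom)
  expect_length(unique(m$seeds), 3L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_length(dir(d1, pattern = "\\.tiff$"), 3L)
  expect_length(dir(d1, pattern = "\\.csv$"), 3L)
  # refusal without overwrite
  expect_error(generate_dataset(mini_preset(), 1, 9, out_dir = d1, geom = geom),
               "overwrite")
  # regeneration from the manifest alone is byte-identical
  regenerate_dataset(file.path(d1, "manifest.json"), d2)
  for (f in dir(d1, pattern = "\\.csv$"))
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  img1 <- read_field_image(file.path(d1, "field_001.tiff"))
  img2 <- read_field_image(file.path(d2, "field_001.tiff"))
  expect_identical(img1, img2)
  # truth CSV carries the documented columns
  tr <- read_truth_csv(file.path(d1, "field_002.csv"))
  expect_named(tr, c("field_id", "x_um", "y_um", "phenotype",
                     marker_channels()))
  unlink(c(d1, d2), recursive = TRUE)
})
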