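ref_df <- function(x, y, phenotype = "malignant") {
  data.frame(x_um = x, y_um = y,
             phenotype = rep_len(phenotype, length(x)))
}

test_that("vicinity area matches the closed-form disk area", {
  geom <- field_geometry()
  vp <- vicinity_params()
  expect_identical(vicinity_area(ref_df(numeric(0), numeric(0)), vp, geom), 0)
  one <- vicinity_area(ref_df(300, 300), vp, geom)
  expect_lt(abs(one - pi * 75^2 * 1e-6) / (pi * 75^2 * 1e-6), 0.005)
  # union is idempotent: a duplicated reference adds nothing
  expect_identical(vicinity_area(ref_df(c(300, 300), c(300, 300)), vp, geom),
                   one)
  # clipping: a corner reference keeps about a quarter disk
  corner <- vicinity_area(ref_df(0, 0), vp, geom)
  expect_lt(abs(corner - pi * 75^2 * 1e-6 / 4) / (pi * 75^2 * 1e-6 / 4), 0.02)
  expect_lte(vicinity_area(ref_df(c(100, 300, 500), c(100, 300, 500)), vp,
                           geom), field_area_mm2(geom))
})

test_that("the 75 um radius is an inclusive boundary", {
  refs <- ref_df(100, 100)
  near <- rbind(refs, ref_df(174, 100, "cd8_t"))
  far <- rbind(refs, ref_df(176, 100, "cd8_t"))
  expect_identical(count_in_vicinity(near, refs, vicinity_params())[["cd8_t"]], 1L)
  expect_identical(count_in_vicinity(far, refs, vicinity_params())[["cd8_t"]], 0L)
})

test_that("a cell inside several reference disks is counted once", {
  refs <- ref_df(c(100, 110, 120), c(100, 100, 100))
  cells <- rbind(refs, ref_df(110, 120, "nk"))
  cnt <- count_in_vicinity(cells, refs, vicinity_params())
  expect_identical(cnt[["nk"]], 1L)
})

test_that("reference cells never count themselves", {
  vp <- vicinity_params()
  lone <- ref_df(100, 100)
  expect_identical(count_in_vicinity(lone, lone, vp)[["malignant"]], 0L)
  pair <- ref_df(c(100, 150), c(100, 100))      # 50 um apart
  expect_identical(count_in_vicinity(pair, pair, vp)[["malignant"]], 2L)
  apart <- ref_df(c(100, 400), c(100, 100))     # 300 um apart
  expect_identical(count_in_vicinity(apart, apart, vp)[["malignant"]], 0L)
})

test_that("vicinity counts equal the all-pairs brute force on random fields", {
  set.seed(31)
  vp <- vicinity_params()
  for (k in 1:50) {
    n <- sample(50:200, 1)
    cells <- data.frame(
      x_um = runif(n, 0, 600), y_um = runif(n, 0, 600),
      phenotype = sample(c("malignant", "cd4_effector", "cd8_t", "nk"),
                         n, replace = TRUE)
    )
    refs <- cells[cells$phenotype == "malignant", ]
    got <- count_in_vicinity(cells, refs, vp)
    want <- brute_count_in_vicinity(cells, refs, vp$radius_um)
    expect_identical(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("planted density is invariant under field enlargement", {
  p <- mini_preset()
  for (geom in list(mini_geom(), field_geometry(512L, 512L, 0.5))) {
    truth <- sample_cell_positions(p, geom, rng_seed = 3)
    va <- attr(truth, "vicinity_area_mm2")
    refs <- truth[truth$phenotype == "malignant", ]
    cnt <- count_in_vicinity(truth, refs, vicinity_params())
    cd4 <- sum(cnt[c("exhausted", "cd4_effector")])
    expect_lt(abs(cd4 / va - 450), 1.5 / va)
  }
})

test_that("counts and area grow monotonically with the radius", {
  set.seed(13)
  geom <- field_geometry()
  cells <- data.frame(
    x_um = runif(300, 0, 600), y_um = runif(300, 0, 600),
    phenotype = sample(c("malignant", "nk"), 300, replace = TRUE)
  )
  refs <- cells[cells$phenotype == "malignant", ]
  radii <- c(20, 40, 75, 120, 200)
  counts <- sapply(radii, function(r)
    count_in_vicinity(cells, refs, vicinity_params(r))[["nk"]])
  areas <- sapply(radii, function(r)
    vicinity_area(refs, vicinity_params(r), geom))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(areas >= 0 & areas <= field_area_mm2(geom)))
})

test_that("fields without reference cells are flagged but still summarised", {
  cells <- data.frame(field_id = 1L,
                      x_um = c(10, 20), y_um = c(10, 20),
                      phenotype = c("nk", "cd8_t"))
  rep <- vicinity_report(cells, geom = mini_geom())
  expect_true(all(is.na(rep$density_inside)))
  expect_identical(rep$vicinity_area_mm2, rep(0, nrow(rep)))
  expect_identical(rep$field_count[rep$phenotype == "nk"], 1L)
  expect_identical(rep$field_density[rep$phenotype == "cd8_t"], 1L)
})

test_that("the report reproduces planted densities from a truth table", {
  geom <- field_geometry()
  truth <- sample_cell_positions(stage_presets()$tumor, geom, rng_seed = 8)
  rep <- vicinity_report(truth, geom = geom)
  va <- rep$vicinity_area_mm2[1]
  cd4 <- compartment_density(rep)$density_inside
  expect_lt(abs(cd4 - 453), 1.5 / va)
  expect_identical(rep$n_reference_cells[1], 300L)
})
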