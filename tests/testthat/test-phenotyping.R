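test_that("bounding-box overlap fraction matches hand-computed cases", {
  a <- c(0, 0, 10, 10)
  expect_identical(bbox_overlap_fraction(a, a), 1)
  expect_identical(bbox_overlap_fraction(a, c(2, 2, 8, 8)), 1)  # containment
  expect_identical(bbox_overlap_fraction(a, c(0, 5, 10, 15)), 0.5)
  expect_identical(bbox_overlap_fraction(a, c(20, 20, 30, 30)), 0)
  # union denominator: inter 50, union 150
  expect_equal(bbox_overlap_fraction(a, c(0, 5, 10, 15), "union"), 1 / 3)
  expect_error(bbox_overlap_fraction(a, c(1, 1, 1, 5)), "zero-area")
})

test_that("overlap fraction is symmetric for random box pairs", {
  set.seed(5)
  for (k in 1:200) {
    a <- c(sort(sample(0:30, 2)), sort(sample(0:30, 2)))[c(1, 3, 2, 4)]
    b <- c(sort(sample(0:30, 2)), sort(sample(0:30, 2)))[c(1, 3, 2, 4)]
    if ((a[3] - a[1]) * (a[4] - a[2]) == 0 ||
        (b[3] - b[1]) * (b[4] - b[2]) == 0) next
    expect_identical(bbox_overlap_fraction(a, b), bbox_overlap_fraction(b, a))
  }
})

make_obj <- function(channel, label, bbox) {
  data.table::data.table(
    channel = channel, label = label, area_px = 10L,
    bbox_min_row = bbox[1], bbox_min_col = bbox[2],
    bbox_max_row = bbox[3], bbox_max_col = bbox[4],
    row = (bbox[1] + bbox[3]) / 2 - 0.5, col = (bbox[2] + bbox[4]) / 2 - 0.5,
    x_um = ((bbox[2] + bbox[4]) / 2) * 0.5,
    y_um = ((bbox[1] + bbox[3]) / 2) * 0.5
  )
}

test_that("marker assignment honours the overlap threshold", {
  anchor <- make_obj("DAPI", 1L, c(0, 0, 10, 10))
  hit <- assign_markers(anchor, make_obj("CD3", 1L, c(0, 0, 10, 10)))
  expect_identical(hit$CD3, 1L)
  miss <- assign_markers(anchor, make_obj("CD3", 1L, c(40, 40, 50, 50)))
  expect_identical(miss$CD3, 0L)
  weak <- assign_markers(anchor, make_obj("CD3", 1L, c(0, 5, 10, 15)))
  expect_identical(weak$CD3, 0L)  # 0.5 < 0.8
  expect_error(
    assign_markers(anchor, make_obj("CD99", 1L, c(0, 0, 10, 10))),
    "CD99"
  )
})

test_that("one stained blob cannot mark two nuclei (greedy one-to-one)", {
  anchors <- rbind(make_obj("DAPI", 1L, c(0, 0, 10, 10)),
                   make_obj("DAPI", 2L, c(0, 20, 10, 30)))
  blob <- make_obj("CD3", 1L, c(0, 0, 10, 30))  # covers both anchors fully
  cells <- assign_markers(anchors, blob)
  expect_identical(sum(cells$CD3), 1L)
  expect_identical(cells$CD3[cells$cell_id == 1L], 1L)  # tie: lower label
  # two blobs, two anchors: both positive
  blobs <- rbind(make_obj("CD3", 1L, c(0, 0, 10, 10)),
                 make_obj("CD3", 2L, c(0, 20, 10, 30)))
  cells2 <- assign_markers(anchors, blobs)
  expect_identical(cells2$CD3, c(1L, 1L))
})

test_that("phenotype rules classify the canonical marker combinations", {
  mk <- function(...) {
    v <- setNames(rep(0L, 7L), marker_channels())
    v[c(...)] <- 1L
    v
  }
  expect_identical(classify_phenotype(mk("CD3", "CD4", "TOX")), "malignant")
  expect_identical(classify_phenotype(mk("CD56")), "nk")
  expect_identical(classify_phenotype(mk("CD3", "CD4", "BTLA")), "exhausted")
  expect_identical(classify_phenotype(mk("CD3", "CD4")), "cd4_effector")
  expect_identical(classify_phenotype(mk("CD3", "CD8", "GZMB")), "cd8_t")
  expect_identical(classify_phenotype(mk()), "unclassified")
  # granzyme B alone participates in no rule
  expect_identical(classify_phenotype(mk("GZMB")), "unclassified")
})

test_that("exhaustion takes priority: no BTLA+CD4+ cell is ever cd4_effector", {
  set.seed(11)
  mt <- matrix(rbinom(7 * 500, 1, 0.5), 500, 7,
               dimnames = list(NULL, marker_channels()))
  lab <- classify_phenotypes(mt)
  btla_cd4 <- mt[, "BTLA"] == 1 & mt[, "CD3"] == 1 & mt[, "CD4"] == 1 &
    mt[, "TOX"] == 0
  expect_false(any(lab[btla_cd4] == "cd4_effector"))
  expect_true(all(lab[btla_cd4] == "exhausted"))
})

test_that("rule sets are validated", {
  expect_error(validate_phenotype_rules(list(
    list(label = "a", priority = 1L, requires = c(CD3 = "-"))
  )), "positive")
  expect_error(validate_phenotype_rules(list(
    list(label = "a", priority = 1L, requires = c(CD3 = "+")),
    list(label = "a", priority = 2L, requires = c(CD4 = "+"))
  )), "unique")
})

test_that("recovered marker vectors match the planted truth on a clean field", {
  geom <- field_geometry(600L, 600L, 0.5)
  preset <- stage_preset("t", malignant_intensity = 60,
                         compartment_targets = c(cd4 = 453, cd8 = 85, nk = 354),
                         exhausted_fraction = 0.3, cluster_sd_um = 60,
                         n_foci = 2)
  truth <- sample_cell_positions(preset, geom, rng_seed = 2)
  img <- render_field(truth, geom, quiet_render(), rng_seed = 2)
  cells <- phenotype_cells(segment_field(img, geom))
  # nearest-anchor match per truth cell
  d2 <- outer(truth$x_um, cells$x_um, "-")^2 + outer(truth$y_um, cells$y_um, "-")^2
  nn <- apply(d2, 1L, which.min)
  ok <- sqrt(d2[cbind(seq_len(nrow(truth)), nn)]) <= 5
  expect_gt(mean(ok), 0.97)
  same <- sapply(which(ok), function(i) {
    all(unlist(truth[i, marker_channels(), with = FALSE]) ==
        unlist(cells[nn[i], marker_channels(), with = FALSE]))
  })
  expect_gt(mean(same), 0.98)
})
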