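#!/usr/bin/env Rscript

# Simulate the study's synthetic multispectral fields.
#
# Twenty fields (seeds 1-20) are planted for each condition: plaque- and
# tumor-stage lesions, and the responder cohort at baseline and end of
# treatment. Per-field ground-truth tables go to results/; a small example
# dataset (two rendered multi-page TIFFs plus truth CSVs and manifest) is
# written under results/example_dataset/ to show the on-disk format. The
# downstream scripts re-derive images deterministically from the same seeds,
# so the full image stack never needs to be stored.

suppressMessages({
  library(mftme)
  library(data.table)
})

n_fields <- 20L
dir.create("results", showWarnings = FALSE)

presets <- stage_presets()
for (pn in names(presets)) {
  truths <- rbindlist(lapply(seq_len(n_fields), function(i) {
    tr <- sample_cell_positions(presets[[pn]], field_geometry(), rng_seed = i)
    cbind(data.table(field_id = i, vicinity_area_mm2 = attr(tr, "vicinity_area_mm2")), tr)
  }))
  fwrite(truths, sprintf("results/truth_%s.csv", pn))
  n_mal <- truths[phenotype == "malignant", .N, by = field_id]$N
  message(sprintf("%-18s: %5d cells over %d fields; malignant/field mean %.0f",
                  pn, nrow(truths), n_fields, mean(n_mal)))
}

# small on-disk example of the raw data format (reduced geometry keeps the
# demo TIFFs a few MB; the study itself stays in memory at full geometry)
ex_dir <- "results/example_dataset"
unlink(ex_dir, recursive = TRUE)
demo_preset <- stage_preset("tumor_demo", malignant_intensity = 40,
                            compartment_targets = c(cd4 = 453, cd8 = 85, nk = 354),
                            exhausted_fraction = 0.30, cluster_sd_um = 50,
                            n_foci = 2)
generate_dataset(demo_preset, n_fields = 2L, base_seed = 1L,
                 out_dir = ex_dir, geom = field_geometry(400L, 400L, 0.5))
message("example TIFF dataset written to ", ex_dir)
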