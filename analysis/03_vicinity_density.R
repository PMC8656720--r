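#!/usr/bin/env Rscript

# Quantify the tumor microenvironment around malignant cells: per-phenotype
# cell densities inside the union of 75 um disks centred on detected
# CD3+CD4+TOX+ cells, per field, for every condition. Writes the per-field
# report (results/vicinity_report.csv) and a pooled per-condition summary
# (results/vicinity_summary.json).

suppressMessages({
  library(mftme)
  library(data.table)
})

geom <- field_geometry()
reports <- rbindlist(lapply(names(stage_presets()), function(pn) {
  cells <- fread(sprintf("results/cells_%s.csv", pn))
  rep <- vicinity_report(cells, geom = geom)
  cbind(data.table(preset = pn), rep)
}))
fwrite(reports, "results/vicinity_report.csv")

summ <- lapply(split(reports, by = "preset"), function(rp) {
  cd4 <- compartment_density(rp)$density_inside
  out <- list(cd4_compartment = as.list(violin_summary(cd4)))
  for (ph in c("cd8_t", "nk", "exhausted", "malignant")) {
    v <- rp[phenotype == ph & !is.na(density_inside)]$density_inside
    out[[ph]] <- as.list(violin_summary(v))
  }
  out$malignant_per_field <- as.list(violin_summary(
    rp[phenotype == "malignant"]$field_count))
  out
})
jsonlite::write_json(summ, "results/vicinity_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

for (pn in names(summ))
  message(sprintf("%-18s: median vicinity density CD4 %.0f, CD8 %.0f, NK %.0f cells/mm^2",
                  pn, summ[[pn]]$cd4_compartment$median,
                  summ[[pn]]$cd8_t$median, summ[[pn]]$nk$median))
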