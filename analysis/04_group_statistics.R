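#!/usr/bin/env Rscript

# Group comparisons over the per-field vicinity densities: Welch t-tests for
# the plaque-to-tumor shifts of each infiltrate phenotype, the percent
# change of the CD4 compartment, responder baseline-vs-EOT malignant
# burden, and a one-way ANOVA with Sidak-Holm-corrected pairwise contrasts
# across all four conditions. Writes results/stats.json.

suppressMessages({
  library(mftme)
  library(data.table)
})

rep <- fread("results/vicinity_report.csv")

dens <- function(pn, ph) rep[preset == pn & phenotype == ph &
                               !is.na(density_inside)]$density_inside
cd4 <- function(pn) compartment_density(rep[preset == pn])$density_inside

stats <- list()

# stage progression: plaque -> tumor
for (ph in c("cd8_t", "nk", "exhausted")) {
  wt <- welch_t(dens("tumor", ph), dens("plaque", ph))
  stats$stage[[ph]] <- wt
  message(sprintf("tumor vs plaque %-10s: t = %6.2f, df = %5.1f, p = %.2g",
                  ph, wt$t, wt$df, wt$p))
}
wt <- welch_t(cd4("tumor"), cd4("plaque"))
stats$stage$cd4_compartment <- wt
pc <- percent_change(median(cd4("plaque")), median(cd4("tumor")))
stats$stage$cd4_percent_change <- pc
message(sprintf("tumor vs plaque CD4 compartment: t = %.2f, p = %.2g; median increase %.0f%%",
                wt$t, wt$p, pc))

# responder cohort: malignant burden per field, baseline vs EOT
mal <- function(pn) rep[preset == pn & phenotype == "malignant"]$field_count
wt <- welch_t(mal("responder_baseline"), mal("responder_eot"))
stats$responder$malignant_welch <- wt
stats$responder$mean_baseline <- mean(mal("responder_baseline"))
stats$responder$mean_eot <- mean(mal("responder_eot"))
message(sprintf("responder malignant/field: %.0f -> %.0f (t = %.2f, p = %.2g)",
                stats$responder$mean_baseline, stats$responder$mean_eot,
                wt$t, wt$p))

# all four conditions at once: one-way ANOVA + Sidak-Holm post test
groups <- list(plaque = cd4("plaque"), tumor = cd4("tumor"),
               responder_baseline = cd4("responder_baseline"),
               responder_eot = cd4("responder_eot"))
an <- anova_sidak_holm(groups)
stats$anova <- list(F = an$F, df1 = an$df1, df2 = an$df2, p = an$p,
                    pairwise = an$pairwise)
message(sprintf("one-way ANOVA over CD4 densities: F(%d, %d) = %.1f, p = %.2g",
                an$df1, an$df2, an$F, an$p))

# worked CAILS example of the responder rule
stats$responder_rule <- data.frame(
  patient = c("P1", "P2", "P3"),
  cails_before = c(20, 20, 18),
  cails_after = c(10, 11, 25)
)
stats$responder_rule$label <- classify_responder(
  stats$responder_rule$cails_before, stats$responder_rule$cails_after)

jsonlite::write_json(stats, "results/stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, dataframe = "rows")
message("wrote results/stats.json")
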