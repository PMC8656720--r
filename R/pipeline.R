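#' Run the full pipeline on one simulated field
#'
#' Chain: plant ground truth, render channels, segment every channel, call
#' marker co-staining on DAPI anchors, classify phenotypes, and (optionally)
#' build the vicinity report.
#'
#' @param preset a [stage_preset()].
#' @param seed integer field seed.
#' @param geom a [field_geometry()].
#' @param render a [render_params()].
#' @param seg a [seg_params()].
#' @param rules a [phenotype_rules()] set.
#' @param overlap an [overlap_rule()].
#' @param vicinity a [vicinity_params()], or `NULL` to skip the report.
#' @param panel the staining panel.
#' @param field_id identifier stamped on the outputs.
#' @return `list(truth, cells, report)` (`report` is `NULL` when skipped).
#' @export
run_field_pipeline <- function(preset, seed, geom = field_geometry(),
                               render = render_params(), seg = seg_params(),
                               rules = phenotype_rules(),
                               overlap = overlap_rule(),
                               vicinity = vicinity_params(),
                               panel = default_panel(), field_id = 1L) {
  sim <- simulate_field(preset, seed, geom, render, panel)
  objs <- segment_field(sim$image, geom, seg, field_id = field_id,
                        channels = panel)
  cells <- phenotype_cells(objs, rules, overlap, panel)
  report <- if (!is.null(vicinity))
    vicinity_report(cells, vicinity, geom) else NULL
  truth <- data.table::copy(sim$truth)
  truth[, field_id := rep(field_id, nrow(truth))]
  list(truth = truth, cells = cells, report = report)
}

#' Run the pipeline over a seeded series of fields
#'
#' @inheritParams run_field_pipeline
#' @param n_fields number of fields; field `i` uses seed
#'   `base_seed + i - 1` and `field_id = i`.
#' @param base_seed first field seed.
#' @return `list(truths, cells, reports)`: row-bound tables across fields.
#' @export
run_study <- function(preset, n_fields, base_seed, geom = field_geometry(),
                      render = render_params(), seg = seg_params(),
                      rules = phenotype_rules(), overlap = overlap_rule(),
                      vicinity = vicinity_params(), panel = default_panel()) {
  runs <- lapply(seq_len(n_fields), function(i) {
    run_field_pipeline(preset, base_seed + i - 1L, geom, render, seg, rules,
                       overlap, vicinity, panel, field_id = i)
  })
  list(
    truths = data.table::rbindlist(lapply(runs, `[[`, "truth")),
    cells = data.table::rbindlist(lapply(runs, `[[`, "cells")),
    reports = if (!is.null(vicinity))
      data.table::rbindlist(lapply(runs, `[[`, "report")) else NULL
  )
}

#' Per-field malignant-cell counts
#'
#' Counts cells carrying the full malignant marker combination (CD3+ CD4+
#' TOX+, i.e. phenotype `malignant`) in each field of a cell table.
#'
#' @param cells cell records (truth tables work too).
#' @return `data.table` with `field_id` and `n_malignant`.
#' @export
malignant_per_field <- function(cells) {
  cells <- data.table::as.data.table(cells)
  if (!"field_id" %in% names(cells)) {
    cells <- data.table::copy(cells)
    cells[, field_id := rep(1L, nrow(cells))]
  }
  cells[, .(n_malignant = sum(phenotype == "malignant")), by = field_id]
}
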