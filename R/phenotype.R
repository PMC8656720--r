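#' Co-staining overlap rule
#'
#' Two channel objects are considered to stain the same cell when their
#' bounding boxes overlap by at least `min_overlap_fraction` (default 0.80).
#' The denominator of the overlap fraction is configurable: `"smaller_box"`
#' (default - a nuclear box fully inside a cytoplasmic box scores 1, which is
#' the reading that lets nucleic and cytoplasmic staining identify the same
#' cell) or `"union"`.
#'
#' How many anchors one stained object may mark is governed by `support`:
#' `"area_capacity"` (default) lets an object support one anchor per typical
#' single-object area it spans on that channel
#' (`ceiling(area / median channel object area)`), so a blob the size of one
#' stain can never mark two well-separated nuclei, while the fused stain of
#' two touching co-stained cells spans more than one typical area and marks
#' both; `"single"` enforces strict one-object-one-anchor.
#'
#' @param min_overlap_fraction fraction in `(0, 1]`.
#' @param denominator `"smaller_box"` or `"union"`.
#' @param support `"area_capacity"` or `"single"`.
#' @return An object of class `overlap_rule`.
#' @export
overlap_rule <- function(min_overlap_fraction = 0.8,
                         denominator = c("smaller_box", "union"),
                         support = c("area_capacity", "single")) {
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]")
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 denominator = match.arg(denominator),
                 support = match.arg(support)),
            class = "overlap_rule")
}

#' Bounding-box overlap fraction
#'
#' Boxes are half-open `(min_row, min_col, max_row, max_col)`. Returns
#' intersection area divided by the area of the smaller box (or of the union,
#' per `denominator`); 0 when disjoint. Symmetric in its arguments.
#'
#' @param a,b numeric length-4 boxes.
#' @param denominator see [overlap_rule()].
#' @return Fraction in `[0, 1]`.
#' @export
bbox_overlap_fraction <- function(a, b, denominator = "smaller_box") {
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  if (area(a) <= 0 || area(b) <= 0) stop("zero-area bounding box")
  ir <- min(a[3], b[3]) - max(a[1], b[1])
  ic <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(0, ir) * max(0, ic)
  denom <- switch(denominator,
    smaller_box = min(area(a), area(b)),
    union = area(a) + area(b) - inter,
    stop("unknown denominator '", denominator, "'")
  )
  inter / denom
}

#' Phenotype rule set
#'
#' Each rule names a phenotype, a priority (lower wins first) and marker
#' requirements (`"+"` = must be positive, `"-"` = must be negative; markers
#' not mentioned are free). The default five-phenotype set, in priority
#' order:
#'
#' 1. `malignant`: CD3+ CD4+ TOX+
#' 2. `exhausted`: BTLA+ CD3+ CD4+ TOX-
#' 3. `cd4_effector`: CD3+ CD4+ TOX- BTLA-
#' 4. `cd8_t`: CD3+ CD8+ TOX-
#' 5. `nk`: CD56+ CD3- TOX-
#'
#' CD4 phenotypes do not require CD8- (nor vice versa), and granzyme B is
#' measured but used by no rule. A record matching no rule is
#' `"unclassified"`.
#'
#' @return List of rules (class `phenotype_rules`), sorted by priority.
#' @export
phenotype_rules <- function() {
  rules <- list(
    list(label = "malignant", priority = 1L,
         requires = c(CD3 = "+", CD4 = "+", TOX = "+")),
    list(label = "exhausted", priority = 2L,
         requires = c(BTLA = "+", CD3 = "+", CD4 = "+", TOX = "-")),
    list(label = "cd4_effector", priority = 3L,
         requires = c(CD3 = "+", CD4 = "+", TOX = "-", BTLA = "-")),
    list(label = "cd8_t", priority = 4L,
         requires = c(CD3 = "+", CD8 = "+", TOX = "-")),
    list(label = "nk", priority = 5L,
         requires = c(CD56 = "+", CD3 = "-", TOX = "-"))
  )
  validate_phenotype_rules(rules)
}

#' @rdname phenotype_rules
#' @param rules a list of rules to validate.
#' @export
validate_phenotype_rules <- function(rules) {
  labels <- vapply(rules, `[[`, "", "label")
  prios <- vapply(rules, function(r) as.integer(r$priority), 0L)
  if (anyDuplicated(labels)) stop("phenotype labels must be unique")
  if (anyDuplicated(prios)) stop("rule priorities must be unique")
  for (r in rules) {
    if (!all(r$requires %in% c("+", "-")))
      stop("rule '", r$label, "': requirements must be '+' or '-'")
    if (!any(r$requires == "+"))
      stop("rule '", r$label, "' has no positive requirement")
  }
  structure(rules[order(prios)], class = "phenotype_rules")
}

#' Classify marker vectors into phenotypes
#'
#' First matching rule in priority order wins; no match gives
#' `"unclassified"`. `classify_phenotype()` takes one named 0/1 (or logical)
#' vector; `classify_phenotypes()` a matrix/data.frame with one column per
#' marker.
#'
#' @param markers named 0/1 or logical vector of marker positivity.
#' @param rules a [phenotype_rules()] set.
#' @return Phenotype label(s).
#' @export
classify_phenotype <- function(markers, rules = phenotype_rules()) {
  classify_phenotypes(matrix(as.integer(markers), 1L,
                             dimnames = list(NULL, names(markers))), rules)
}

#' @rdname classify_phenotype
#' @param marker_table matrix or data.frame of 0/1 marker columns.
#' @export
classify_phenotypes <- function(marker_table, rules = phenotype_rules()) {
  mt <- as.matrix(marker_table)
  storage.mode(mt) <- "integer"
  out <- rep("unclassified", nrow(mt))
  open <- rep(TRUE, nrow(mt))
  for (r in rules) {
    need <- names(r$requires)
    missing <- setdiff(need, colnames(mt))
    if (length(missing))
      stop("marker(s) required by rule '", r$label, "' not measured: ",
           paste(missing, collapse = ", "))
    want <- as.integer(r$requires == "+")
    hit <- open & rowSums(mt[, need, drop = FALSE] ==
                            matrix(want, nrow(mt), length(need),
                                   byrow = TRUE)) == length(need)
    out[hit] <- r$label
    open <- open & !hit
  }
  out
}

#' Call marker positivity on DAPI anchors by bounding-box overlap
#'
#' Every DAPI object is a cell anchor. For each marker channel, candidate
#' (anchor, object) pairs whose boxes overlap by at least the rule threshold
#' are ranked by descending overlap fraction (ties: lower anchor label, then
#' lower object id) and assigned greedily under the rule's support limit
#' (see [overlap_rule()]): a single-stain-sized blob cannot mark two nuclei,
#' while a fused blob spanning two stains may mark two. An anchor is
#' positive for a marker iff it received at least one object on that
#' channel.
#'
#' @param anchors DAPI rows of a [segment_field()] table.
#' @param marker_objects non-DAPI rows (column `channel` names the marker).
#' @param rule an [overlap_rule()].
#' @param panel allowed channels; a marker channel absent from the panel is
#'   an error.
#' @return `data.table`: one row per anchor with `cell_id`, centroid, bbox,
#'   one 0/1 column per marker channel of the panel.
#' @export
assign_markers <- function(anchors, marker_objects, rule = overlap_rule(),
                           panel = default_panel()) {
  anchors <- data.table::as.data.table(anchors)
  marker_objects <- data.table::as.data.table(marker_objects)
  mk <- marker_channels(panel)
  if (nrow(marker_objects)) {
    bad <- setdiff(unique(marker_objects$channel), panel)
    if (length(bad))
      stop("marker channel(s) not in panel [", paste(panel, collapse = ", "),
           "]: ", paste(bad, collapse = ", "))
  }
  cells <- anchors[, .(
    cell_id = label, x_um, y_um,
    bbox_min_row, bbox_min_col, bbox_max_row, bbox_max_col
  )]
  for (m in mk) data.table::set(cells, j = m, value = rep(0L, nrow(cells)))
  if (!nrow(cells)) return(cells[])

  A <- anchors[, .(
    anchor_label = label,
    start = bbox_min_row, end = bbox_max_row - 1L,
    ac1 = bbox_min_col, ac2 = bbox_max_col,
    ar1 = bbox_min_row, ar2 = bbox_max_row,
    aarea = as.numeric(bbox_max_row - bbox_min_row) *
            (bbox_max_col - bbox_min_col)
  )]
  data.table::setkey(A, start, end)
  for (m in intersect(mk, unique(marker_objects$channel))) {
    mo <- marker_objects[channel == m]
    if (!nrow(mo)) next
    # an object may support one anchor per typical-object-area it spans,
    # rounded up: a fused pair of stains (~1.2-2x the median) gets 2 slots,
    # a lone stain gets 1; higher-overlap anchors claim slots first
    capacity <- if (rule$support == "area_capacity")
      pmax(1L, as.integer(ceiling(mo$area_px / stats::median(mo$area_px))))
    else rep(1L, nrow(mo))
    B <- mo[, .(
      object_id = seq_len(.N),
      start = bbox_min_row, end = bbox_max_row - 1L,
      bc1 = bbox_min_col, bc2 = bbox_max_col,
      br1 = bbox_min_row, br2 = bbox_max_row,
      barea = as.numeric(bbox_max_row - bbox_min_row) *
              (bbox_max_col - bbox_min_col)
    )]
    ov <- data.table::foverlaps(B, A, type = "any", nomatch = NULL)
    if (!nrow(ov)) next
    ov <- ov[bc1 < ac2 & ac1 < bc2]
    if (!nrow(ov)) next
    ov[, overlap := {
      inter <- (pmin(ar2, br2) - pmax(ar1, br1)) * (pmin(ac2, bc2) - pmax(ac1, bc1))
      if (rule$denominator == "smaller_box") inter / pmin(aarea, barea)
      else inter / (aarea + barea - inter)
    }]
    ov <- ov[overlap >= rule$min_overlap_fraction]
    if (!nrow(ov)) next
    data.table::setorder(ov, -overlap, anchor_label, object_id)
    nth <- stats::ave(seq_len(nrow(ov)), ov$object_id, FUN = seq_along)
    kept <- ov[nth <= capacity[ov$object_id]]
    pos <- unique(kept$anchor_label)
    data.table::set(cells, i = match(pos, cells$cell_id), j = m, value = 1L)
  }
  cells[]
}

#' Full phenotyping of a segmented field
#'
#' Splits a [segment_field()] object table into DAPI anchors and marker
#' objects, calls marker positivity with [assign_markers()] and assigns
#' phenotypes with [classify_phenotypes()].
#'
#' @param objects object table from [segment_field()].
#' @param rules a [phenotype_rules()] set.
#' @param rule an [overlap_rule()].
#' @param panel the staining panel.
#' @return `data.table` of cell records: `field_id`, `cell_id`, `x_um`,
#'   `y_um`, marker 0/1 columns, `phenotype`.
#' @export
phenotype_cells <- function(objects, rules = phenotype_rules(),
                            rule = overlap_rule(), panel = default_panel()) {
  objects <- data.table::as.data.table(objects)
  fid <- if ("field_id" %in% names(objects) && nrow(objects))
    objects$field_id[1] else NA_integer_
  anchors <- objects[channel == "DAPI"]
  markers <- objects[channel != "DAPI"]
  cells <- assign_markers(anchors, markers, rule, panel)
  mk <- marker_channels(panel)
  cells[, phenotype := if (nrow(cells))
    classify_phenotypes(as.matrix(cells[, mk, with = FALSE]), rules)
    else character(0)]
  cells[, field_id := rep(fid, nrow(cells))]
  data.table::setcolorder(cells, "field_id")
  cells[]
}
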