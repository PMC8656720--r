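#' Bradley locally adaptive thresholding
#'
#' A pixel is foreground iff its intensity exceeds the mean intensity of the
#' `window_px x window_px` neighbourhood centred on it, scaled by
#' `1 - sensitivity`. The local mean is computed with an integral image;
#' windows at the border are clipped to the raster (clipped-window mean, not
#' padded), so the result is exactly the naive per-pixel windowed mean. The
#' ratio form makes the rule invariant to smooth multiplicative illumination
#' changes, which is why it is preferred over a global threshold for
#' fluorescence fields with lamp or optics gradients.
#'
#' @param channel 2-D numeric intensity matrix.
#' @param window_px odd window edge length, >= 3; must not exceed both image
#'   dimensions.
#' @param sensitivity fraction in `[0, 1)`; larger values accept dimmer
#'   pixels.
#' @return Logical matrix of the same shape.
#' @export
bradley_threshold <- function(channel, window_px = 41L, sensitivity = 0.15) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("window_px must be an odd integer >= 3")
  if (sensitivity < 0 || sensitivity >= 1)
    stop("sensitivity must be in [0, 1)")
  n <- nrow(channel); m <- ncol(channel)
  if (window_px > n && window_px > m)
    stop("window_px larger than both image dimensions")
  h <- (window_px - 1L) %/% 2L
  S <- matrix(0, n + 1L, m + 1L)
  S[-1L, -1L] <- t(apply(apply(channel, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(1L, seq_len(n) - h); r2 <- pmin(n, seq_len(n) + h)
  c1 <- pmax(1L, seq_len(m) - h); c2 <- pmin(m, seq_len(m) + h)
  sums <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  # intensities are non-negative, so true window sums are >= 0; the integral-
  # image difference can leave ~1e-10 cancellation residue on empty regions,
  # which would otherwise turn a zero pixel "foreground" via a negative mean
  sums <- pmax(sums, 0)
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  channel > (sums / cnt) * (1 - sensitivity)
}

#' Remove small foreground objects
#'
#' Deletes every 8-connected foreground component whose pixel count is below
#' `min_object_area`; surviving pixels are untouched. This is the artifact
#' filter applied between thresholding and instance splitting.
#'
#' @param mask logical matrix.
#' @param min_object_area minimum component area in pixels (>= 1).
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_object_area = 20L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  min_object_area <- as.integer(min_object_area)
  if (min_object_area < 1L) stop("min_object_area must be >= 1")
  if (min_object_area == 1L || !any(mask)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab)
  keep <- sizes >= min_object_area
  out <- mask
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Split touching cells by seeded watershed
#'
#' Computes the Euclidean distance transform of the mask, places seeds at its
#' local maxima (thinned so seeds within one connected component are at least
#' `min_peak_separation_um` apart; every component keeps at least its global
#' maximum), and floods the negated distance topography from the seeds. The
#' union of the output labels equals the input foreground exactly - no pixel
#' is gained or lost - and the number of labels is at least the number of
#' connected components.
#'
#' @param mask logical matrix (typically after [remove_small_objects()]).
#' @param min_peak_separation_um minimum seed separation in micrometres
#'   (default 6, one nucleus diameter minus blur).
#' @param um_per_px pixel pitch used to convert the separation to pixels.
#' @return Integer label matrix (0 = background).
#' @export
split_touching <- function(mask, min_peak_separation_um = 6, um_per_px = 0.5) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  comp <- label_components8(mask)
  dist <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  dist <- matrix(as.numeric(dist), nrow(mask), ncol(mask))
  seeds <- watershed_seeds(dist, comp, min_peak_separation_um / um_per_px)
  watershed_flood(dist, seeds, mask)
}

#' Extract per-object geometry from a label raster
#'
#' One row per surviving label: pixel area, half-open 0-based bounding box,
#' unweighted pixel-mean centroid in 0-based pixel indices and in
#' micrometres via the pixel-centre mapping `(index + 0.5) * um_per_px`.
#' Objects whose area fell below `min_object_area` after splitting are
#' dropped.
#'
#' @param labels integer label matrix from [split_touching()].
#' @param channel marker name recorded on every row.
#' @param geom a [field_geometry()].
#' @param min_object_area minimum area in pixels.
#' @return `data.table` with columns `channel`, `label`, `area_px`,
#'   `bbox_min_row`, `bbox_min_col`, `bbox_max_row`, `bbox_max_col`,
#'   `row`, `col` (0-based centroid), `x_um`, `y_um`.
#' @export
extract_objects <- function(labels, channel, geom = field_geometry(),
                            min_object_area = 20L) {
  stopifnot(is.matrix(labels))
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(data.table::data.table(
      channel = character(0), label = integer(0), area_px = integer(0),
      bbox_min_row = integer(0), bbox_min_col = integer(0),
      bbox_max_row = integer(0), bbox_max_col = integer(0),
      row = numeric(0), col = numeric(0), x_um = numeric(0), y_um = numeric(0)
    ))
  }
  nr <- nrow(labels)
  dt <- data.table::data.table(
    label = labels[idx],
    row0 = (idx - 1L) %% nr,          # 0-based row index
    col0 = (idx - 1L) %/% nr          # 0-based col index
  )
  upp <- geom$um_per_px
  out <- dt[, .(
    area_px = .N,
    bbox_min_row = min(row0), bbox_min_col = min(col0),
    bbox_max_row = max(row0) + 1L, bbox_max_col = max(col0) + 1L,
    row = mean(row0), col = mean(col0)
  ), by = label][area_px >= min_object_area]
  out[, `:=`(channel = rep(channel, .N),
             x_um = (col + 0.5) * upp,
             y_um = (row + 0.5) * upp)]
  data.table::setcolorder(out, c("channel", "label", "area_px",
                                 "bbox_min_row", "bbox_min_col",
                                 "bbox_max_row", "bbox_max_col",
                                 "row", "col", "x_um", "y_um"))
  out[]
}

#' Segmentation parameters
#'
#' Defaults: 41 px window (~20 um, about 2.5 nucleus diameters), sensitivity
#' 0.15, minimum object area 20 px, 6 um seed separation.
#'
#' @param window_px,sensitivity see [bradley_threshold()].
#' @param min_object_area see [remove_small_objects()].
#' @param min_peak_separation_um see [split_touching()].
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(window_px = 41L, sensitivity = 0.15,
                       min_object_area = 20L, min_peak_separation_um = 6) {
  structure(list(
    window_px = as.integer(window_px), sensitivity = sensitivity,
    min_object_area = as.integer(min_object_area),
    min_peak_separation_um = min_peak_separation_um
  ), class = "seg_params")
}

#' Segment one channel / one whole field
#'
#' `segment_channel()` chains threshold, artifact removal, watershed
#' splitting and object extraction for a single intensity raster;
#' `segment_field()` applies it to every channel of a field image and binds
#' the object tables.
#'
#' @param img numeric matrix (one channel).
#' @param channel channel name.
#' @param geom a [field_geometry()].
#' @param params a [seg_params()].
#' @return `data.table` of segmented objects (see [extract_objects()]).
#' @export
segment_channel <- function(img, channel, geom = field_geometry(),
                            params = seg_params()) {
  mask <- bradley_threshold(img, params$window_px, params$sensitivity)
  mask <- remove_small_objects(mask, params$min_object_area)
  labels <- split_touching(mask, params$min_peak_separation_um, geom$um_per_px)
  extract_objects(labels, channel, geom, params$min_object_area)
}

#' @rdname segment_channel
#' @param image named list of channel matrices.
#' @param field_id identifier recorded on every row.
#' @param channels channels to segment (default: all in `image`).
#' @export
segment_field <- function(image, geom = field_geometry(),
                          params = seg_params(), field_id = 1L,
                          channels = names(image)) {
  objs <- data.table::rbindlist(lapply(channels, function(ch) {
    segment_channel(image[[ch]], ch, geom, params)
  }))
  if (nrow(objs)) objs[, field_id := rep(field_id, .N)]
  else objs[, field_id := integer(0)]
  data.table::setcolorder(objs, "field_id")
  objs[]
}
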