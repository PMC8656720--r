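#' Field geometry
#'
#' Physical description of one imaged region of interest: raster size in
#' pixels and the pixel pitch in micrometres. The default emulates a single
#' 20x multispectral region scanned at 0.5 um/px: 1200 x 1200 px = 600 x 600
#' um = 0.36 mm^2.
#'
#' Coordinate conventions used throughout the package: rasters are row-major
#' with 0-based pixel indices, bounding boxes are half-open
#' `(min_row, min_col, max_row, max_col)`, and the micrometre position of a
#' pixel is its centre, `(col + 0.5) * um_per_px` (likewise for rows).
#'
#' @param width_px,height_px raster size in pixels (>= 64).
#' @param um_per_px physical pixel pitch in micrometres (> 0).
#' @return An object of class `field_geometry`.
#' @export
field_geometry <- function(width_px = 1200L, height_px = 1200L,
                           um_per_px = 0.5) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 64L || height_px < 64L)
    stop("field dimensions must be at least 64 px")
  if (!is.finite(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be > 0")
  structure(
    list(width_px = width_px, height_px = height_px, um_per_px = um_per_px),
    class = "field_geometry"
  )
}

#' Field dimensions in micrometres and area in mm^2
#' @param geom a [field_geometry()].
#' @return `field_width_um`/`field_height_um`: micrometres;
#'   `field_area_mm2`: square millimetres.
#' @export
field_width_um <- function(geom) geom$width_px * geom$um_per_px

#' @rdname field_width_um
#' @export
field_height_um <- function(geom) geom$height_px * geom$um_per_px

#' @rdname field_width_um
#' @export
field_area_mm2 <- function(geom) {
  geom$width_px * geom$height_px * (geom$um_per_px / 1000)^2
}

#' Evaluate code with a fixed, restored RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulation helpers do not disturb the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
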