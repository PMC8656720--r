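#' Plant ground-truth cell positions for one synthetic field
#'
#' Malignant CD3+CD4+TOX+ cells are placed as a clustered process (Gaussian
#' scatter around uniformly drawn focus centres); the infiltrate phenotypes
#' are then placed uniformly *inside* the union of `vicinity_radius_um` disks
#' around the malignant cells until each phenotype reaches exactly
#' `ceiling(target_density * vicinity_area_mm2)` cells, which makes the
#' planted vicinity density equal to the preset target up to the rounding of
#' a single cell. A configurable out-of-vicinity background (default 20% of
#' the in-vicinity density) is placed uniformly in the remainder of the
#' field.
#'
#' A minimum centre-to-centre spacing is honoured by rejection sampling,
#' except for a configured fraction of placements deliberately planted at
#' touching distance from an existing same-phenotype cell (these exercise
#' watershed splitting downstream). If a placement cannot be realised the
#' target density is geometrically infeasible at the configured spacing and
#' an error naming the phenotype is raised.
#'
#' @param preset a [stage_preset()].
#' @param geom a [field_geometry()].
#' @param rng_seed integer seed; the same seed reproduces the table exactly.
#' @param vicinity_radius_um vicinity radius (default 75 um).
#' @param nucleus_radius_um,stain_radius_um rendered radii recorded per cell.
#' @return A `data.table` with columns `x_um`, `y_um`, `phenotype`, one 0/1
#'   column per marker channel, `nucleus_radius_um`, `stain_radius_um`, and
#'   attributes `vicinity_area_mm2` (area of the planted malignant vicinity)
#'   and `touching` (logical vector marking deliberately touching placements).
#' @export
sample_cell_positions <- function(preset, geom = field_geometry(), rng_seed,
                                  vicinity_radius_um = 75,
                                  nucleus_radius_um = 4,
                                  stain_radius_um = 6) {
  stopifnot(inherits(preset, "stage_preset"), inherits(geom, "field_geometry"))
  profiles <- phenotype_marker_profiles()
  W <- field_width_um(geom); H <- field_height_um(geom)
  min_sp2 <- preset$min_spacing_um^2
  max_attempts <- 2000L

  res <- with_seed(rng_seed, {
    xs <- numeric(0); ys <- numeric(0)
    phen <- character(0); touch <- logical(0)

    ok_spacing <- function(x, y) {
      length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_sp2
    }

    place_cells <- function(n, ph, propose, region_ok) {
      placed <- 0L
      while (placed < n) {
        x <- NA_real_; y <- NA_real_; is_touch <- FALSE; done <- FALSE
        same <- which(phen == ph)
        if (length(same) > 0L && runif(1) < preset$touching_fraction) {
          for (a in 1:50) {
            j <- same[sample.int(length(same), 1L)]
            th <- runif(1, 0, 2 * pi)
            px <- xs[j] + preset$touch_distance_um * cos(th)
            py <- ys[j] + preset$touch_distance_um * sin(th)
            if (px >= 0 && px < W && py >= 0 && py < H && region_ok(px, py)) {
              x <- px; y <- py; is_touch <- TRUE; done <- TRUE; break
            }
          }
        }
        if (!done) {
          for (a in seq_len(max_attempts)) {
            p <- propose()
            if (p[1] >= 0 && p[1] < W && p[2] >= 0 && p[2] < H &&
                region_ok(p[1], p[2]) && ok_spacing(p[1], p[2])) {
              x <- p[1]; y <- p[2]; done <- TRUE; break
            }
          }
          if (!done)
            stop("target density geometrically infeasible at minimum spacing ",
                 preset$min_spacing_um, " um for phenotype '", ph, "'")
        }
        xs <<- c(xs, x); ys <<- c(ys, y)
        phen <<- c(phen, ph); touch <<- c(touch, is_touch)
        placed <- placed + 1L
      }
    }

    # --- malignant cells: clustered around foci -------------------------
    n_mal <- preset$malignant_intensity
    if (n_mal > 0L) {
      mx <- min(preset$cluster_sd_um, W / 4); my <- min(preset$cluster_sd_um, H / 4)
      fx <- runif(preset$n_foci, mx, W - mx)
      fy <- runif(preset$n_foci, my, H - my)
      propose_mal <- function() {
        k <- sample.int(preset$n_foci, 1L)
        c(fx[k] + rnorm(1, 0, preset$cluster_sd_um),
          fy[k] + rnorm(1, 0, preset$cluster_sd_um))
      }
      place_cells(n_mal, "malignant", propose_mal, function(x, y) TRUE)
    }
    mal_x <- xs[phen == "malignant"]; mal_y <- ys[phen == "malignant"]

    # --- vicinity geometry ---------------------------------------------
    vic_area <- vicinity_area(
      data.frame(x_um = mal_x, y_um = mal_y),
      vicinity_params(radius_um = vicinity_radius_um), geom
    )
    out_area <- field_area_mm2(geom) - vic_area
    r2 <- vicinity_radius_um^2
    in_vic <- function(x, y) {
      length(mal_x) > 0L && min((mal_x - x)^2 + (mal_y - y)^2) <= r2
    }
    propose_unif <- function() c(runif(1, 0, W), runif(1, 0, H))

    # --- infiltrate: exact counts inside the vicinity, background outside.
    # Each compartment is planted with a single ceiling() so its in-vicinity
    # density is exact to one cell; the CD4 compartment is then split into
    # exhausted/effector by the rounded BTLA+ fraction.
    f <- preset$exhausted_fraction
    comp_specs <- list(
      cd4 = c(exhausted = f, cd4_effector = 1 - f),
      cd8 = c(cd8_t = 1),
      nk = c(nk = 1)
    )
    split_counts <- function(n_tot, split) {
      if (length(split) == 1L) return(setNames(n_tot, names(split)))
      n1 <- as.integer(round(split[[1L]] * n_tot))
      setNames(c(n1, n_tot - n1), names(split))
    }
    for (comp in names(comp_specs)) {
      target <- if (comp %in% names(preset$compartment_targets))
        preset$compartment_targets[[comp]] else 0
      if (target <= 0) next
      split <- comp_specs[[comp]]
      if (vic_area > 0) {
        ns <- split_counts(as.integer(ceiling(target * vic_area)), split)
        for (ph in names(ns))
          if (ns[[ph]] > 0L) place_cells(ns[[ph]], ph, propose_unif, in_vic)
      }
      n_out <- as.integer(round(preset$background_fraction * target * out_area))
      if (n_out > 0L) {
        ns <- split_counts(n_out, split)
        for (ph in names(ns))
          if (ns[[ph]] > 0L)
            place_cells(ns[[ph]], ph, propose_unif, function(x, y) !in_vic(x, y))
      }
    }

    list(xs = xs, ys = ys, phen = phen, touch = touch, vic_area = vic_area)
  })

  mk <- marker_channels()
  markers <- do.call(rbind, lapply(res$phen, function(p) profiles[[p]][mk]))
  if (is.null(markers)) markers <- matrix(integer(0), 0L, length(mk),
                                          dimnames = list(NULL, mk))
  out <- data.table::data.table(
    x_um = res$xs, y_um = res$ys, phenotype = res$phen
  )
  for (m in mk)
    data.table::set(out, j = m,
                    value = if (nrow(out)) as.integer(markers[, m]) else integer(0))
  data.table::set(out, j = "nucleus_radius_um",
                  value = rep(nucleus_radius_um, nrow(out)))
  data.table::set(out, j = "stain_radius_um",
                  value = rep(stain_radius_um, nrow(out)))
  data.table::setattr(out, "vicinity_area_mm2", res$vic_area)
  data.table::setattr(out, "touching", res$touch)
  out[]
}

#' Render a planted cell table into a multichannel field image
#'
#' Each channel is built as: uniform background, plus amplitude disks
#' (`cell_peak_level - background_level`, scaled per cell and channel by the
#' staining-heterogeneity factor `U[1 - peak_jitter, 1]`) at the planted
#' centres - nucleus disks for DAPI, stain disks for every cell positive for
#' that marker - blurred by the Gaussian PSF, multiplied by the illumination
#' ramp, plus additive Gaussian shot noise (per-pixel SD
#' `noise_sd * sqrt(I)`), clipped to `[0, 1]`.
#'
#' @param cells truth table from [sample_cell_positions()] (any data.frame
#'   with `x_um`, `y_um` and one 0/1 column per marker works).
#' @param geom a [field_geometry()].
#' @param params a [render_params()].
#' @param rng_seed seed for the noise draw.
#' @param panel channel order; must contain `DAPI` and every marker column of
#'   `cells` (an unknown marker raises an error listing the panel).
#' @return Named list of `height_px x width_px` matrices, one per channel, in
#'   panel order.
#' @export
render_field <- function(cells, geom = field_geometry(),
                         params = render_params(), rng_seed = 1L,
                         panel = default_panel()) {
  stopifnot(inherits(geom, "field_geometry"), inherits(params, "render_params"))
  meta <- c("field_id", "x_um", "y_um", "phenotype",
            "nucleus_radius_um", "stain_radius_um")
  marker_cols <- setdiff(names(cells), meta)
  unknown <- setdiff(marker_cols, panel)
  if (length(unknown))
    stop("marker(s) not in panel [", paste(panel, collapse = ", "), "]: ",
         paste(unknown, collapse = ", "))
  if (!"DAPI" %in% panel) stop("panel must contain DAPI")
  n <- nrow(cells)
  if (n > 0L) {
    if (any(cells$x_um < 0 | cells$x_um >= field_width_um(geom) |
            cells$y_um < 0 | cells$y_um >= field_height_um(geom)))
      stop("cell centroids must lie within the field")
  }
  h <- geom$height_px; w <- geom$width_px; upp <- geom$um_per_px
  amp <- params$cell_peak_level - params$background_level
  sigma_px <- params$psf_sigma_um / upp
  nuc_r <- if (n && "nucleus_radius_um" %in% names(cells))
    cells$nucleus_radius_um[1] else params$nucleus_radius_um
  stn_r <- if (n && "stain_radius_um" %in% names(cells))
    cells$stain_radius_um[1] else params$stain_radius_um

  grad <- if (params$illumination_gradient_amplitude > 0)
    1 + params$illumination_gradient_amplitude * ((seq_len(w) - 0.5) / w - 0.5)
  else NULL

  with_seed(rng_seed, {
    out <- vector("list", length(panel)); names(out) <- panel
    for (ch in panel) {
      if (ch == "DAPI") {
        sel <- seq_len(n)
        radius <- nuc_r
      } else {
        sel <- if (ch %in% marker_cols) which(cells[[ch]] == 1L) else integer(0)
        radius <- stn_r
      }
      canvas <- matrix(0, h, w)
      if (length(sel)) {
        fac <- if (params$peak_jitter > 0)
          runif(length(sel), 1 - params$peak_jitter, 1) else rep(1, length(sel))
        canvas <- splat_disks(h, w, upp, cells$x_um[sel], cells$y_um[sel],
                              radius, amp * fac)
        if (sigma_px > 0) {
          brush <- EBImage::makeBrush(2L * as.integer(ceiling(3 * sigma_px)) + 1L,
                                      "Gaussian", sigma = sigma_px)
          # zero-padded convolution: no wrap-around of disk tails across
          # field edges (FFT-circular boundaries would plant faint ghosts)
          canvas <- EBImage::filter2(canvas, brush, boundary = 0)
          # clamp numerical dust below a 16-bit quantization step
          canvas[canvas < 2^-16] <- 0
        }
      }
      img <- params$background_level + canvas
      if (!is.null(grad)) img <- sweep(img, 2L, grad, "*")
      if (params$noise_sd > 0)
        img <- img + rnorm(h * w) * params$noise_sd * sqrt(pmax(img, 0))
      out[[ch]] <- pmin(pmax(img, 0), 1)
    }
    out
  })
}

#' Simulate one complete field (truth table + rendered image)
#'
#' @inheritParams sample_cell_positions
#' @inheritParams render_field
#' @param seed integer seed used for both placement and rendering noise.
#' @return `list(truth = data.table, image = named list of matrices)`.
#' @export
simulate_field <- function(preset, seed, geom = field_geometry(),
                           params = render_params(), panel = default_panel()) {
  truth <- sample_cell_positions(preset, geom, rng_seed = seed,
                                 nucleus_radius_um = params$nucleus_radius_um,
                                 stain_radius_um = params$stain_radius_um)
  image <- render_field(truth, geom, params, rng_seed = seed, panel = panel)
  list(truth = truth, image = image)
}

truth_csv_columns <- function(truth, field_id) {
  cols <- c("x_um", "y_um", "phenotype", marker_channels())
  out <- data.table::as.data.table(truth)[, cols, with = FALSE]
  data.table::setcolorder(
    cbind(data.table::data.table(field_id = rep(field_id, nrow(out))), out),
    c("field_id", cols)
  )
}

#' Write a simulated dataset to disk
#'
#' One multi-page 32-bit float TIFF (page order = panel order) and one truth
#' CSV per field, plus a JSON manifest recording the preset, geometry,
#' rendering parameters, panel and per-field seeds - enough to regenerate the
#' dataset bit-identically with [regenerate_dataset()].
#'
#' @param images list of field images (each a named list of channel matrices).
#' @param truths list of truth tables, same length as `images`.
#' @param out_dir output directory; an existing non-empty directory is
#'   refused unless `overwrite = TRUE`.
#' @param preset the [stage_preset()] used.
#' @param seeds integer vector of per-field seeds.
#' @param geom,params,panel generation parameters to record.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest (invisibly), also written to `manifest.json`.
#' @export
write_dataset <- function(images, truths, out_dir, preset, seeds,
                          geom = field_geometry(), params = render_params(),
                          panel = default_panel(), overwrite = FALSE) {
  stopifnot(length(images) == length(truths), length(seeds) == length(images))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("refusing to write into non-empty directory '", out_dir,
         "' (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(images)
  img_files <- sprintf("field_%03d.tiff", seq_len(n))
  csv_files <- sprintf("field_%03d.csv", seq_len(n))
  for (i in seq_len(n)) {
    tiff::writeTIFF(unname(images[[i]][panel]),
                    file.path(out_dir, img_files[i]), bits.per.sample = 32L)
    utils::write.csv(truth_csv_columns(truths[[i]], i),
                     file.path(out_dir, csv_files[i]), row.names = FALSE)
  }
  pl <- unclass(preset)
  # named numeric vectors serialize as nameless JSON arrays; store the
  # targets as named lists so the manifest round-trips
  pl$compartment_targets <- as.list(pl$compartment_targets)
  pl$vicinity_density_targets <- NULL  # derived; rebuilt by stage_preset()
  manifest <- list(
    preset = pl,
    seeds = as.integer(seeds),
    geometry = unclass(geom),
    render = unclass(params),
    panel = panel,
    files = list(images = img_files, truths = csv_files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate and write a multi-field dataset for one preset
#'
#' @inheritParams write_dataset
#' @param n_fields number of fields.
#' @param base_seed fields use seeds `base_seed + 0:(n_fields - 1)`.
#' @return The manifest (invisibly).
#' @export
generate_dataset <- function(preset, n_fields, base_seed, out_dir,
                             geom = field_geometry(), params = render_params(),
                             panel = default_panel(), overwrite = FALSE) {
  seeds <- as.integer(base_seed) + seq_len(n_fields) - 1L
  sims <- lapply(seeds, function(s) simulate_field(preset, s, geom, params, panel))
  write_dataset(lapply(sims, `[[`, "image"), lapply(sims, `[[`, "truth"),
                out_dir, preset, seeds, geom, params, panel, overwrite)
}

preset_from_list <- function(x) {
  stage_preset(
    name = x$name,
    malignant_intensity = x$malignant_intensity,
    compartment_targets = unlist(x$compartment_targets),
    exhausted_fraction = x$exhausted_fraction,
    cluster_sd_um = x$cluster_sd_um,
    n_foci = x$n_foci,
    background_fraction = x$background_fraction,
    min_spacing_um = x$min_spacing_um,
    touching_fraction = x$touching_fraction,
    touch_distance_um = x$touch_distance_um
  )
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest_file path to a `manifest.json` written by [write_dataset()].
#' @param out_dir destination directory.
#' @param overwrite passed to [write_dataset()].
#' @return The regenerated manifest (invisibly).
#' @export
regenerate_dataset <- function(manifest_file, out_dir, overwrite = FALSE) {
  m <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  preset <- preset_from_list(as.list(m$preset))
  geom <- field_geometry(m$geometry$width_px, m$geometry$height_px,
                         m$geometry$um_per_px)
  rp <- as.list(m$render)
  params <- do.call(render_params, rp)
  sims <- lapply(m$seeds, function(s) simulate_field(preset, s, geom, params, m$panel))
  write_dataset(lapply(sims, `[[`, "image"), lapply(sims, `[[`, "truth"),
                out_dir, preset, m$seeds, geom, params, m$panel, overwrite)
}

#' Read a multi-page field TIFF back as a named channel list
#'
#' @param path TIFF file as written by [write_dataset()].
#' @param panel channel names, in page order.
#' @return Named list of matrices.
#' @export
read_field_image <- function(path, panel = default_panel()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(panel))
    stop("TIFF has ", length(pages), " pages but panel has ", length(panel))
  names(pages) <- panel
  pages
}

#' @rdname read_field_image
#' @export
read_truth_csv <- function(path) data.table::fread(path)
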