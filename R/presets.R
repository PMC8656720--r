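#' Stage and response presets for the synthetic-field generator
#'
#' A preset fixes the planted spatial composition of one disease condition:
#' the number of malignant CD3+CD4+TOX+ cells per field, the target infiltrate
#' densities (cells/mm^2) inside the 75 um malignant vicinity for the
#' CD3+CD4+TOX- (CD4) compartment, CD8+ T cells and NK cells, and the fraction
#' of the CD4 compartment that carries BTLA (the exhausted subpopulation).
#'
#' The CD4 compartment target is split into per-phenotype targets
#' `exhausted = f * cd4` and `cd4_effector = (1 - f) * cd4`, so that the
#' planted density of each phenotype label is exact by construction and their
#' sum - the CD3+CD4+TOX- readout of stage comparisons - equals the
#' compartment target.
#'
#' Packaged presets (see [stage_presets()]):
#' * `plaque`: vicinity targets cd4 269, cd8 57, nk 255 cells/mm^2; 120
#'   malignant cells/field; exhausted fraction 0.15.
#' * `tumor`: cd4 453, cd8 85, nk 354 cells/mm^2; 300 malignant cells/field;
#'   exhausted fraction 0.30.
#' * `responder_baseline`: 958 malignant cells/field, tumor-stage infiltrate,
#'   exhausted fraction 0.30.
#' * `responder_eot`: 453 malignant cells/field (end of treatment), cd4 453
#'   with exhausted fraction 0.10, raised cytotoxic infiltrate (cd8 120,
#'   nk 480) reflecting the NK/CD8 influx that accompanies response.
#'
#' @param name preset identifier.
#' @param malignant_intensity planted malignant-cell count per field.
#' @param compartment_targets named numeric, cells/mm^2 inside the vicinity,
#'   names `cd4`, `cd8`, `nk` (any subset; all >= 0).
#' @param exhausted_fraction fraction of CD4-compartment placements rendered
#'   BTLA+ and labelled `exhausted`, in `[0, 1]`.
#' @param cluster_sd_um dispersion (SD, um) of malignant cells around their
#'   focus centres.
#' @param n_foci number of malignant foci; default `max(1, round(n/150))`.
#' @param background_fraction out-of-vicinity infiltrate density as a
#'   fraction of the in-vicinity target (default 0.2).
#' @param min_spacing_um minimum centre-to-centre spacing honoured by the
#'   placement process (default 9 um, just above one nucleus diameter).
#' @param touching_fraction fraction of placements deliberately planted at
#'   `touch_distance_um` from an existing cell to exercise instance
#'   splitting (default 0.05).
#' @param touch_distance_um centre distance of deliberately touching pairs
#'   (default 6 um; two such nuclei merge into one foreground component).
#' @return An object of class `stage_preset`.
#' @export
stage_preset <- function(name,
                         malignant_intensity,
                         compartment_targets = c(cd4 = 0, cd8 = 0, nk = 0),
                         exhausted_fraction = 0,
                         cluster_sd_um = 120,
                         n_foci = NULL,
                         background_fraction = 0.2,
                         min_spacing_um = 9,
                         touching_fraction = 0.05,
                         touch_distance_um = 6) {
  stopifnot(is.character(name), length(name) == 1L)
  malignant_intensity <- as.integer(malignant_intensity)
  if (malignant_intensity < 0L) stop("malignant_intensity must be >= 0")
  if (any(compartment_targets < 0)) stop("densities must be >= 0")
  bad <- setdiff(names(compartment_targets), c("cd4", "cd8", "nk"))
  if (length(bad))
    stop("unknown compartment target(s): ", paste(bad, collapse = ", "))
  if (exhausted_fraction < 0 || exhausted_fraction > 1)
    stop("exhausted_fraction must be in [0, 1]")
  if (is.null(n_foci)) n_foci <- max(1L, as.integer(round(malignant_intensity / 150)))

  cd4 <- if ("cd4" %in% names(compartment_targets)) compartment_targets[["cd4"]] else 0
  targets <- c(
    exhausted    = cd4 * exhausted_fraction,
    cd4_effector = cd4 * (1 - exhausted_fraction),
    cd8_t        = if ("cd8" %in% names(compartment_targets)) compartment_targets[["cd8"]] else 0,
    nk           = if ("nk" %in% names(compartment_targets)) compartment_targets[["nk"]] else 0
  )
  known <- names(phenotype_marker_profiles())
  stopifnot(all(names(targets) %in% known))

  structure(list(
    name = name,
    malignant_intensity = malignant_intensity,
    compartment_targets = compartment_targets,
    exhausted_fraction = exhausted_fraction,
    vicinity_density_targets = targets,
    cluster_sd_um = cluster_sd_um,
    n_foci = as.integer(n_foci),
    background_fraction = background_fraction,
    min_spacing_um = min_spacing_um,
    touching_fraction = touching_fraction,
    touch_distance_um = touch_distance_um
  ), class = "stage_preset")
}

#' @rdname stage_preset
#' @export
stage_presets <- function() {
  list(
    plaque = stage_preset(
      "plaque", malignant_intensity = 120,
      compartment_targets = c(cd4 = 269, cd8 = 57, nk = 255),
      exhausted_fraction = 0.15
    ),
    tumor = stage_preset(
      "tumor", malignant_intensity = 300,
      compartment_targets = c(cd4 = 453, cd8 = 85, nk = 354),
      exhausted_fraction = 0.30
    ),
    responder_baseline = stage_preset(
      "responder_baseline", malignant_intensity = 958,
      compartment_targets = c(cd4 = 453, cd8 = 85, nk = 354),
      exhausted_fraction = 0.30
    ),
    responder_eot = stage_preset(
      "responder_eot", malignant_intensity = 453,
      compartment_targets = c(cd4 = 453, cd8 = 120, nk = 480),
      exhausted_fraction = 0.10
    )
  )
}

#' Rendering parameters for synthetic channels
#'
#' Intensities are on a normalized `[0, 1]` scale. Every nucleus renders a
#' disk of radius `nucleus_radius_um` on the DAPI page; every positive marker
#' renders a disk of radius `stain_radius_um` on that marker's page; disks
#' are blurred by a Gaussian point-spread function, multiplied by a linear
#' illumination ramp along x of fractional amplitude
#' `illumination_gradient_amplitude` (factor `1 - A/2` at the left edge to
#' `1 + A/2` at the right), and corrupted by additive Gaussian shot noise
#' whose SD scales with the square root of the local signal
#' (`noise_sd * sqrt(I)`, the Gaussian approximation to Poisson photon
#' noise; a zero-signal pixel is noise-free).
#'
#' The default background is 0, as in a spectrally unmixed fluorescence
#' channel. This matters for thresholding: the local-mean rule
#' `I > mean * (1 - s)` classifies *any* flat strictly positive region
#' entirely as foreground (the pixel always exceeds the discounted mean of
#' its flat surroundings), so a nonzero `background_level` is only useful
#' for constructing adversarial inputs.
#'
#' Staining intensity varies strongly between cells in real multiplexed
#' immunofluorescence; `peak_jitter` emulates this by scaling each cell's
#' disk on each channel by an independent factor drawn uniformly from
#' `[1 - peak_jitter, 1]`. This heterogeneity is what makes a global
#' threshold fragile under illumination gradients (dim cells on the dim side
#' of the ramp drop below a single global cut) while the ratio-based local
#' rule is unaffected.
#'
#' @param background_level,cell_peak_level normalized intensities in `[0, 1]`.
#' @param noise_sd full-scale shot-noise SD (>= 0); per-pixel SD is
#'   `noise_sd * sqrt(I)`.
#' @param peak_jitter per-cell-per-channel brightness heterogeneity in
#'   `[0, 1)`; 0 renders every cell at full `cell_peak_level`.
#' @param illumination_gradient_amplitude fractional ramp amplitude in `[0, 1)`.
#' @param psf_sigma_um Gaussian blur SD in micrometres.
#' @param nucleus_radius_um,stain_radius_um rendered disk radii in micrometres.
#' @return An object of class `render_params`.
#' @export
render_params <- function(background_level = 0,
                          cell_peak_level = 0.9,
                          noise_sd = 0.02,
                          illumination_gradient_amplitude = 0.1,
                          psf_sigma_um = 1,
                          peak_jitter = 0.7,
                          nucleus_radius_um = 4,
                          stain_radius_um = 6) {
  stopifnot(
    background_level >= 0, background_level <= 1,
    cell_peak_level >= 0, cell_peak_level <= 1,
    noise_sd >= 0,
    illumination_gradient_amplitude >= 0, illumination_gradient_amplitude < 1,
    psf_sigma_um >= 0, peak_jitter >= 0, peak_jitter < 1,
    nucleus_radius_um > 0, stain_radius_um > 0
  )
  structure(list(
    background_level = background_level,
    cell_peak_level = cell_peak_level,
    noise_sd = noise_sd,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    psf_sigma_um = psf_sigma_um,
    peak_jitter = peak_jitter,
    nucleus_radius_um = nucleus_radius_um,
    stain_radius_um = stain_radius_um
  ), class = "render_params")
}
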