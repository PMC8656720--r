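#' Default staining panel
#'
#' The eight-channel panel used throughout: seven lineage/functional markers
#' plus the DAPI nuclear counterstain. Channel order here is the page order
#' of rendered multi-page TIFFs.
#'
#' @return Character vector of channel names.
#' @export
default_panel <- function() {
  c("CD3", "CD4", "CD8", "CD56", "GZMB", "TOX", "BTLA", "DAPI")
}

#' @rdname default_panel
#' @export
marker_channels <- function(panel = default_panel()) setdiff(panel, "DAPI")

# Ground-truth marker profile (0/1 over the marker channels) for each planted
# phenotype. Granzyme B is carried on the cytotoxic lineages but is used by
# no classification rule; it exists to exercise a measured-but-unused channel.
phenotype_marker_profiles <- function() {
  list(
    malignant    = c(CD3 = 1L, CD4 = 1L, CD8 = 0L, CD56 = 0L, GZMB = 0L, TOX = 1L, BTLA = 0L),
    exhausted    = c(CD3 = 1L, CD4 = 1L, CD8 = 0L, CD56 = 0L, GZMB = 0L, TOX = 0L, BTLA = 1L),
    cd4_effector = c(CD3 = 1L, CD4 = 1L, CD8 = 0L, CD56 = 0L, GZMB = 0L, TOX = 0L, BTLA = 0L),
    cd8_t        = c(CD3 = 1L, CD4 = 0L, CD8 = 1L, CD56 = 0L, GZMB = 1L, TOX = 0L, BTLA = 0L),
    nk           = c(CD3 = 0L, CD4 = 0L, CD8 = 0L, CD56 = 1L, GZMB = 1L, TOX = 0L, BTLA = 0L)
  )
}
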