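#' Detection parameters for the asymmetry and P-I pipelines
#'
#' Defaults are the published operating point of the method: 10 mm FWHM
#' smoothing, stroke mask at 30 percent of the whole-brain maximum, global
#' mean normalization to 100, primary threshold 2.0 SD with a 1.5 SD
#' fallback, cluster extent threshold 125 voxels (1 mL at 2 mm isotropic),
#' and a 5 cm maximum lesion distance.
#'
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM in mm.
#' @param stroke_mask_fraction Fraction of the whole-brain maximum below
#'   which a voxel joins the stroke mask (strictly between 0 and 1).
#' @param norm_target Target global mean after count normalization.
#' @param z_primary Primary detection threshold in SD units.
#' @param z_fallback Fallback threshold in SD units (must be below
#'   `z_primary`).
#' @param cluster_extent_min_vox Minimum surviving cluster extent in voxels.
#' @param max_lesion_distance_mm Maximum cluster-to-lesion distance in mm.
#' @param connectivity Cluster connectivity: 6, 18 or 26.
#' @return An object of class `asym_params`.
#' @export
asym_params <- function(smoothing_fwhm_mm = 10,
                        stroke_mask_fraction = 0.30,
                        norm_target = 100,
                        z_primary = 2.0,
                        z_fallback = 1.5,
                        cluster_extent_min_vox = 125L,
                        max_lesion_distance_mm = 50,
                        connectivity = 26L) {
  if (!(stroke_mask_fraction > 0 && stroke_mask_fraction < 1))
    stop("`stroke_mask_fraction` must lie strictly between 0 and 1",
         call. = FALSE)
  if (!(z_fallback < z_primary))
    stop("`z_fallback` must be below `z_primary`", call. = FALSE)
  if (cluster_extent_min_vox < 1)
    stop("`cluster_extent_min_vox` must be at least 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (smoothing_fwhm_mm <= 0)
    stop("`smoothing_fwhm_mm` must be positive", call. = FALSE)
  structure(list(smoothing_fwhm_mm = smoothing_fwhm_mm,
                 stroke_mask_fraction = stroke_mask_fraction,
                 norm_target = norm_target,
                 z_primary = z_primary,
                 z_fallback = z_fallback,
                 cluster_extent_min_vox = as.integer(cluster_extent_min_vox),
                 max_lesion_distance_mm = max_lesion_distance_mm,
                 connectivity = as.integer(connectivity)),
            class = "asym_params")
}

#' @export
print.asym_params <- function(x, ...) {
  cat("<asym_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# round half away from zero (printed-percent convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
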