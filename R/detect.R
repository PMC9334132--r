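# The two detection pipelines: mirror asymmetry and P-I subtraction.

#' Mirror-asymmetry z-map of a standardized postictal SPECT
#'
#' Runs the image-processing chain of the asymmetry method up to the z-map:
#' smooth (FWHM in `params`), stroke mask at the configured fraction of the
#' whole-brain maximum (or the supplied lesion hint), global-mean
#' normalization over brain-minus-stroke, subtraction of the mirrored image,
#' and z-standardization over brain minus the union of the stroke mask and
#' its mirror. Because the template brain mask is symmetric, normalizing the
#' mirrored image over the mirrored stroke mask yields the same scale factor
#' as the forward image, so a single normalization is applied and the
#' difference map is exactly antisymmetric.
#'
#' @param postictal_std Standardized postictal SPECT [volume()] on the
#'   template grid.
#' @param template A [make_template()] object.
#' @param params An [asym_params()] object.
#' @param lesion_hint Optional logical lesion mask overriding the automatic
#'   stroke mask.
#' @return A list with `z` (a [zscore_map()]), `stroke` (the stroke mask),
#'   `stroke_union` (stroke or mirrored stroke), `smoothed`, `normalized`,
#'   `diff` volumes.
#' @export
asymmetry_zmap <- function(postictal_std, template, params = asym_params(),
                           lesion_hint = NULL) {
  stopifnot(inherits(template, "perf_template"))
  if (!grids_equal(postictal_std, template))
    stop("contract error: postictal volume is not on the template grid",
         call. = FALSE)
  sm <- gaussian_smooth(postictal_std, params$smoothing_fwhm_mm)
  brain <- template$brain_mask
  stroke <- if (is.null(lesion_hint))
    compute_stroke_mask(sm, brain, params$stroke_mask_fraction)
  else (lesion_hint & brain)
  include_norm <- brain & !stroke
  norm <- normalize_global_mean(sm, include_norm, params$norm_target)
  mirror <- flip_lr(norm, template)
  diffv <- volume(norm$data - mirror$data, norm$spacing, norm$origin)
  stroke_union <- stroke | flip_lr_array(stroke)
  include_z <- brain & !stroke_union
  z <- zscore_map(diffv, include_z, mid_index = template$mid_index)
  list(z = z, stroke = stroke, stroke_union = stroke_union,
       smoothed = sm, normalized = norm, diff = diffv)
}

finalize_detection <- function(clusters, template, method, sd_level, params,
                               stroke, zmap, extra = list()) {
  positive <- nrow(clusters) > 0L
  laterality <- "none"
  max_region <- NA_character_
  if (positive) {
    clusters <- localize_clusters(clusters, template)
    ord <- order(-clusters$peak_z, -clusters$extent_vox,
                 clusters$hemisphere != "left")
    clusters <- subset_cluster_set(clusters, ord)
    clusters$cluster <- seq_len(nrow(clusters))
    top_hemi <- clusters$hemisphere[1L]
    laterality <- if (top_hemi %in% c("left", "right")) top_hemi else "none"
    max_region <- clusters$peak_region[1L]
  }
  structure(list(positive = positive,
                 sd_level = if (positive) sd_level else NA_real_,
                 clusters = clusters,
                 laterality = laterality,
                 max_region = max_region,
                 method = method,
                 params = params,
                 stroke_mask = stroke,
                 zmap = zmap,
                 extra = extra),
            class = c(paste0(method, "_scan"), "perf_detection"))
}

negative_detection <- function(template, method, params, stroke, reason) {
  empty <- make_cluster_set(array(0, template$grid$dim),
                            array(0L, template$grid$dim), 0L,
                            template$grid, template$mid_index)
  out <- finalize_detection(empty, template, method, NA_real_, params,
                            stroke, NULL)
  out$extra$note <- reason
  out
}

#' Detect paradoxical asymmetric hyperperfusion from one postictal SPECT
#'
#' The full asymmetry method: mirror-subtraction z-map
#' ([asymmetry_zmap()]), suprathreshold clusters at the primary threshold
#' (2.0 SD) with the 125-voxel extent rule, anatomical exclusion rules
#' (outside cortex, in ventricles, farther than 5 cm from the lesion,
#' contralateral to it), and -- when nothing survives -- a single fallback
#' pass at 1.5 SD. The result records which SD level yielded positivity.
#'
#' @inheritParams asymmetry_zmap
#' @return An object of class `c("asym_scan", "perf_detection")`: fields
#'   `positive`, `sd_level` (2.0, 1.5 or `NA`), `clusters`, `laterality`,
#'   `max_region`, `params`, `stroke_mask`, `zmap`.
#' @export
detect_asymmetry <- function(postictal_std, template, params = asym_params(),
                             lesion_hint = NULL) {
  pz <- tryCatch(
    asymmetry_zmap(postictal_std, template, params, lesion_hint),
    perfusym_degenerate_map = function(e) NULL)
  if (is.null(pz)) {
    warning("degenerate mirror-difference map (zero variance): ",
            "reported as negative", call. = FALSE)
    return(negative_detection(template, "asym", params,
                              array(FALSE, template$grid$dim),
                              "degenerate z-map"))
  }
  if (!any(pz$stroke))
    warning("no stroke lesion identifiable (empty stroke mask): distance ",
            "and contralateral exclusions will be skipped", call. = FALSE)
  run_level <- function(z_thresh) {
    cl <- threshold_clusters(pz$z, z_thresh, params$cluster_extent_min_vox,
                             params$connectivity)
    suppressWarnings(
      apply_exclusion_rules(cl, pz$stroke, template,
                            params$max_lesion_distance_mm))
  }
  surv <- run_level(params$z_primary)
  sd_level <- params$z_primary
  if (nrow(surv) == 0L) {
    surv <- run_level(params$z_fallback)
    sd_level <- params$z_fallback
  }
  finalize_detection(surv, template, "asym", sd_level, params,
                     pz$stroke, pz$z)
}

#' Postictal-interictal (SISCOM-style) subtraction detection
#'
#' The gold-standard comparator: both standardized scans are smoothed, the
#' stroke mask is taken from the postictal scan, both are global-mean
#' normalized over brain-minus-stroke, and the postictal minus interictal
#' difference is z-standardized over the same mask. Hyperperfusion clusters
#' are thresholded at the primary level (2.0 SD) with the extent rule; there
#' is no 1.5 SD fallback and no lesion-distance or contralateral exclusion.
#' Hypoperfusion clusters (z below -2.0) are returned as `hypo_clusters`.
#'
#' @param postictal_std,interictal_std Standardized [volume()]s on the
#'   template grid.
#' @param template A [make_template()] object.
#' @param params An [asym_params()] object (the P-I method uses its
#'   smoothing, stroke fraction, normalization target, primary threshold,
#'   extent and connectivity).
#' @param lesion_hint Optional logical lesion mask overriding the automatic
#'   stroke mask.
#' @return An object of class `c("pisub_scan", "perf_detection")` with the
#'   same fields as [detect_asymmetry()] plus `extra$hypo_clusters`.
#' @export
detect_pi <- function(postictal_std, interictal_std, template,
                      params = asym_params(), lesion_hint = NULL) {
  stopifnot(inherits(template, "perf_template"))
  if (!grids_equal(postictal_std, template) ||
      !grids_equal(interictal_std, template))
    stop("contract error: both scans must be on the template grid",
         call. = FALSE)
  sm_p <- gaussian_smooth(postictal_std, params$smoothing_fwhm_mm)
  sm_i <- gaussian_smooth(interictal_std, params$smoothing_fwhm_mm)
  brain <- template$brain_mask
  stroke <- if (is.null(lesion_hint))
    compute_stroke_mask(sm_p, brain, params$stroke_mask_fraction)
  else (lesion_hint & brain)
  include <- brain & !stroke
  np <- normalize_global_mean(sm_p, include, params$norm_target)
  ni <- normalize_global_mean(sm_i, include, params$norm_target)
  diffv <- volume(np$data - ni$data, np$spacing, np$origin)
  z <- tryCatch(zscore_map(diffv, include, mid_index = template$mid_index),
                perfusym_degenerate_map = function(e) NULL)
  if (is.null(z)) {
    warning("degenerate P-I difference map (zero variance): reported as ",
            "negative", call. = FALSE)
    return(negative_detection(template, "pisub", params, stroke,
                              "degenerate z-map"))
  }
  hyper <- threshold_clusters(z, params$z_primary,
                              params$cluster_extent_min_vox,
                              params$connectivity)
  zneg <- z
  zneg$values <- -z$values
  hypo <- threshold_clusters(zneg, params$z_primary,
                             params$cluster_extent_min_vox,
                             params$connectivity)
  hypo$peak_z <- -hypo$peak_z
  if (nrow(hypo)) hypo <- localize_clusters(hypo, template)
  out <- finalize_detection(hyper, template, "pisub", params$z_primary,
                            params, stroke, z,
                            extra = list(hypo_clusters = hypo))
  out
}

#' @export
print.perf_detection <- function(x, ...) {
  meth <- if (identical(x$method, "asym")) "asymmetry (mirror subtraction)"
  else "P-I subtraction"
  cat(sprintf("<%s detection>\n", meth))
  cat(sprintf("  positive:   %s\n", x$positive))
  cat(sprintf("  sd_level:   %s\n",
              if (is.na(x$sd_level)) "none" else format(x$sd_level)))
  cat(sprintf("  laterality: %s\n", x$laterality))
  cat(sprintf("  max_region: %s\n",
              if (is.na(x$max_region)) "-" else x$max_region))
  cat(sprintf("  clusters:   %d\n", nrow(x$clusters)))
  invisible(x)
}

#' @export
summary.perf_detection <- function(object, ...) {
  print(object)
  if (nrow(object$clusters)) {
    cat("\n")
    print(object$clusters)
  }
  if (!is.null(object$extra$hypo_clusters) &&
      nrow(object$extra$hypo_clusters)) {
    cat("\nhypoperfusion clusters:\n")
    print(object$extra$hypo_clusters)
  }
  invisible(object)
}

#' Plot an axial z-map slice of a detection result
#'
#' @param x A `perf_detection` object (needs its z-map).
#' @param slice Axial (z) slice index; defaults to the slice of the top
#'   cluster peak, or the mid-slice when negative.
#' @param ... Passed to [graphics::image()].
#' @export
plot.perf_detection <- function(x, slice = NULL, ...) {
  if (is.null(x$zmap)) {
    warning("no z-map stored in this result", call. = FALSE)
    return(invisible(x))
  }
  d <- dim(x$zmap$values)
  if (is.null(slice)) {
    slice <- if (nrow(x$clusters)) {
      pk <- attr(x$clusters, "peak_vox")[1L]
      lin_to_ijk(d, pk)[3L] + 1L
    } else (d[3L] + 1L) %/% 2L
  }
  img <- x$zmap$values[, , slice]
  img[!x$zmap$include[, , slice]] <- NA
  graphics::image(img, main = sprintf("z-map, axial slice %d", slice),
                  xlab = "left - right", ylab = "posterior - anterior", ...)
  invisible(x)
}

#' Convert a detection result to a JSON-ready list
#'
#' @param x A `perf_detection` object.
#' @return A plain list (no arrays) suitable for `jsonlite`.
#' @export
detection_as_list <- function(x) {
  stopifnot(inherits(x, "perf_detection"))
  cl <- as.data.frame(x$clusters)
  list(method = x$method,
       positive = x$positive,
       sd_level = if (is.na(x$sd_level)) "none" else x$sd_level,
       laterality = x$laterality,
       max_region = if (is.na(x$max_region)) NULL else x$max_region,
       n_clusters = nrow(cl),
       clusters = cl,
       zmap = if (is.null(x$zmap)) NULL else
         list(mean_used = x$zmap$mean_used, sd_used = x$zmap$sd_used,
              n_include = sum(x$zmap$include)),
       params = unclass(x$params))
}
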