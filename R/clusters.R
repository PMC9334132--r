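# 3-D connected-component labelling and cluster bookkeeping.

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1L,
                 "18" = ord >= 1L & ord <= 2L,
                 "26" = ord >= 1L,
                 stop("`connectivity` must be 6, 18 or 26", call. = FALSE))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3-D mask
#'
#' Frontier-expanding flood fill under 6-, 18- or 26-connectivity.
#'
#' @param mask Logical 3-D array.
#' @param connectivity One of 6, 18, 26.
#' @return A list with `labels` (integer array, 0 = background) and `n`
#'   (number of components).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  off <- neighbor_offsets(connectivity)
  K <- nrow(off)
  lab <- integer(prod(d))
  inmask <- as.logical(mask)
  seeds <- which(inmask)
  nlab <- 0L
  for (s in seeds) {
    if (lab[s] > 0L) next
    nlab <- nlab + 1L
    lab[s] <- nlab
    frontier <- s
    while (length(frontier)) {
      c0 <- lin_to_ijk(d, frontier)  # 0-based
      n <- nrow(c0)
      a1 <- rep(c0[, 1L], each = K) + rep(off[, 1L], n)
      a2 <- rep(c0[, 2L], each = K) + rep(off[, 2L], n)
      a3 <- rep(c0[, 3L], each = K) + rep(off[, 3L], n)
      ok <- a1 >= 0L & a1 < d[1L] & a2 >= 0L & a2 < d[2L] & a3 >= 0L & a3 < d[3L]
      cand <- unique(1L + a1[ok] + d[1L] * (a2[ok] + d[2L] * a3[ok]))
      cand <- cand[inmask[cand] & lab[cand] == 0L]
      lab[cand] <- nlab
      frontier <- cand
    }
  }
  list(labels = array(lab, d), n = nlab)
}

# build a cluster_set data frame from suprathreshold voxel labels
make_cluster_set <- function(zvals, labels, n, grid, mid_index) {
  g <- as_grid(grid)
  cols <- c("cluster", "extent_vox", "peak_z",
            "peak_x_mm", "peak_y_mm", "peak_z_mm",
            "centroid_x_mm", "centroid_y_mm", "centroid_z_mm",
            "hemisphere", "min_lesion_distance_mm", "regions")
  if (n == 0L) {
    df <- data.frame(cluster = integer(), extent_vox = integer(),
                     peak_z = numeric(),
                     peak_x_mm = numeric(), peak_y_mm = numeric(),
                     peak_z_mm = numeric(),
                     centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                     centroid_z_mm = numeric(),
                     hemisphere = character(),
                     min_lesion_distance_mm = numeric(),
                     regions = character(), stringsAsFactors = FALSE)
    attr(df, "voxels") <- list()
    attr(df, "peak_vox") <- integer()
    attr(df, "grid") <- g
    attr(df, "mid_index") <- mid_index
    class(df) <- c("cluster_set", "data.frame")
    return(df)
  }
  vox <- split(which(labels > 0L), labels[labels > 0L])
  rows <- lapply(seq_len(n), function(i) {
    vi <- vox[[i]]
    zi <- zvals[vi]
    pk <- vi[which.max(zi)]
    ijk <- lin_to_ijk(dim(labels), vi) + 1  # 1-based
    mm <- vox_to_mm(g, ijk)
    ctr <- colMeans(mm)
    pmm <- vox_to_mm(g, lin_to_ijk(dim(labels), pk) + 1)
    cx_vox <- mean(ijk[, 1L])
    hemi <- if (is.na(mid_index)) NA_character_
    else if (abs(cx_vox - mid_index) <= 1) "midline"
    else if (cx_vox < mid_index) "left" else "right"
    list(extent = length(vi), peak_z = max(zi), peak_vox = pk,
         pmm = pmm, ctr = ctr, hemi = hemi)
  })
  df <- data.frame(
    cluster = seq_len(n),
    extent_vox = vapply(rows, `[[`, integer(1), "extent"),
    peak_z = vapply(rows, `[[`, numeric(1), "peak_z"),
    peak_x_mm = vapply(rows, function(r) r$pmm[1], numeric(1)),
    peak_y_mm = vapply(rows, function(r) r$pmm[2], numeric(1)),
    peak_z_mm = vapply(rows, function(r) r$pmm[3], numeric(1)),
    centroid_x_mm = vapply(rows, function(r) r$ctr[1], numeric(1)),
    centroid_y_mm = vapply(rows, function(r) r$ctr[2], numeric(1)),
    centroid_z_mm = vapply(rows, function(r) r$ctr[3], numeric(1)),
    hemisphere = vapply(rows, function(r) r$hemi, character(1)),
    min_lesion_distance_mm = NA_real_,
    regions = NA_character_,
    stringsAsFactors = FALSE)
  peak_vox <- vapply(rows, function(r) as.integer(r$peak_vox), integer(1))
  ord <- order(-df$peak_z, -df$extent_vox)
  df <- df[ord, , drop = FALSE]
  df$cluster <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "voxels") <- vox[ord]
  attr(df, "peak_vox") <- peak_vox[ord]
  attr(df, "grid") <- g
  attr(df, "mid_index") <- mid_index
  class(df) <- c("cluster_set", "data.frame")
  df
}

# subset a cluster_set keeping its parallel attributes
subset_cluster_set <- function(cs, keep) {
  vox <- attr(cs, "voxels")[keep]
  pk <- attr(cs, "peak_vox")[keep]
  g <- attr(cs, "grid"); mi <- attr(cs, "mid_index")
  df <- as.data.frame(cs)[keep, , drop = FALSE]
  if (nrow(df)) df$cluster <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "voxels") <- vox
  attr(df, "peak_vox") <- pk
  attr(df, "grid") <- g
  attr(df, "mid_index") <- mi
  class(df) <- c("cluster_set", "data.frame")
  df
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("cluster", "extent_vox", "peak_z",
                                 "hemisphere", "min_lesion_distance_mm",
                                 "regions")]
    print(show, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Suprathreshold clusters of a z-map
#'
#' Connected components of `{z > z_thresh}` within the z-map's inclusion
#' mask; components smaller than the cluster extent threshold are discarded
#' (a component of exactly `min_extent` voxels survives). Clusters are sorted
#' by peak z descending.
#'
#' @param z A [zscore_map()] object.
#' @param z_thresh Threshold in SD units (voxels strictly above survive).
#' @param min_extent Minimum connected extent in voxels (default 125, i.e.
#'   1 mL at 2 mm isotropic).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `cluster_set` data frame.
#' @export
threshold_clusters <- function(z, z_thresh, min_extent = 125L,
                               connectivity = 26L) {
  stopifnot(inherits(z, "perf_zmap"))
  if (!is.numeric(min_extent) || min_extent < 1)
    stop("`min_extent` must be at least 1", call. = FALSE)
  supra <- z$include & (z$values > z_thresh)
  lab <- label_components(supra, connectivity)
  if (lab$n > 0L) {
    sizes <- tabulate(lab$labels[lab$labels > 0L], lab$n)
    small <- which(sizes < min_extent)
    if (length(small)) {
      lab$labels[array(lab$labels %in% small, dim(lab$labels))] <- 0L
      keepers <- setdiff(seq_len(lab$n), small)
      relab <- integer(lab$n); relab[keepers] <- seq_along(keepers)
      lab$labels[lab$labels > 0L] <- relab[lab$labels[lab$labels > 0L]]
      lab$n <- length(keepers)
    }
  }
  make_cluster_set(z$values, lab$labels, lab$n, z$grid, z$mid_index)
}

#' Anatomical exclusion rules for asymmetry clusters
#'
#' Removes artifact clusters: peak outside the template brain mask or inside
#' the ventricle mask; minimum cluster-to-lesion Euclidean distance above
#' `max_dist_mm` (default 50 mm); centroid in the hemisphere contralateral to
#' the lesion-dominant hemisphere. Midline clusters (centroid within one voxel
#' of the mid-sagittal plane) are never excluded as contralateral. When the
#' lesion mask is empty the distance and contralateral rules are skipped with
#' a warning.
#'
#' @param clusters A `cluster_set`.
#' @param lesion Logical lesion (stroke) mask on the template grid.
#' @param template A [make_template()] object.
#' @param max_dist_mm Maximum allowed lesion distance in mm (default 50).
#' @return The filtered `cluster_set`, with `min_lesion_distance_mm` filled in.
#' @export
apply_exclusion_rules <- function(clusters, lesion, template,
                                  max_dist_mm = 50) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (nrow(clusters) == 0L) return(clusters)
  g <- attr(clusters, "grid")
  pk <- attr(clusters, "peak_vox")
  keep <- template$brain_mask[pk] & !template$ventricle_mask[pk]

  if (!any(lesion)) {
    warning("empty lesion mask: distance and contralateral exclusion rules ",
            "skipped", call. = FALSE)
    return(subset_cluster_set(clusters, which(keep)))
  }

  les_mm <- vox_to_mm(g, lin_to_ijk(g$dim, which(lesion)) + 1)
  vox <- attr(clusters, "voxels")
  dmin <- vapply(seq_len(nrow(clusters)), function(i) {
    cl_mm <- vox_to_mm(g, lin_to_ijk(g$dim, vox[[i]]) + 1)
    # min over all (cluster voxel, lesion voxel) pairs
    d2 <- outer(rowSums(cl_mm^2), rowSums(les_mm^2), `+`) -
      2 * tcrossprod(cl_mm, les_mm)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  clusters$min_lesion_distance_mm <- dmin
  keep <- keep & dmin <= max_dist_mm

  mid <- attr(clusters, "mid_index")
  les_x <- lin_to_ijk(g$dim, which(lesion))[, 1L] + 1
  frac_left <- mean(les_x < mid)
  dominant <- if (frac_left > 0.5) "left"
  else if (1 - frac_left > 0.5) "right" else NA_character_
  if (!is.na(dominant)) {
    opposite <- if (dominant == "left") "right" else "left"
    keep <- keep & !(clusters$hemisphere == opposite)
  }
  subset_cluster_set(clusters, which(keep))
}
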