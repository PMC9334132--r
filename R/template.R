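# The symmetric standard-space template: grid, brain/ventricle masks,
# ten-region geometric atlas, mid-sagittal plane, FLAIR-like reference.

#' Build the symmetric standard-space template
#'
#' Constructs a left-right flip-symmetric ellipsoidal brain on a 2 mm
#' isotropic RAS grid with an odd left-right dimension (so the mid-sagittal
#' plane falls exactly on a voxel plane), a cortical ribbon, a central
#' ventricle mask, and a ten-region geometric atlas: five sectors (frontal,
#' central, parietal, occipital, temporal) in each hemisphere. The sectors
#' carry the standard lobe names but are geometric stand-ins, not gyral
#' anatomy; any standards-conformant label volume can replace the atlas.
#'
#' @param dim Grid dimensions (default `c(67, 81, 61)`); the first (LR)
#'   dimension must be odd.
#' @param spacing Isotropic voxel size in mm (default 2).
#' @param semi_axes Brain ellipsoid semi-axes in mm (x, y, z).
#' @return An object of class `perf_template`: list with `grid`,
#'   `brain_mask`, `ventricle_mask`, `cortex_mask`, `atlas`, `label_table`,
#'   `mid_index`, `reference` (FLAIR-like volume), `coords`, `semi_axes`.
#' @export
make_template <- function(dim = c(67L, 81L, 61L), spacing = 2,
                          semi_axes = c(60, 75, 55)) {
  dim <- as.integer(dim)
  if (dim[1L] %% 2L == 0L)
    stop("argument error: the left-right dimension must be odd so the ",
         "midline is a voxel plane", call. = FALSE)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  origin <- -(dim - 1) / 2 * spacing
  g <- grid_spec(dim, spacing, origin)

  xs <- origin[1L] + (seq_len(dim[1L]) - 1) * spacing[1L]
  ys <- origin[2L] + (seq_len(dim[2L]) - 1) * spacing[2L]
  zs <- origin[3L] + (seq_len(dim[3L]) - 1) * spacing[3L]
  X <- array(rep(xs, times = dim[2L] * dim[3L]), dim)
  Y <- array(rep(rep(ys, each = dim[1L]), times = dim[3L]), dim)
  Z <- array(rep(zs, each = dim[1L] * dim[2L]), dim)

  rn2 <- (X / semi_axes[1L])^2 + (Y / semi_axes[2L])^2 + (Z / semi_axes[3L])^2
  brain <- rn2 <= 1
  ventricle <- ((X / 14)^2 + ((Y + 5) / 30)^2 + (Z / 12)^2) <= 1 & brain
  rn <- sqrt(rn2)
  cortex <- brain & rn > 0.68
  white <- brain & !cortex & !ventricle

  # ten geometric sectors named after the five lobar areas per hemisphere
  u <- Y / semi_axes[2L]   # anterior +
  w <- Z / semi_axes[3L]   # superior +
  region <- array("", dim)
  region[cortex & u > 0.3] <- "frontal"
  region[cortex & u <= 0.3 & u >= -0.6 & w < -0.2] <- "temporal"
  region[cortex & u <= 0.3 & u > 0 & w >= -0.2] <- "central"
  region[cortex & u <= 0 & u >= -0.6 & w >= -0.2] <- "parietal"
  region[cortex & u < -0.6] <- "occipital"
  mid_index <- (dim[1L] + 1L) / 2L
  hemi <- array("midline", dim)
  hemi[X < 0] <- "left"
  hemi[X > 0] <- "right"

  regions5 <- c("frontal", "central", "parietal", "occipital", "temporal")
  label_table <- data.frame(
    label = 1:10,
    region = rep(regions5, 2L),
    hemisphere = rep(c("left", "right"), each = 5L),
    name = paste(rep(regions5, 2L), rep(c("left", "right"), each = 5L),
                 sep = "_"),
    stringsAsFactors = FALSE)

  atlas <- array(0L, dim)
  for (i in seq_len(nrow(label_table))) {
    sel <- region == label_table$region[i] & hemi == label_table$hemisphere[i]
    atlas[sel] <- label_table$label[i]
  }

  reference <- array(0, dim)          # FLAIR-like: CSF dark, GM > WM
  reference[white] <- 70
  reference[cortex] <- 90
  reference[ventricle] <- 10

  structure(list(grid = g,
                 brain_mask = brain,
                 ventricle_mask = ventricle,
                 cortex_mask = cortex,
                 atlas = atlas,
                 label_table = label_table,
                 mid_index = mid_index,
                 reference = volume(reference, spacing, origin),
                 coords = list(x = X, y = Y, z = Z),
                 semi_axes = semi_axes),
            class = "perf_template")
}

#' @export
print.perf_template <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<perf_template> %d x %d x %d @ %g mm, brain %d voxels, 10-region atlas\n",
              g$dim[1], g$dim[2], g$dim[3], g$spacing[1], sum(x$brain_mask)))
  invisible(x)
}

#' Write a template to a directory (NIfTI volumes + JSON manifest)
#'
#' @param template A [make_template()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- template$grid
  wv <- function(a, f)
    write_volume(volume(a + 0, g$spacing, g$origin), file.path(dir, f))
  wv(template$brain_mask, "brain_mask.nii.gz")
  wv(template$ventricle_mask, "ventricle_mask.nii.gz")
  wv(template$cortex_mask, "cortex_mask.nii.gz")
  wv(template$atlas, "atlas.nii.gz")
  write_volume(template$reference, file.path(dir, "reference.nii.gz"))
  jsonlite::write_json(
    list(grid = list(dim = g$dim, spacing = g$spacing, origin = g$origin),
         mid_index = template$mid_index,
         semi_axes = template$semi_axes,
         label_table = template$label_table),
    file.path(dir, "template.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a template written by [write_template()]
#'
#' @param dir Template directory.
#' @return A `perf_template`.
#' @export
load_template <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "template.json"),
                             simplifyVector = TRUE)
  g <- grid_spec(man$grid$dim, man$grid$spacing, man$grid$origin)
  rv <- function(f) read_volume(file.path(dir, f))
  brain <- rv("brain_mask.nii.gz")$data > 0.5
  ventricle <- rv("ventricle_mask.nii.gz")$data > 0.5
  cortex <- rv("cortex_mask.nii.gz")$data > 0.5
  atlas_v <- rv("atlas.nii.gz")
  atlas <- array(as.integer(round(atlas_v$data)), g$dim)
  xs <- g$origin[1L] + (seq_len(g$dim[1L]) - 1) * g$spacing[1L]
  ys <- g$origin[2L] + (seq_len(g$dim[2L]) - 1) * g$spacing[2L]
  zs <- g$origin[3L] + (seq_len(g$dim[3L]) - 1) * g$spacing[3L]
  structure(list(grid = g,
                 brain_mask = brain, ventricle_mask = ventricle,
                 cortex_mask = cortex, atlas = atlas,
                 label_table = as.data.frame(man$label_table),
                 mid_index = man$mid_index,
                 reference = rv("reference.nii.gz"),
                 coords = list(
                   x = array(rep(xs, times = g$dim[2L] * g$dim[3L]), g$dim),
                   y = array(rep(rep(ys, each = g$dim[1L]), times = g$dim[3L]),
                             g$dim),
                   z = array(rep(zs, each = g$dim[1L] * g$dim[2L]), g$dim)),
                 semi_axes = man$semi_axes),
            class = "perf_template")
}
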