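#' Construct a 3-D scalar volume
#'
#' The universal image container of the package: a 3-D array of scalar values
#' (SPECT counts or MRI intensity, arbitrary units) on an axis-aligned grid in
#' canonical RAS orientation. Axis 1 runs left-to-right (+x = subject right),
#' axis 2 posterior-to-anterior, axis 3 inferior-to-superior. The physical
#' position of voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`
#' millimetres.
#'
#' @param data 3-D numeric array.
#' @param spacing Voxel size in mm per axis (length 3, all positive).
#' @param origin Physical coordinate in mm of the first voxel (length 3).
#' @return An object of class `perf_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "perf_volume")
}

#' Grid specification
#'
#' @param dim Integer grid dimensions (length 3).
#' @param spacing Voxel size in mm per axis.
#' @param origin Physical mm coordinate of the first voxel.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dim, spacing, origin) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("`dim` must be three positive integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("degenerate target grid: spacing must be positive", call. = FALSE)
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.perf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<perf_volume> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# grid of a volume / template / grid_spec, as a grid_spec
as_grid <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, "perf_volume"))
    return(grid_spec(dim(x$data), x$spacing, x$origin))
  if (inherits(x, "perf_template")) return(x$grid)
  stop("cannot extract a grid from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

grids_equal <- function(a, b, tol = 1e-6) {
  a <- as_grid(a); b <- as_grid(b)
  identical(a$dim, b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# physical mm coordinates of 1-based voxel indices (n x 3 matrix in, n x 3 out)
vox_to_mm <- function(grid, idx) {
  g <- as_grid(grid)
  sweep(sweep(idx - 1, 2L, g$spacing, `*`), 2L, g$origin, `+`)
}

# continuous 1-based voxel coordinates of physical mm points
mm_to_vox <- function(grid, pts) {
  g <- as_grid(grid)
  sweep(sweep(pts, 2L, g$origin, `-`), 2L, g$spacing, `/`) + 1
}

# linear (column-major) index from 1-based i, j, k vectors
lin_index <- function(d, i1, i2, i3) i1 + d[1L] * ((i2 - 1L) + d[2L] * (i3 - 1L))

# 0-based (i, j, k) from 1-based linear index
lin_to_ijk <- function(d, v) {
  v0 <- v - 1L
  i1 <- v0 %% d[1L]
  r <- v0 %/% d[1L]
  cbind(i1, r %% d[2L], r %/% d[2L])
}

# trilinear interpolation of array `a` at continuous 1-based voxel coords;
# points outside the field evaluate to 0
interp_trilinear <- function(a, cx, cy, cz) {
  d <- dim(a)
  inside <- cx >= 1 & cx <= d[1L] & cy >= 1 & cy <= d[2L] & cz >= 1 & cz <= d[3L]
  out <- numeric(length(cx))
  if (!any(inside)) return(out)
  cx <- cx[inside]; cy <- cy[inside]; cz <- cz[inside]
  f1 <- pmin(pmax(floor(cx), 1), max(1L, d[1L] - 1L))
  f2 <- pmin(pmax(floor(cy), 1), max(1L, d[2L] - 1L))
  f3 <- pmin(pmax(floor(cz), 1), max(1L, d[3L] - 1L))
  # upper corners clamped for singleton dimensions (their weight is then 0)
  g1 <- pmin(f1 + 1, d[1L]); g2 <- pmin(f2 + 1, d[2L]); g3 <- pmin(f3 + 1, d[3L])
  w1 <- cx - f1; w2 <- cy - f2; w3 <- cz - f3
  val <-
    a[lin_index(d, f1, f2, f3)] * (1 - w1) * (1 - w2) * (1 - w3) +
    a[lin_index(d, g1, f2, f3)] * w1       * (1 - w2) * (1 - w3) +
    a[lin_index(d, f1, g2, f3)] * (1 - w1) * w2       * (1 - w3) +
    a[lin_index(d, g1, g2, f3)] * w1       * w2       * (1 - w3) +
    a[lin_index(d, f1, f2, g3)] * (1 - w1) * (1 - w2) * w3 +
    a[lin_index(d, g1, f2, g3)] * w1       * (1 - w2) * w3 +
    a[lin_index(d, f1, g2, g3)] * (1 - w1) * w2       * w3 +
    a[lin_index(d, g1, g2, g3)] * w1       * w2       * w3
  out[inside] <- val
  out
}

interp_nearest <- function(a, cx, cy, cz) {
  d <- dim(a)
  r1 <- round(cx); r2 <- round(cy); r3 <- round(cz)
  inside <- r1 >= 1 & r1 <= d[1L] & r2 >= 1 & r2 <= d[2L] & r3 >= 1 & r3 <= d[3L]
  out <- numeric(length(cx))
  if (any(inside))
    out[inside] <- a[lin_index(d, r1[inside], r2[inside], r3[inside])]
  out
}

#' Read a NIfTI volume, canonicalized to RAS
#'
#' Reads a single scalar 3-D NIfTI file and reorients it so that the stored
#' array is in canonical RAS axis order. Oblique (non-axis-aligned) images are
#' rejected: the pipeline operates on axis-aligned grids only.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("format error: file does not exist: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error: unreadable NIfTI (",
                                           conditionMessage(e), ")", call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("format error: expected a single 3-D scalar volume, got a ",
         length(d), "-D image", call. = FALSE)
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  cols <- sweep(rot, 2L, sqrt(colSums(rot^2)), `/`)
  if (any(abs(abs(cols)[abs(cols) > 1e-3] - 1) > 1e-3) ||
      any(colSums(abs(cols) > 1e-3) != 1L))
    stop("format error: non-orthogonal (oblique) orientation is not supported",
         call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  x <- RNifti::xform(img)
  volume(array(as.numeric(img), dim = dim(img)),
         spacing = sqrt(colSums(x[1:3, 1:3]^2)),  # robust to stale pixdim
         origin = x[1:3, 4])
}

#' Write a volume as NIfTI
#'
#' @param v A [volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "perf_volume"))
  # pixdim must be set in the header itself: the xform setters normalize
  # their rotation part against it
  img <- RNifti::asNifti(v$data,
                         reference = list(pixdim = c(1, v$spacing, 0, 0, 0, 0)))
  m <- diag(4)
  m[1:3, 1:3] <- diag(v$spacing)
  m[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid
#'
#' Values are interpolated in physical (mm) space; target voxels falling
#' outside the source field of view are set to 0.
#'
#' @param v A [volume()].
#' @param target A [grid_spec()], or an object a grid can be taken from
#'   (volume, template).
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @return A [volume()] on the target grid.
#' @export
resample_to_grid <- function(v, target, interpolation = c("linear", "nearest")) {
  stopifnot(inherits(v, "perf_volume"))
  interpolation <- match.arg(interpolation)
  g <- as_grid(target)
  if (grids_equal(v, g)) return(volume(v$data, g$spacing, g$origin))
  idx <- as.matrix(expand.grid(i = seq_len(g$dim[1L]),
                               j = seq_len(g$dim[2L]),
                               k = seq_len(g$dim[3L])))
  cv <- mm_to_vox(v, vox_to_mm(g, idx))
  vals <- switch(interpolation,
                 linear  = interp_trilinear(v$data, cv[, 1], cv[, 2], cv[, 3]),
                 nearest = interp_nearest(v$data, cv[, 1], cv[, 2], cv[, 3]))
  volume(array(vals, dim = g$dim), g$spacing, g$origin)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm Full width at half maximum.
#' @return `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# separable shift-and-add convolution along one axis, zero boundary padding.
# Opposite offsets are summed pairwise before scaling, so a left-right
# symmetric input stays bit-identically symmetric after smoothing.
convolve_axis <- function(a, kern, axis) {
  r <- (length(kern) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  shifted <- function(off) {
    s1 <- max(1L, 1L + off); s2 <- min(n, n + off)
    out <- array(0, d)
    if (s1 > s2) return(out)
    dst <- (s1 - off):(s2 - off)
    src <- s1:s2
    if (axis == 1L) out[dst, , ] <- a[src, , ]
    else if (axis == 2L) out[, dst, ] <- a[, src, ]
    else out[, , dst] <- a[, , src]
    out
  }
  acc <- kern[r + 1L] * a
  for (j in seq_len(r))
    acc <- acc + kern[r + 1L + j] * (shifted(j) + shifted(-j))
  acc
}

#' Isotropic Gaussian smoothing in physical units
#'
#' Smooths with an isotropic Gaussian specified by its full width at half
#' maximum in millimetres; the per-axis kernel is the sampled Gaussian density
#' normalized to unit sum, so total image mass is preserved when the support
#' lies inside the field (zero padding at the boundary).
#'
#' @param v A [volume()].
#' @param fwhm_mm Full width at half maximum in mm (> 0).
#' @return The smoothed [volume()].
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "perf_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0)
    stop("`fwhm_mm` must be a single positive number", call. = FALSE)
  sigma <- fwhm_to_sigma(fwhm_mm)
  a <- v$data
  for (axis in 1:3) {
    sv <- sigma / v$spacing[axis]
    r <- max(1L, as.integer(ceiling(4 * sv)))
    k <- stats::dnorm(seq(-r, r), sd = sv)
    k <- k / sum(k)
    a <- convolve_axis(a, k, axis)
  }
  volume(a, v$spacing, v$origin)
}

#' Mirror a standardized volume about the template mid-sagittal plane
#'
#' Reverses the left-right axis (axis 1) index order. Only meaningful for
#' volumes on the symmetric standard grid, whose odd left-right dimension puts
#' the mid-sagittal plane exactly on a voxel plane (which maps to itself).
#'
#' @param v A [volume()] on the standard grid.
#' @param template Optional [make_template()] object; when supplied the
#'   volume's grid must match the template grid exactly.
#' @return The mirrored [volume()].
#' @export
flip_lr <- function(v, template = NULL) {
  stopifnot(inherits(v, "perf_volume"))
  if (!is.null(template) && !grids_equal(v, template))
    stop("contract error: volume is not on the standard template grid; ",
         "standardize before flipping", call. = FALSE)
  d1 <- dim(v$data)[1L]
  if (d1 %% 2L == 0L)
    stop("contract error: left-right dimension must be odd so the midline ",
         "is a voxel plane", call. = FALSE)
  volume(v$data[d1:1, , , drop = FALSE], v$spacing, v$origin)
}

flip_lr_array <- function(a) a[dim(a)[1L]:1, , , drop = FALSE]

#' Whole-brain mask
#'
#' Returns the template brain mask when one is available; otherwise a
#' threshold-and-largest-component heuristic on the (smoothed) volume:
#' voxels above `threshold_fraction` of the maximum, largest 6-connected
#' component kept.
#'
#' @param v A [volume()] (smoothed standardized SPECT).
#' @param template Optional template whose `brain_mask` is returned as-is.
#' @param threshold_fraction Intensity fraction of the maximum for the
#'   heuristic (default 0.25).
#' @return A logical 3-D array on the volume's grid.
#' @export
compute_brain_mask <- function(v, template = NULL, threshold_fraction = 0.25) {
  if (!is.null(template)) {
    if (!grids_equal(v, template))
      stop("contract error: volume grid does not match the template grid",
           call. = FALSE)
    return(template$brain_mask)
  }
  stopifnot(inherits(v, "perf_volume"))
  thr <- threshold_fraction * max(v$data)
  m <- v$data > thr
  if (!any(m))
    stop("detection error: brain mask is empty after thresholding",
         call. = FALSE)
  lab <- label_components(m, connectivity = 6L)
  if (lab$n > 1L) {
    sizes <- tabulate(lab$labels[lab$labels > 0L], lab$n)
    m <- array(lab$labels == which.max(sizes), dim(m))
  }
  m
}

#' Automatic stroke-lesion mask
#'
#' Flags voxels inside the brain whose smoothed uptake falls below a fraction
#' of the whole-brain maximum (default 30 percent) -- a fully automatic rule
#' with no manual region definition.
#'
#' @param v_smoothed Smoothed standardized SPECT [volume()].
#' @param brain Logical brain mask on the same grid.
#' @param fraction Proportion of the whole-brain maximum (0 < fraction < 1).
#' @return A logical 3-D array (possibly empty when no voxel is that low).
#' @export
compute_stroke_mask <- function(v_smoothed, brain, fraction = 0.30) {
  stopifnot(inherits(v_smoothed, "perf_volume"))
  if (!any(brain)) stop("`brain` mask is empty", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  mx <- max(v_smoothed$data[brain])
  brain & (v_smoothed$data < fraction * mx)
}

#' Global-mean count normalization
#'
#' Scales the whole volume so that its mean over the inclusion mask equals
#' `target` (stroke areas are excluded from the mask by the caller).
#'
#' @param v A [volume()].
#' @param include Logical inclusion mask on the volume's grid.
#' @param target Target global mean (default 100, the perfusion convention).
#' @return The rescaled [volume()].
#' @export
normalize_global_mean <- function(v, include, target = 100) {
  stopifnot(inherits(v, "perf_volume"))
  if (!any(include)) stop("inclusion mask is empty", call. = FALSE)
  m <- mean(v$data[include])
  if (!is.finite(m) || m <= 0)
    stop("numeric error: non-positive mean over the inclusion mask",
         call. = FALSE)
  volume(v$data * (target / m), v$spacing, v$origin)
}
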