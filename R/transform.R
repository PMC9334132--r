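# Spatial transforms in physical (mm) coordinates.
#
# Convention: a transform is used for *resampling* -- it maps points of the
# FIXED (target) space into the MOVING (source) space. `apply_transform(v, t,
# grid)` evaluates `v` at `t(x)` for every grid point `x`.

rot_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rigid (6-DOF) transform
#'
#' `T(x) = R (x - center) + center + translation`, with `R` the rotation
#' composed as Rz Ry Rx from per-axis angles in degrees.
#'
#' @param rotation Angles in degrees about x, y, z.
#' @param translation Offsets in mm.
#' @param center Rotation centre in mm.
#' @return An object of class `c("rigid_transform", "perf_transform")`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  R <- rot_matrix(rotation)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + translation - R %*% center
  structure(list(matrix = m, rotation = rotation, translation = translation,
                 center = center),
            class = c("rigid_transform", "perf_transform"))
}

#' Affine (12-DOF) transform
#'
#' @param matrix A 3x4 or 4x4 matrix in physical mm coordinates; the linear
#'   part must be non-singular.
#' @return An object of class `c("affine_transform", "perf_transform")`.
#' @export
affine_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) == 3L) m <- rbind(m, c(0, 0, 0, 1))
  stopifnot(nrow(m) == 4L, ncol(m) == 4L)
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    stop("registration error: singular affine linear part", call. = FALSE)
  structure(list(matrix = m), class = c("affine_transform", "perf_transform"))
}

#' Apply a transform to physical points
#'
#' @param t A `perf_transform`.
#' @param pts An n x 3 matrix of mm coordinates.
#' @return The transformed n x 3 matrix.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "perf_transform"))
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- t$matrix %*% pts
  t(out[1:3, , drop = FALSE])
}

#' Invert a transform
#' @param t A `perf_transform`.
#' @return The inverse as an `affine_transform` (a rigid inverse is still
#'   rigid; it is returned in matrix form).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "perf_transform"))
  affine_transform(solve(t$matrix))
}

#' Compose transforms
#'
#' `compose_transforms(a, b)` is the map `x -> a(b(x))`.
#' @param a,b `perf_transform` objects.
#' @return An `affine_transform`.
#' @export
compose_transforms <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix)
}

#' Resample a volume through a transform
#'
#' Evaluates `v` at `t(x)` for every voxel centre `x` of the target grid
#' (fixed-to-moving resampling convention); out-of-field points give 0.
#'
#' @param v The moving [volume()].
#' @param t A `perf_transform` mapping target (fixed) mm points into `v`'s
#'   space.
#' @param target Target grid ([grid_spec()], volume or template).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A [volume()] on the target grid.
#' @export
apply_transform <- function(v, t, target, interpolation = c("linear", "nearest")) {
  stopifnot(inherits(v, "perf_volume"), inherits(t, "perf_transform"))
  interpolation <- match.arg(interpolation)
  g <- as_grid(target)
  idx <- as.matrix(expand.grid(i = seq_len(g$dim[1L]),
                               j = seq_len(g$dim[2L]),
                               k = seq_len(g$dim[3L])))
  pts <- transform_points(t, vox_to_mm(g, idx))
  cv <- mm_to_vox(v, pts)
  vals <- switch(interpolation,
                 linear  = interp_trilinear(v$data, cv[, 1], cv[, 2], cv[, 3]),
                 nearest = interp_nearest(v$data, cv[, 1], cv[, 2], cv[, 3]))
  volume(array(vals, dim = g$dim), g$spacing, g$origin)
}

#' Serialize a transform to JSON
#'
#' Rigid transforms store angles in degrees and offsets in mm; all transforms
#' store the row-major 4x4 matrix.
#'
#' @param t A `perf_transform`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "perf_transform"))
  obj <- list(type = class(t)[1L],
              matrix_row_major = as.vector(t(t$matrix)))
  if (inherits(t, "rigid_transform")) {
    obj$rotation_deg <- t$rotation
    obj$translation_mm <- t$translation
    obj$center_mm <- t$center
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform from JSON
#' @param path Path written by [write_transform_json()].
#' @return A `perf_transform`.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "rigid_transform"))
    rigid_transform(obj$rotation_deg, obj$translation_mm, obj$center_mm)
  else
    affine_transform(matrix(obj$matrix_row_major, 4, 4, byrow = TRUE))
}
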