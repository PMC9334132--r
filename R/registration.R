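# Rigid co-registration and affine anatomical standardization.

# binned mutual information between two equal-length samples
mutual_information <- function(x, y, bins = 32L) {
  rx <- range(x); ry <- range(y)
  if (rx[1] == rx[2] || ry[1] == ry[2]) return(0)
  bx <- pmin(as.integer((x - rx[1]) / (rx[2] - rx[1]) * bins) + 1L, bins)
  by <- pmin(as.integer((y - ry[1]) / (ry[2] - ry[1]) * bins) + 1L, bins)
  joint <- tabulate(bx + bins * (by - 1L), bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins))
  py <- colSums(matrix(p, bins, bins))
  nz <- p > 0
  pp <- outer(px, py)
  sum(p[nz] * log(p[nz] / pp[nz]))
}

# Nelder-Mead with an explicit initial simplex step per parameter.
# stats::optim sizes its initial simplex from the magnitude of the starting
# values, which degenerates for warm starts near zero; registration needs
# steps on the physical scale of the problem (degrees / mm) instead.
nelder_mead <- function(fn, par, step, maxit = 400L, tol = 1e-7) {
  n <- length(par)
  simplex <- matrix(rep(par, each = n + 1L), nrow = n + 1L)
  for (i in seq_len(n)) simplex[i + 1L, i] <- simplex[i + 1L, i] + step[i]
  fvals <- apply(simplex, 1L, fn)
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    ord <- order(fvals)
    simplex <- simplex[ord, , drop = FALSE]
    fvals <- fvals[ord]
    if (abs(fvals[n + 1L] - fvals[1L]) < tol * (abs(fvals[1L]) + tol)) break
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    worst <- simplex[n + 1L, ]
    xr <- centroid + (centroid - worst)
    fr <- fn(xr)
    if (fr < fvals[1L]) {                       # expand
      xe <- centroid + 2 * (centroid - worst)
      fe <- fn(xe)
      if (fe < fr) { simplex[n + 1L, ] <- xe; fvals[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fvals[n + 1L] <- fr }
    } else if (fr < fvals[n]) {                 # reflect
      simplex[n + 1L, ] <- xr
      fvals[n + 1L] <- fr
    } else {                                    # contract / shrink
      xc <- centroid + 0.5 * (worst - centroid)
      fc <- fn(xc)
      if (fc < fvals[n + 1L]) { simplex[n + 1L, ] <- xc; fvals[n + 1L] <- fc }
      else {
        for (i in 2:(n + 1L)) {
          simplex[i, ] <- simplex[1L, ] + 0.5 * (simplex[i, ] - simplex[1L, ])
          fvals[i] <- fn(simplex[i, ])
        }
      }
    }
  }
  ord <- order(fvals)
  list(par = simplex[ord[1L], ], value = fvals[ord[1L]],
       converged = it < maxit)
}

# downsample a volume to `factor` times its spacing (for the multiresolution
# pyramid); light pre-smoothing suppresses aliasing
pyramid_level <- function(v, factor) {
  if (factor <= 1) return(v)
  sm <- gaussian_smooth(v, fwhm_mm = mean(v$spacing) * factor)
  g0 <- as_grid(v)
  newdim <- pmax(2L, as.integer(ceiling(g0$dim / factor)))
  resample_to_grid(sm, grid_spec(newdim, g0$spacing * factor, g0$origin),
                   "linear")
}

#' Rigid 6-DOF co-registration
#'
#' Registers a moving volume to a fixed volume by maximizing binned mutual
#' information (a cross-modality similarity) over rotation and translation,
#' with a three-level multiresolution schedule and Nelder-Mead optimization.
#' Deterministic: no random sampling is used.
#'
#' The returned transform follows the resampling convention: it maps fixed
#' physical points into the moving volume's space, so
#' `apply_transform(moving, t, fixed)` aligns the moving image onto the fixed
#' grid.
#'
#' @param moving,fixed [volume()] objects with overlapping fields of view.
#' @param bins Histogram bins for mutual information (default 32).
#' @param levels Multiresolution spacing factors, coarse to fine.
#' @param max_points Sampling cap per level (a deterministic stride is used).
#' @param maxit Nelder-Mead iteration cap per level.
#' @return A [rigid_transform()] with a `metric` attribute (final mutual
#'   information).
#' @export
register_rigid <- function(moving, fixed, bins = 32L, levels = c(4, 2, 1),
                           max_points = 40000L, maxit = 500L) {
  stopifnot(inherits(moving, "perf_volume"), inherits(fixed, "perf_volume"))
  if (all(moving$data == 0) || all(fixed$data == 0))
    stop("registration error: empty input volume", call. = FALSE)
  par <- rep(0, 6)  # rx, ry, rz (deg), tx, ty, tz (mm)
  metric <- NA_real_
  center <- NULL
  for (lev in levels) {
    fx <- pyramid_level(fixed, lev)
    mv <- pyramid_level(moving, lev)
    thr <- 0.05 * max(fx$data)
    sel <- which(fx$data > thr)
    if (length(sel) < 50L)
      stop("registration error: too few foreground voxels at level ", lev,
         call. = FALSE)
    if (length(sel) > max_points)
      sel <- sel[seq(1L, length(sel), length.out = max_points)]
    ijk <- lin_to_ijk(dim(fx$data), sel) + 1
    pts <- vox_to_mm(fx, ijk)
    fvals <- fx$data[sel]
    if (is.null(center)) center <- colMeans(pts)
    objective <- function(p) {
      t <- rigid_transform(p[1:3], p[4:6], center)
      cv <- mm_to_vox(mv, transform_points(t, pts))
      mvals <- interp_trilinear(mv$data, cv[, 1], cv[, 2], cv[, 3])
      -mutual_information(fvals, mvals, bins)
    }
    # initial simplex on the physical scale of the level: degrees and mm
    step <- c(rep(max(0.5, lev), 3L), rep(max(1, lev) * 1.5, 3L))
    fit <- nelder_mead(objective, par, step, maxit = maxit, tol = 1e-8)
    if (!fit$converged) {
      fit2 <- nelder_mead(objective, fit$par, step / 4, maxit = maxit,
                          tol = 1e-8)
      if (fit2$value <= fit$value) fit <- fit2
      if (!fit$converged && lev == levels[length(levels)])
        stop("registration error: optimizer failed to converge (final ",
             "mutual information ", format(-fit$value), ")", call. = FALSE)
    }
    par <- fit$par
    metric <- -fit$value
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "metric") <- metric
  out
}

# symmetric matrix square root
sqrtm_spd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
}

mask_moments <- function(mask, grid) {
  g <- as_grid(grid)
  mm <- vox_to_mm(g, lin_to_ijk(g$dim, which(mask)) + 1)
  list(mu = colMeans(mm), cov = stats::cov(mm))
}

#' Estimate the anatomical standardization affine
#'
#' A deterministic 12-DOF linear map from a subject structural volume onto
#' the symmetric template, computed by moment matching of brain extractions:
#' the centroid is aligned and the linear part is the whitening-coloring map
#' `sqrtm(C_template) %*% solve(sqrtm(C_subject))` of the mask covariances.
#' The same threshold-and-largest-component extraction rule is applied to
#' both the subject structural and the template reference volume, so
#' standardizing the template reference itself is an exact fixed point.
#' Returned in the forward (subject-to-template) direction.
#'
#' @param structural Subject structural [volume()].
#' @param template A [make_template()] object.
#' @param threshold_fraction Brain-extraction threshold applied to both
#'   volumes (see [compute_brain_mask()]).
#' @return An [affine_transform()] mapping subject mm points to template mm
#'   points.
#' @export
estimate_affine <- function(structural, template, threshold_fraction = 0.25) {
  sm <- compute_brain_mask(structural, threshold_fraction = threshold_fraction)
  ms <- mask_moments(sm, structural)
  tm <- compute_brain_mask(template$reference,
                           threshold_fraction = threshold_fraction)
  mt <- mask_moments(tm, template$grid)
  B <- sqrtm_spd(mt$cov) %*% solve(sqrtm_spd(ms$cov))
  m <- diag(4)
  m[1:3, 1:3] <- B
  m[1:3, 4] <- mt$mu - B %*% ms$mu
  affine_transform(m)
}

#' Anatomical standardization onto the template grid
#'
#' Resamples a volume onto the symmetric standard grid by composing the
#' case's rigid SPECT-to-structural transform with the structural-to-template
#' affine. The affine is estimated once per case (or passed in) and the same
#' composed parameters must be reused for every volume of the case.
#'
#' @param v [volume()] to standardize (a SPECT scan, or the structural
#'   itself).
#' @param structural The case's structural volume (used to estimate the
#'   affine when `affine` is `NULL`).
#' @param template A [make_template()] object.
#' @param rigid Optional rigid transform mapping structural-space points into
#'   `v`'s space (from `register_rigid(v, structural)`); identity when `NULL`.
#' @param affine Optional pre-estimated subject-to-template
#'   [affine_transform()]; pass the same object for every volume of a case.
#' @param pre_aligned If `TRUE`, `v` is asserted to be on the template grid
#'   already and returned unchanged (decouples detection from registration).
#' @return A [volume()] on the template grid.
#' @export
standardize <- function(v, structural, template, rigid = NULL, affine = NULL,
                        pre_aligned = FALSE) {
  stopifnot(inherits(v, "perf_volume"))
  if (pre_aligned) {
    if (!grids_equal(v, template))
      stop("contract error: `pre_aligned` volume is not on the template grid",
           call. = FALSE)
    return(v)
  }
  if (is.null(affine)) affine <- estimate_affine(structural, template)
  total <- invert_transform(affine)           # template -> structural
  if (!is.null(rigid)) total <- compose_transforms(rigid, total)
  apply_transform(v, total, template$grid, "linear")
}

#' Standardize a full phantom/patient case with shared parameters
#'
#' Registers each SPECT scan rigidly to the structural volume, estimates the
#' structural-to-template affine once, and standardizes every volume of the
#' case with the same affine parameters.
#'
#' @param case A list with `postictal`, optional `interictal`, and
#'   `structural` [volume()] fields (e.g. a [simulate_case()] package).
#' @param template A [make_template()] object.
#' @param pre_aligned If `TRUE`, volumes are assumed to be on the template
#'   grid already and only checked.
#' @return The case with `postictal`/`interictal` replaced by standardized
#'   volumes, plus `rigid_postictal`, `rigid_interictal` and `affine` entries.
#' @export
standardize_case <- function(case, template, pre_aligned = FALSE) {
  if (pre_aligned) {
    case$postictal <- standardize(case$postictal, template = template,
                                  pre_aligned = TRUE)
    if (!is.null(case$interictal))
      case$interictal <- standardize(case$interictal, template = template,
                                     pre_aligned = TRUE)
    return(case)
  }
  affine <- estimate_affine(case$structural, template)
  rig_p <- register_rigid(case$postictal, case$structural)
  case$rigid_postictal <- rig_p
  case$postictal <- standardize(case$postictal, case$structural, template,
                                rigid = rig_p, affine = affine)
  if (!is.null(case$interictal)) {
    rig_i <- register_rigid(case$interictal, case$structural)
    case$rigid_interictal <- rig_i
    case$interictal <- standardize(case$interictal, case$structural, template,
                                   rigid = rig_i, affine = affine)
  }
  case$affine <- affine
  case
}
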