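# Synthetic stroke-brain phantom generator.
#
# Emulates the image structure the asymmetry method assumes: a hemispheric
# stroke lesion with near-zero uptake, a hypoperfused penumbral rim, an
# optional focal hyperperfusion island adjacent to the lesion ("island in
# the sea"), Poisson-like count noise, and optional rigid misalignment
# between scans.

#' Phantom case specification
#'
#' @param seed Integer RNG seed; the whole case is deterministic given the
#'   seed.
#' @param lesion List: `present`, `center` (mm, must sit in one hemisphere),
#'   `radius` (mm), `intensity_fraction` of the underlying uptake (default
#'   0.10).
#' @param penumbra List: `width` (shell thickness mm outside the lesion),
#'   `intensity_fraction` (default 0.7).
#' @param island List: `present`, `offset` (mm from the lesion edge to the
#'   island centre, must be at most `max_offset`), `radius` (mm),
#'   `amplitude` (added uptake as a fraction of cortical intensity),
#'   `direction` (3-vector from the lesion centre), `chronic` (if `TRUE` the
#'   island is present in both scans).
#' @param noise List: `count_scale` -- intensity-to-counts factor for
#'   Poisson noise (`counts ~ Poisson(intensity * count_scale)`, returned as
#'   `counts / count_scale`); 0 disables noise.
#' @param misalignment Optional [rigid_transform()] applied to the raw
#'   postictal scan (to exercise registration).
#' @param interictal Generate an interictal scan too?
#' @param max_offset Maximum allowed island offset in mm (adjacency
#'   invariant; default 50).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         lesion = list(),
                         penumbra = list(),
                         island = list(),
                         noise = list(),
                         misalignment = NULL,
                         interictal = TRUE,
                         max_offset = 50) {
  lesion <- utils::modifyList(
    list(present = TRUE, center = c(32, 12, 8), radius = 14,
         intensity_fraction = 0.10), lesion)
  penumbra <- utils::modifyList(
    list(width = 6, intensity_fraction = 0.7), penumbra)
  island <- utils::modifyList(
    list(present = TRUE, offset = 10, radius = 8, amplitude = 0.8,
         direction = c(0.3, 0.9, 0.3), chronic = FALSE), island)
  noise <- utils::modifyList(list(count_scale = 2), noise)
  if (island$present && island$offset > max_offset)
    stop("spec error: island offset exceeds the adjacency limit (",
         max_offset, " mm)", call. = FALSE)
  if (lesion$present && abs(lesion$center[1L]) <= lesion$radius)
    stop("spec error: lesion must lie entirely within one hemisphere",
         call. = FALSE)
  if (noise$count_scale < 0)
    stop("spec error: noise count_scale must be non-negative", call. = FALSE)
  structure(list(seed = as.integer(seed), lesion = lesion,
                 penumbra = penumbra, island = island, noise = noise,
                 misalignment = misalignment, interictal = interictal),
            class = "phantom_spec")
}

sphere_mask <- function(template, center, radius) {
  co <- template$coords
  (co$x - center[1L])^2 + (co$y - center[2L])^2 + (co$z - center[3L])^2 <=
    radius^2
}

# base SPECT uptake pattern on the template tissue classes
base_uptake <- function(template, cortex = 100, white = 60, csf = 15) {
  a <- array(0, template$grid$dim)
  a[template$brain_mask] <- white
  a[template$cortex_mask] <- cortex
  a[template$ventricle_mask] <- csf
  a
}

add_poisson_noise <- function(a, count_scale) {
  if (count_scale <= 0) return(a)
  pos <- a > 0
  a[pos] <- stats::rpois(sum(pos), a[pos] * count_scale) / count_scale
  a
}

#' Simulate one phantom case
#'
#' Builds the postictal (and optionally interictal) SPECT, a FLAIR-like
#' structural volume on 5 mm slices, and ground-truth masks, all
#' deterministically from the spec seed. The scans are generated in standard
#' space; optional rigid misalignment is applied to the raw postictal scan
#' afterwards so registration can be exercised or bypassed.
#'
#' @param spec A [phantom_spec()].
#' @param template A [make_template()] object.
#' @param cortical_intensity Cortical uptake level (arbitrary counts).
#' @return An object of class `phantom_case`: list with `postictal`,
#'   `interictal` (or `NULL`), `structural`, `truth` (lesion/island masks,
#'   laterality, region), and `spec`.
#' @export
simulate_case <- function(spec, template, cortical_intensity = 100) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(template, "perf_template"))
  set.seed(spec$seed)
  g <- template$grid
  base <- base_uptake(template, cortex = cortical_intensity)

  lesion_mask <- array(FALSE, g$dim)
  penumbra_mask <- array(FALSE, g$dim)
  if (spec$lesion$present) {
    lesion_mask <- sphere_mask(template, spec$lesion$center,
                               spec$lesion$radius) & template$brain_mask
    penumbra_mask <- sphere_mask(template, spec$lesion$center,
                                 spec$lesion$radius + spec$penumbra$width) &
      template$brain_mask & !lesion_mask
  }

  island_mask <- array(FALSE, g$dim)
  island_center <- NULL
  if (spec$island$present) {
    if (!spec$lesion$present)
      stop("spec error: an island requires a lesion to be adjacent to",
           call. = FALSE)
    u <- spec$island$direction / sqrt(sum(spec$island$direction^2))
    island_center <- spec$lesion$center +
      u * (spec$lesion$radius + spec$island$offset)
    island_mask <- sphere_mask(template, island_center, spec$island$radius) &
      template$brain_mask
    if (any(island_mask & template$ventricle_mask))
      stop("spec error: island collides with the ventricle mask",
           call. = FALSE)
  }

  shape <- base
  shape[penumbra_mask] <- shape[penumbra_mask] * spec$penumbra$intensity_fraction
  shape[lesion_mask] <- base[lesion_mask] * spec$lesion$intensity_fraction
  interictal_shape <- shape
  postictal_shape <- shape
  bump <- spec$island$amplitude * cortical_intensity
  if (spec$island$present) {
    postictal_shape[island_mask] <- postictal_shape[island_mask] + bump
    if (spec$island$chronic)
      interictal_shape[island_mask] <- interictal_shape[island_mask] + bump
  }

  post <- volume(add_poisson_noise(postictal_shape, spec$noise$count_scale),
                 g$spacing, g$origin)
  inter <- NULL
  if (spec$interictal)
    inter <- volume(add_poisson_noise(interictal_shape, spec$noise$count_scale),
                    g$spacing, g$origin)

  if (!is.null(spec$misalignment))
    post <- apply_transform(post, spec$misalignment, g, "linear")

  struct_hi <- template$reference$data
  if (spec$lesion$present)          # FLAIR-hyperintense infarct
    struct_hi[lesion_mask] <- struct_hi[lesion_mask] + 60
  struct_hi <- volume(struct_hi, g$spacing, g$origin)
  nz <- ceiling(g$dim[3L] * g$spacing[3L] / 5)
  structural <- resample_to_grid(
    struct_hi, grid_spec(c(g$dim[1:2], nz), c(g$spacing[1:2], 5),
                         c(g$origin[1:2], g$origin[3L])), "linear")

  laterality <- "none"
  region <- NA_character_
  if (spec$island$present) {
    laterality <- if (island_center[1L] < 0) "left" else "right"
    cidx <- round(mm_to_vox(g, matrix(island_center, 1)))
    lab <- template$atlas[cidx[1L], cidx[2L], cidx[3L]]
    if (lab > 0L)
      region <- template$label_table$region[template$label_table$label == lab]
  }

  structure(list(postictal = post, interictal = inter,
                 structural = structural,
                 truth = list(lesion_mask = lesion_mask,
                              penumbra_mask = penumbra_mask,
                              island_mask = island_mask,
                              laterality = laterality,
                              region = region),
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d, lesion %s, island %s (laterality %s)\n",
              x$spec$seed,
              if (x$spec$lesion$present) "present" else "absent",
              if (x$spec$island$present) "present" else "absent",
              x$truth$laterality))
  invisible(x)
}

#' Simulate a cohort of phantom cases
#'
#' Generates `n` cases of which exactly `round(n * prevalence)` carry a
#' postictal island; per-case seeds and the positive/negative assignment are
#' derived deterministically from the master seed.
#'
#' @param n Number of cases.
#' @param prevalence Proportion of island-positive cases (0 to 1).
#' @param base_spec A [phantom_spec()] used as the per-case template.
#' @param template A [make_template()] object.
#' @param seed Master seed.
#' @return A list with `cases` (list of [simulate_case()] packages) and
#'   `truth` (data frame: case_id, island_present, laterality, region).
#' @export
simulate_cohort <- function(n, prevalence, base_spec, template, seed = 1L) {
  if (prevalence < 0 || prevalence > 1)
    stop("`prevalence` must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L)
    return(list(cases = list(),
                truth = data.frame(case_id = integer(),
                                   island_present = logical(),
                                   laterality = character(),
                                   region = character())))
  set.seed(seed)
  n_pos <- as.integer(round(n * prevalence))
  pos <- rep(FALSE, n)
  pos[sample.int(n, n_pos)] <- TRUE
  case_seeds <- (as.integer(seed) %% 100000L) * 20000L + seq_len(n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- case_seeds[i]
    sp$island$present <- pos[i]
    cases[[i]] <- simulate_case(sp, template)
  }
  truth <- data.frame(
    case_id = seq_len(n),
    island_present = pos,
    laterality = vapply(cases, function(cc) cc$truth$laterality, character(1)),
    region = vapply(cases, function(cc) {
      r <- cc$truth$region
      if (is.na(r)) NA_character_ else r
    }, character(1)),
    stringsAsFactors = FALSE)
  list(cases = cases, truth = truth)
}

#' Calibrate the island amplitude to a target peak z
#'
#' The pipeline's z-map is self-standardized, so the island peak z is not an
#' input parameter. Peak z rises monotonically with amplitude but not quite
#' linearly (the stroke mask and normalization themselves depend on the
#' image maximum), so the helper brackets the target and refines by regula
#' falsi with bisection clamping.
#'
#' @param spec A [phantom_spec()] (its island must be present).
#' @param template A [make_template()] object.
#' @param target_z Desired island peak z (e.g. 1.8 for the fallback band).
#' @param params [asym_params()] used for probing.
#' @param probes Two starting probe amplitudes.
#' @param tol Acceptable |achieved - target| in SD units.
#' @param maxit Maximum refinement probes after bracketing.
#' @return A list with `amplitude` and `achieved_z` (from a verification
#'   run).
#' @export
calibrate_island_amplitude <- function(spec, template, target_z = 1.8,
                                       params = asym_params(),
                                       probes = c(0.3, 0.6), tol = 0.05,
                                       maxit = 12L) {
  stopifnot(spec$island$present)
  peak_z_at <- function(a) {
    sp <- spec
    sp$island$amplitude <- a
    case <- simulate_case(sp, template)
    pz <- asymmetry_zmap(case$postictal, template, params)
    max(pz$z$values[case$truth$island_mask & pz$z$include])
  }
  lo <- min(probes); hi <- max(probes)
  zlo <- peak_z_at(lo); zhi <- peak_z_at(hi)
  while (zlo > target_z && lo > 1e-3) {
    hi <- lo; zhi <- zlo
    lo <- lo / 2; zlo <- peak_z_at(lo)
  }
  while (zhi < target_z && hi < 8) {
    lo <- hi; zlo <- zhi
    hi <- hi * 2; zhi <- peak_z_at(hi)
  }
  best_a <- if (abs(zlo - target_z) < abs(zhi - target_z)) lo else hi
  best_z <- if (abs(zlo - target_z) < abs(zhi - target_z)) zlo else zhi
  for (it in seq_len(maxit)) {
    if (abs(best_z - target_z) <= tol) break
    a <- lo + (target_z - zlo) * (hi - lo) / (zhi - zlo)
    # keep the probe strictly inside the bracket
    a <- min(max(a, lo + 0.05 * (hi - lo)), hi - 0.05 * (hi - lo))
    za <- peak_z_at(a)
    if (abs(za - target_z) < abs(best_z - target_z)) {
      best_a <- a; best_z <- za
    }
    if (za < target_z) { lo <- a; zlo <- za } else { hi <- a; zhi <- za }
  }
  list(amplitude = best_a, achieved_z = best_z)
}
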