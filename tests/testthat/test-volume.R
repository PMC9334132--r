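test_that("NIfTI round trip preserves data, spacing and origin", {
  set.seed(11)
  v <- volume(array(rnorm(16^3), dim = c(16, 16, 16)),
              spacing = c(1.5, 2, 2.5), origin = c(-10, 0, 5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
})

test_that("LPS-stored images are canonicalized to RAS on read", {
  set.seed(12)
  a <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  # store the same physical image with flipped x and y axes (LPS)
  a_lps <- a[4:1, 5:1, ]
  sp <- c(2, 2, 2)
  img <- RNifti::asNifti(a_lps, reference = list(pixdim = c(1, sp, 0, 0, 0, 0)))
  # RAS affine of the original: origin (0,0,0); LPS version starts at the
  # opposite corner with negated x/y directions
  m <- rbind(c(-sp[1], 0, 0, (4 - 1) * sp[1]),
             c(0, -sp[2], 0, (5 - 1) * sp[2]),
             c(0, 0, sp[3], 0),
             c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- read_volume(f)
  expect_equal(v$data, a)
  expect_equal(v$origin, c(0, 0, 0), tolerance = 1e-6)
})

test_that("4-D and oblique inputs are rejected with a format error", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 3))), f)
  expect_error(read_volume(f), "3-D")
  # oblique: 30-degree rotation in the xy plane
  img <- RNifti::asNifti(array(0, dim = c(4, 4, 4)))
  c30 <- cos(pi / 6); s30 <- sin(pi / 6)
  m <- rbind(c(c30, -s30, 0, 0), c(s30, c30, 0, 0), c(0, 0, 1, 0),
             c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2)
  expect_error(read_volume(f2), "oblique|non-orthogonal")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "exist")
})

test_that("resampling 5 mm slices to 2 mm covers the same extent", {
  # 10 slices at 5 mm: z coordinates 0..45; a linear ramp in z
  d <- c(6, 6, 10)
  zs <- (seq_len(d[3]) - 1) * 5
  a <- array(rep(zs, each = d[1] * d[2]), d)
  v <- volume(a, spacing = c(5, 5, 5), origin = c(0, 0, 0))
  tgt <- grid_spec(c(6, 6, 23), c(5, 5, 2), c(0, 0, 0))  # 0..44 mm
  r <- resample_to_grid(v, tgt, "linear")
  expect_equal(dim(r$data), c(6L, 6L, 23L))
  # linear interpolation reproduces the ramp at every 2 mm position
  expect_equal(r$data[3, 3, ], (seq_len(23) - 1) * 2, tolerance = 1e-10)
  # midpoint between slice values 10 and 20 is 15
  v2 <- volume(array(c(10, 20), dim = c(1, 1, 2)), spacing = c(1, 1, 5))
  mid <- resample_to_grid(v2, grid_spec(c(1, 1, 1), c(1, 1, 1),
                                        c(0, 0, 2.5)), "linear")
  expect_equal(as.numeric(mid$data), 15)
})

test_that("resampling to the identical grid is exact", {
  set.seed(13)
  v <- volume(array(rnorm(5 * 6 * 7), dim = c(5, 6, 7)),
              spacing = c(2, 2, 2), origin = c(-4, -5, -6))
  r <- resample_to_grid(v, as_grid(v), "nearest")
  expect_identical(r$data, v$data)
  expect_error(resample_to_grid(v, grid_spec(c(5, 6, 7), c(0, 2, 2),
                                             c(0, 0, 0))),
               "degenerate|positive")
})

test_that("Gaussian smoothing: sigma conversion, mass conservation, kernel", {
  expect_equal(fwhm_to_sigma(10), 4.2466, tolerance = 1e-4)
  d <- c(33, 33, 33)
  a <- array(0, d); a[17, 17, 17] <- 1
  v <- volume(a, spacing = c(2, 2, 2), origin = -c(32, 32, 32))
  sm <- gaussian_smooth(v, 10)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  # impulse response equals the separable sampled-Gaussian kernel
  sigma_vox <- fwhm_to_sigma(10) / 2
  r <- ceiling(4 * sigma_vox)
  k <- dnorm(seq(-r, r), sd = sigma_vox); k <- k / sum(k)
  k0 <- k[r + 1]; k1 <- k[r + 2]
  expect_equal(sm$data[17, 17, 17], k0^3, tolerance = 1e-10)
  expect_equal(sm$data[18, 17, 17], k1 * k0^2, tolerance = 1e-10)
  expect_equal(sm$data[17, 18, 17], k1 * k0^2, tolerance = 1e-10)
  expect_equal(sm$data[17, 17, 16], k1 * k0^2, tolerance = 1e-10)
  expect_error(gaussian_smooth(v, 0), "positive")
})

test_that("left-right flip is an involution and reverses the LR axis", {
  set.seed(14)
  v <- volume(array(rnorm(7 * 5 * 5), dim = c(7, 5, 5)))
  expect_identical(flip_lr(flip_lr(v))$data, v$data)
  row <- volume(array(c(1, 2, 3), dim = c(3, 1, 1)))
  expect_equal(as.numeric(flip_lr(row)$data), c(3, 2, 1))
  sym <- volume(array(rep(c(1, 2, 3, 2, 1), 4), dim = c(5, 2, 2)))
  expect_identical(flip_lr(sym)$data, sym$data)
  even <- volume(array(0, dim = c(4, 4, 4)))
  expect_error(flip_lr(even), "odd|midline")
  tpl <- test_template()
  off_grid <- volume(array(0, dim = c(7, 7, 7)))
  expect_error(flip_lr(off_grid, tpl), "standard|grid")
})

test_that("brain mask: template pass-through, heuristic accuracy, errors", {
  tpl <- test_template()
  v <- volume(array(1, tpl$grid$dim), tpl$grid$spacing, tpl$grid$origin)
  expect_identical(compute_brain_mask(v, tpl), tpl$brain_mask)
  # ellipsoid at 100 in air: heuristic mask vs the generating mask
  ph <- volume(tpl$brain_mask * 100, tpl$grid$spacing, tpl$grid$origin)
  m <- compute_brain_mask(ph)
  dice <- 2 * sum(m & tpl$brain_mask) / (sum(m) + sum(tpl$brain_mask))
  expect_gt(dice, 0.95)
  zero <- volume(array(0, c(8, 8, 8)))
  expect_error(compute_brain_mask(zero), "empty")
})

test_that("stroke mask flags exactly the voxels below the fraction of max", {
  set.seed(15)
  a <- array(runif(10^3, 50, 200), dim = c(10, 10, 10))
  a[1, 1, 1] <- 200  # pin the maximum
  brain <- array(TRUE, dim(a))
  v <- volume(a)
  m <- compute_stroke_mask(v, brain, 0.30)
  expect_identical(m, brain & (a < 60))
  # uniform brain: nothing below 30% of max
  u <- volume(array(100, c(6, 6, 6)))
  expect_false(any(compute_stroke_mask(u, array(TRUE, c(6, 6, 6)), 0.30)))
  expect_error(compute_stroke_mask(v, brain, 1.2), "between 0 and 1")
})

test_that("automatic stroke mask covers the planted lesion core", {
  tpl <- test_template()
  case <- simulate_case(phantom_spec(seed = 21, island = list(present = FALSE)),
                        tpl)
  sm <- gaussian_smooth(case$postictal, 10)
  mask <- compute_stroke_mask(sm, tpl$brain_mask, 0.30)
  # core: lesion eroded by the smoothing scale (edges are blurred outward)
  core <- blob_mask(tpl, c(32, 12, 8), 14 - 4) & tpl$brain_mask
  expect_gte(sum(mask & core) / sum(core), 0.95)
})

test_that("global-mean normalization is exact and scale invariant", {
  set.seed(16)
  a <- array(runif(8^3, 10, 90), dim = c(8, 8, 8))
  v <- volume(a)
  include <- array(runif(8^3) > 0.3, dim(a))
  n1 <- normalize_global_mean(v, include, 100)
  expect_equal(mean(n1$data[include]), 100, tolerance = 1e-9)
  n2 <- normalize_global_mean(volume(a * 7.3), include, 100)
  expect_equal(n2$data, n1$data, tolerance = 1e-12)
  const <- normalize_global_mean(volume(array(50, c(4, 4, 4))),
                                 array(TRUE, c(4, 4, 4)), 100)
  expect_true(all(const$data == 100))
  neg <- volume(array(-1, c(4, 4, 4)))
  expect_error(normalize_global_mean(neg, array(TRUE, c(4, 4, 4))),
               "numeric error|non-positive")
})
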