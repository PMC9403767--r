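# Volume data model, NIfTI round trips, resampling, FWHM normalization.

test_that("NIfTI round trips preserve masks exactly and floats to 1e-6", {
  td <- withr::local_tempdir()
  ph <- small_phantom(seed = 3, shape = c(8, 20, 20))

  write_volume(ph$disease, file.path(td, "m.nii.gz"))
  m2 <- read_volume(file.path(td, "m.nii.gz"), kind = "disease")
  expect_identical(m2$voxels, ph$disease$voxels)
  expect_equal(m2$spacing, ph$disease$spacing, tolerance = 1e-6)

  write_volume(ph$image, file.path(td, "i.nii.gz"))
  i2 <- read_volume(file.path(td, "i.nii.gz"))
  expect_lt(max(abs(i2$voxels - ph$image$voxels)), 1e-6)

  pm <- synth_probability_map(ph$disease, 2, 0.05, rng_seed = 1)
  write_volume(pm, file.path(td, "p.nii.gz"))
  p2 <- read_volume(file.path(td, "p.nii.gz"), kind = "prob")
  expect_lt(max(abs(p2$voxels - pm$voxels)), 1e-6)

  expect_error(write_volume(ph$image, file.path(td, "no-such-dir", "x.nii")),
               "directory")
})

test_that("read_volume rejects non-3D images and passes the header through", {
  td <- withr::local_tempdir()
  arr4 <- array(0, dim = c(4, 4, 4, 2))
  RNifti::writeNifti(RNifti::asNifti(arr4), file.path(td, "four.nii.gz"))
  expect_error(read_volume(file.path(td, "four.nii.gz")), "3D")
  expect_error(read_volume(file.path(td, "absent.nii.gz")), "absent")

  img <- RNifti::asNifti(array(rnorm(4 * 5 * 6), dim = c(6, 5, 4)))
  RNifti::pixdim(img) <- c(0.7, 0.8, 2.5)  # x, y, z mm
  RNifti::writeNifti(img, file.path(td, "thick.nii.gz"))
  v <- read_volume(file.path(td, "thick.nii.gz"))
  expect_equal(v$spacing[1], 2.5, tolerance = 1e-6)  # slice thickness first
  expect_equal(dim(v$voxels), c(4, 5, 6))
})

test_that("volume constructors enforce their invariants", {
  expect_error(ct_volume(array(c(1, NaN), dim = c(2, 1, 1)), c(1, 1, 1)),
               "finite")
  expect_error(ct_volume(array(1, dim = c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(binary_mask(array(0.5, dim = c(2, 2, 2)), c(1, 1, 1)),
               "0 or 1")
  expect_error(probability_map(array(1.5, dim = c(2, 2, 2)), c(1, 1, 1)),
               "\\[0, 1\\]")
})

test_that("resampling follows the round(n*s_old/s_new) size rule", {
  v <- ct_volume(array(rnorm(10 * 20 * 20), dim = c(10, 20, 20)),
                 spacing = c(5, 0.75, 0.75))
  r <- resample_to_spacing(v, c(1, 0.75, 0.75))
  expect_equal(dim(r$voxels), c(50, 20, 20))

  same <- resample_to_spacing(v, v$spacing)
  expect_equal(dim(same$voxels), dim(v$voxels))
  expect_lt(max(abs(same$voxels - v$voxels)), 1e-6)

  const <- ct_volume(array(100, dim = c(6, 8, 8)), spacing = c(2, 1, 1))
  rc <- resample_to_spacing(const, c(1.3, 0.7, 0.9))
  expect_true(all(abs(rc$voxels - 100) < 1e-9))

  expect_error(resample_to_spacing(v, c(0, 1, 1)), "positive")
})

test_that("mask resampling interpolates linearly then thresholds at 0.5", {
  arr <- zeros3(c(6, 10, 10))
  arr[2:5, 3:8, 3:8] <- 1
  m <- mask_from_array(arr, spacing = c(2, 1, 1))
  r <- resample_to_spacing(m, c(1, 1, 1))
  expect_true(all(r$voxels %in% c(0, 1)))
  expect_equal(dim(r$voxels), c(12, 10, 10))
  # nearest-neighbor mapping back reproduces the original exactly
  back <- resample_mask_to_grid(r, m)
  expect_identical(back$voxels, m$voxels)
})

test_that("fwhm_stats recovers the generating Gaussian inside the liver", {
  d <- c(40, 50, 50)
  liver <- mask_from_array(array(1, dim = d), kind = "liver")
  for (seed in 1:5) {
    set.seed(seed)
    v <- ct_volume(array(rnorm(prod(d), 100, 15), dim = d), c(1, 1, 1))
    st <- fwhm_stats(v, liver)
    expect_lt(abs(st$center - 100), 1)
    expect_lt(abs(st$sigma - 15), 1)
    expect_equal(st$fwhm, st$sigma * 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  }
})

test_that("fwhm_stats locks onto the dominant mode of a mixture", {
  d <- c(40, 50, 50)
  liver <- mask_from_array(array(1, dim = d), kind = "liver")
  set.seed(11)
  n <- prod(d)
  vals <- c(rnorm(round(0.8 * n), 90, 10), rnorm(n - round(0.8 * n), 300, 20))
  v <- ct_volume(array(sample(vals), dim = d), c(1, 1, 1))
  st <- fwhm_stats(v, liver)
  expect_lt(abs(st$center - 90), 2)
  expect_lt(abs(st$sigma - 10), 2)
})

test_that("fwhm_stats fails cleanly on degenerate histograms", {
  d <- c(4, 4, 4)
  liver <- mask_from_array(array(1, dim = d), kind = "liver")
  flat <- ct_volume(array(50, dim = d), c(1, 1, 1))
  expect_error(fwhm_stats(flat, liver), "degenerate")
  empty <- mask_from_array(zeros3(d), kind = "liver")
  expect_error(fwhm_stats(flat, empty), "empty")
  expect_error(fwhm_stats(flat, liver, bin_width = 0), "bin_width")
})

test_that("normalize_in_mask standardizes inside and zeroes outside", {
  d <- c(20, 30, 30)
  arr <- array(0, dim = d)
  liver_arr <- zeros3(d)
  liver_arr[5:16, 5:26, 5:26] <- 1
  set.seed(2)
  arr[liver_arr == 1] <- rnorm(sum(liver_arr), 100, 15)
  arr[liver_arr == 0] <- rnorm(sum(liver_arr == 0), -500, 300)
  v <- ct_volume(arr, c(1, 1, 1))
  liver <- mask_from_array(liver_arr, kind = "liver")
  st <- list(center = 100, sigma = 15)
  nz <- normalize_in_mask(v, liver, st)
  expect_true(all(nz$voxels[liver_arr == 0] == 0))
  inside <- nz$voxels[liver_arr == 1]
  expect_lt(abs(mean(inside)), 0.05)
  expect_lt(abs(sd(inside) - 1), 0.05)
  # a voxel exactly at the center maps to 0
  v$voxels[6, 6, 6] <- 100
  nz2 <- normalize_in_mask(v, liver, st)
  expect_equal(nz2$voxels[6, 6, 6], 0)
  # grid mismatch is an error
  other <- mask_from_array(zeros3(c(4, 4, 4)), kind = "liver")
  expect_error(normalize_in_mask(v, other, st), "grid")
})

test_that("disease labels outside the liver are clipped with a warning", {
  d <- c(6, 6, 6)
  liver <- mask_from_array({
    a <- zeros3(d); a[2:5, 2:5, 2:5] <- 1; a
  }, kind = "liver")
  dis <- mask_from_array({
    a <- zeros3(d); a[1:3, 2:4, 2:4] <- 1; a
  })
  expect_warning(clipped <- clip_disease_to_liver(dis, liver), "outside")
  expect_true(all(clipped$voxels * (1 - liver$voxels) == 0))
})
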