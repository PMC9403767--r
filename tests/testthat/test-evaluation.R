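# Dice, surface distances, site matching, sensitivity, false-positive
# decomposition and the cohort report.

box_mask <- function(d, lo, hi, spacing = c(1, 1, 1)) {
  arr <- zeros3(d)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  mask_from_array(arr, spacing)
}

test_that("dice follows 2|A∩B|/(|A|+|B|) with the empty-mask convention", {
  d <- c(6, 8, 8)
  a <- box_mask(d, c(2, 2, 2), c(3, 3, 3))  # 8 voxels
  expect_equal(dice(a, a), 1)
  b <- box_mask(d, c(5, 5, 5), c(6, 6, 6))
  expect_equal(dice(a, b), 0)
  # |A|=8, |B|=8, overlap 4
  c_ <- box_mask(d, c(2, 2, 3), c(3, 3, 4))
  expect_equal(dice(a, c_), 0.5)
  expect_equal(dice(a, c_), dice(c_, a))
  e <- mask_from_array(zeros3(d))
  expect_equal(dice(e, e), 1)
  expect_equal(dice(a, e), 0)
  expect_error(dice(a, mask_from_array(zeros3(c(2, 2, 2)))), "grid")
})

test_that("global dice stacks patients instead of averaging them", {
  d <- c(4, 4, 4)
  a1 <- box_mask(d, c(1, 1, 1), c(2, 2, 2))           # 8 voxels
  b1 <- box_mask(d, c(1, 1, 2), c(2, 2, 3))           # overlap 4
  a2 <- box_mask(d, c(4, 4, 1), c(4, 4, 2))           # 2 voxels
  b2 <- box_mask(d, c(1, 4, 4), c(2, 4, 4))           # disjoint, 2 voxels
  g <- global_dice(list(list(a1, b1), list(a2, b2)))
  expect_equal(g, 2 * 4 / (8 + 8 + 2 + 2))            # 0.4
  expect_equal(mean(c(dice(a1, b1), dice(a2, b2))), 0.25)
  expect_equal(global_dice(list(list(a1, b1))), dice(a1, b1))
  e <- mask_from_array(zeros3(d))
  expect_equal(global_dice(list(list(e, e))), 1)
  expect_error(global_dice(list()), "empty")
})

test_that("median surface distance handles plates, spacing and emptiness", {
  d <- c(10, 8, 8)
  a <- box_mask(d, c(3, 2, 2), c(3, 7, 7))
  expect_equal(median_surface_distance(a, a), 0)
  b <- box_mask(d, c(6, 2, 2), c(6, 7, 7))     # offset 3 voxels at 1 mm
  expect_equal(median_surface_distance(a, b), 3)
  a25 <- box_mask(d, c(3, 2, 2), c(3, 7, 7), spacing = c(2.5, 1, 1))
  b25 <- box_mask(d, c(5, 2, 2), c(5, 7, 7), spacing = c(2.5, 1, 1))
  expect_equal(median_surface_distance(a25, b25), 5)
  e <- mask_from_array(zeros3(d))
  expect_true(is.na(median_surface_distance(a, e)))
})

test_that("median surface distance matches the exhaustive oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- random_mask(c(9, 9, 9), p = 0.4, spacing = c(2, 1.5, 1.5))
    b <- random_mask(c(9, 9, 9), p = 0.4, spacing = c(2, 1.5, 1.5))
    if (sum(a$voxels) == 0 || sum(b$voxels) == 0) next
    expect_equal(median_surface_distance(a, b),
                 oracle_msd(a$voxels, b$voxels, a$spacing))
  }
})

test_that("surface distance is invariant under joint translation", {
  d <- c(12, 12, 12)
  a <- box_mask(d, c(2, 2, 2), c(4, 5, 4))
  b <- box_mask(d, c(3, 3, 3), c(6, 6, 6))
  shift <- function(m) {
    arr <- zeros3(d)
    arr[4:12, 4:12, 4:12] <- m$voxels[1:9, 1:9, 1:9]
    mask_from_array(arr, m$spacing)
  }
  expect_equal(median_surface_distance(shift(a), shift(b)),
               median_surface_distance(a, b))
})

test_that("sites match to the nearest predicted centroid, with reuse", {
  d <- c(20, 20, 20)
  gt <- box_mask(d, c(10, 10, 10), c(11, 11, 11))
  pr_arr <- zeros3(d)
  pr_arr[12:13, 10:11, 10:11] <- 1   # ~2 mm away
  pr_arr[18:19, 18:19, 18:19] <- 1   # far blob
  pred <- mask_from_array(pr_arr, kind = "prediction")
  m <- match_sites(label_components(gt), label_components(pred))
  expect_equal(nrow(m), 1)
  expect_equal(m$pred_id, 1L)  # nearer component (first in scan order)

  # no predictions: unmatched
  m0 <- match_sites(label_components(gt),
                    label_components(mask_from_array(zeros3(d))))
  expect_true(is.na(m0$pred_id))

  # two ground-truth sites may share one prediction
  gt2_arr <- zeros3(d)
  gt2_arr[4:5, 4:5, 4:5] <- 1
  gt2_arr[4:5, 8:9, 4:5] <- 1
  pr2 <- box_mask(d, c(4, 6, 4), c(5, 7, 5))
  m2 <- match_sites(label_components(mask_from_array(gt2_arr)),
                    label_components(pr2))
  expect_equal(m2$pred_id, c(1L, 1L))
})

test_that("detection uses the inclusive 45% overlap boundary", {
  d <- c(5, 10, 10)
  gt <- box_mask(d, c(2, 1, 1), c(3, 5, 10))  # 100 voxels
  cover <- function(n) {
    idx <- which(gt$voxels == 1)[seq_len(n)]
    arr <- zeros3(d); arr[idx] <- 1
    mask_from_array(arr, kind = "prediction")
  }
  expect_true(site_sensitivity(gt, cover(45))$detected)
  expect_false(site_sensitivity(gt, cover(44))$detected)
  full <- site_sensitivity(gt, cover(100))
  expect_equal(full$fraction, 1)
  expect_true(full$detected)
  # fractional boundary is exact: 0.45 detects, 0.4499 does not
  g2 <- box_mask(c(4, 50, 50), c(1, 1, 1), c(4, 50, 50))
  expect_true(site_sensitivity(g2, g2, min_overlap = 0.45)$detected)
  expect_error(site_sensitivity(mask_from_array(zeros3(d)), gt), "empty")
})

test_that("false-positive volume splits exactly into erroneous + overseg", {
  d <- c(10, 12, 12)
  gt <- box_mask(d, c(3, 3, 3), c(6, 7, 7))            # 100 voxels
  pr_arr <- gt$voxels
  pr_arr[7, 3:7, 3:4] <- 1          # 10 extra voxels attached to the GT blob
  pr_arr[9:10, 10:11, 8:12] <- 1    # disjoint 20-voxel blob
  pred <- mask_from_array(pr_arr, kind = "prediction")
  fp <- false_positive_metrics(gt, pred)
  expect_equal(fp$discoveries, 1)
  expect_equal(fp$fp_cc, 0.030)
  expect_equal(fp$erroneous_cc, 0.020)
  expect_equal(fp$overseg_cc, 0.010)

  sub <- box_mask(d, c(4, 4, 4), c(5, 5, 5))
  fp2 <- false_positive_metrics(gt, sub)
  expect_equal(unlist(fp2), c(discoveries = 0, fp_cc = 0, erroneous_cc = 0,
                              overseg_cc = 0))
  fp3 <- false_positive_metrics(gt, gt)
  expect_equal(fp3$discoveries, 0)
  expect_equal(fp3$fp_cc, 0)
})

test_that("fp conservation holds on random mask pairs", {
  for (seed in 1:20) {
    set.seed(seed)
    gt <- random_mask(c(10, 10, 10), p = 0.2, spacing = c(2, 0.7, 0.7))
    pr <- random_mask(c(10, 10, 10), p = 0.2, spacing = c(2, 0.7, 0.7))
    fp <- false_positive_metrics(gt, pr)
    expect_lt(abs(fp$erroneous_cc + fp$overseg_cc - fp$fp_cc), 1e-9)
    expect_gte(fp$erroneous_cc, 0)
    expect_gte(fp$overseg_cc, -1e-12)
  }
})

test_that("equivalent diameter inverts the sphere volume", {
  expect_equal(equivalent_diameter(1), (6000 / pi)^(1 / 3))       # ~12.41
  expect_equal(equivalent_diameter(0.001), (6 / pi)^(1 / 3))      # ~1.24
  expect_error(equivalent_diameter(0), "> 0")
  # rasterized 10 mm radius sphere
  spec <- phantom_spec(c(30, 30, 30), c(1.5, 1.5, 1.5),
                       liver = list(center = c(21, 21, 21),
                                    semiaxes = c(18, 18, 18)),
                       lesions = list(list(center = c(21, 21, 21),
                                           diameter = 20, hu_offset = -40)),
                       rng_seed = 1)
  ph <- generate_phantom(spec)
  cs <- label_components(ph$disease)
  expect_lt(abs(equivalent_diameter(cs$volumes_cc[1]) - 20) / 20, 0.05)
})

test_that("a perfect case gives perfect patient and cohort metrics", {
  ph <- small_phantom(seed = 2)
  res <- evaluate_cohort(list(list(gt = ph$disease, pred = ph$disease)))
  expect_equal(res$global_dsc, 1)
  expect_equal(res$patient_table$dsc, 1)
  expect_equal(res$patient_table$false_positive_volume_cc, 0)
  expect_equal(res$site_table$sensitivity, rep(1, nrow(res$site_table)))
  expect_equal(res$patients[[1]]$median_surface_distance_mm, 0)
})

test_that("cohort sensitivity equals the planted detection fraction", {
  d <- c(10, 30, 30)
  cases <- list()
  planted <- 0; total <- 0
  for (i in 1:4) {
    gt_arr <- zeros3(d)
    gt_arr[3:6, 3:10, 3:10] <- 1       # big site, will be predicted
    gt_arr[3:4, 20:22, 20:22] <- 1     # small site, detected on even i
    pred_arr <- zeros3(d)
    pred_arr[3:6, 3:10, 3:10] <- 1
    total <- total + 2
    planted <- planted + 1
    if (i %% 2 == 0) {
      pred_arr[3:4, 20:22, 20:22] <- 1
      planted <- planted + 1
    }
    cases[[i]] <- list(gt = mask_from_array(gt_arr),
                       pred = mask_from_array(pred_arr, kind = "prediction"))
  }
  res <- evaluate_cohort(cases, diameter_bins = 15)
  sites <- res$sites
  expect_equal(sum(sites$detected), planted)
  expect_equal(nrow(sites), total)
})

test_that("cohort metrics run at original resolution via NN resampling", {
  ph <- small_phantom(seed = 6)
  # prediction made on a finer processing grid
  pred_fine <- resample_to_spacing(ph$disease, c(1, 1, 1))
  res <- evaluate_cohort(list(list(gt = ph$disease, pred = pred_fine)))
  expect_gt(res$global_dsc, 0.9)
  expect_equal(dim(res$patients[[1]]$site_results)[1],
               label_components(ph$disease)$count)
})

test_that("diameter bins default to the <15 / >=15 mm strata", {
  fm <- formals(evaluate_cohort)
  expect_equal(eval(fm$diameter_bins), 15)
})
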