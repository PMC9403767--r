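# Quantitative evaluation at original image resolution: Dice on site /
# patient / global level, median surface distance, detection sensitivity at
# the 45% overlap criterion, and the decomposition of false-positive volume
# into erroneous (unconnected to any ground truth) and over-segmentation
# components.

#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A|+|B|)`; two empty masks score 1 by convention (an empty
#' mask against a non-empty one scores 0).
#'
#' @param a,b `binary_mask`s on the same grid.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_grid_mismatch(a, b, "dice")
  sa <- sum(a$voxels)
  sb <- sum(b$voxels)
  if (sa + sb == 0) return(1)
  2 * sum(a$voxels * b$voxels) / (sa + sb)
}

#' Global (stacked) Dice similarity coefficient
#'
#' All patients' masks are pooled before the ratio is taken:
#' `2 * sum_i |A_i ∩ B_i| / sum_i (|A_i| + |B_i|)`. Large patients therefore
#' weigh more than under a mean of patient-wise DSCs.
#'
#' @param pairs Non-empty list of `list(gt, pred)` mask pairs.
#' @return Global DSC in \[0, 1\].
#' @export
global_dice <- function(pairs) {
  if (length(pairs) == 0) stop("global_dice: empty case list")
  num <- den <- 0
  for (p in pairs) {
    stop_grid_mismatch(p[[1]], p[[2]], "global_dice")
    num <- num + 2 * sum(p[[1]]$voxels * p[[2]]$voxels)
    den <- den + sum(p[[1]]$voxels) + sum(p[[2]]$voxels)
  }
  if (den == 0) return(1)
  num / den
}

#' Median surface distance between two masks
#'
#' Surface voxels are foreground voxels with at least one face-adjacent
#' background voxel. Nearest-surface distances are computed symmetrically
#' (a to b and b to a, in physical mm), pooled, and the median returned.
#'
#' @param a,b Non-empty `binary_mask`s on the same grid.
#' @return Median surface distance in mm, or `NA_real_` when either mask is
#'   empty (undefined, reported as missing rather than 0).
#' @export
median_surface_distance <- function(a, b) {
  stop_grid_mismatch(a, b, "median_surface_distance")
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0) return(NA_real_)
  d <- dim(a$voxels)
  sa <- cpp_surface_voxels(as.integer(a$voxels), as.integer(d))
  sb <- cpp_surface_voxels(as.integer(b$voxels), as.integer(d))
  pooled <- c(cpp_nearest_distances(sa, sb, as.integer(d), a$spacing),
              cpp_nearest_distances(sb, sa, as.integer(d), a$spacing))
  median(pooled)
}

#' Match ground-truth sites to predicted components by centroid distance
#'
#' Every ground-truth component is matched to the predicted component whose
#' centroid is nearest in physical mm; a predicted component may serve
#' several ground-truth sites. With no predictions, all sites are unmatched.
#'
#' @param gt,pred `component_set`s.
#' @return data.frame with `gt_id`, `pred_id` (NA when unmatched) and
#'   `centroid_distance_mm`.
#' @export
match_sites <- function(gt, pred) {
  if (gt$count == 0)
    return(data.frame(gt_id = integer(0), pred_id = integer(0),
                      centroid_distance_mm = numeric(0)))
  pred_id <- rep(NA_integer_, gt$count)
  dist_mm <- rep(NA_real_, gt$count)
  if (pred$count > 0) {
    for (i in seq_len(gt$count)) {
      dd <- sqrt(colSums((t(pred$centroids) - gt$centroids[i, ])^2))
      j <- which.min(dd)
      pred_id[i] <- j
      dist_mm[i] <- dd[j]
    }
  }
  data.frame(gt_id = seq_len(gt$count), pred_id = pred_id,
             centroid_distance_mm = dist_mm)
}

#' Site detection by the 45% overlap criterion
#'
#' A disease site counts as identified when at least 45% of its ground-truth
#' voxels are covered by the union of all predicted voxels (boundary
#' inclusive).
#'
#' @param gt_component Non-empty `binary_mask` of one ground-truth site.
#' @param pred_union `binary_mask` of all predicted voxels.
#' @param min_overlap Detection threshold on the covered fraction
#'   (default 0.45).
#' @return List with `fraction` and `detected`.
#' @export
site_sensitivity <- function(gt_component, pred_union, min_overlap = 0.45) {
  stop_grid_mismatch(gt_component, pred_union, "site_sensitivity")
  n <- sum(gt_component$voxels)
  if (n == 0) stop("site_sensitivity: ground-truth component is empty")
  fraction <- sum(gt_component$voxels * pred_union$voxels) / n
  list(fraction = fraction, detected = fraction >= min_overlap)
}

#' False-positive volume decomposition
#'
#' False-positive voxels are predicted voxels outside the ground truth.
#' Erroneous volume comes from predicted components with zero ground-truth
#' overlap ("discoveries"); over-segmentation volume is the remaining
#' false-positive volume, so erroneous + over-segmentation equals the total
#' false-positive volume exactly.
#'
#' @param gt,pred `binary_mask`s on the same grid.
#' @param connectivity Component connectivity (default 26).
#' @return List with `discoveries` (count of predicted components with zero
#'   ground-truth overlap), `fp_cc`, `erroneous_cc`, `overseg_cc` (volumes in
#'   cc).
#' @export
false_positive_metrics <- function(gt, pred, connectivity = 26) {
  stop_grid_mismatch(gt, pred, "false_positive_metrics")
  vox_cc <- prod(pred$spacing) / 1000
  comps <- label_components(pred, connectivity = connectivity)
  fp <- pred$voxels * (1 - gt$voxels)
  fp_cc <- sum(fp) * vox_cc
  discoveries <- 0L
  err_vox <- 0
  if (comps$count > 0) {
    overlap <- tabulate(comps$labels[comps$labels > 0 & gt$voxels == 1],
                        nbins = comps$count)
    zero <- which(overlap == 0)
    discoveries <- length(zero)
    err_vox <- sum(comps$voxel_counts[zero])
  }
  erroneous_cc <- err_vox * vox_cc
  list(discoveries = discoveries, fp_cc = fp_cc,
       erroneous_cc = erroneous_cc, overseg_cc = fp_cc - erroneous_cc)
}

#' Sphere-equivalent diameter of a component volume
#'
#' @param volume_cc Physical volume in cc (> 0).
#' @return Diameter in mm of the sphere with the same volume,
#'   `(6V/pi)^(1/3)` with V in mm^3.
#' @export
equivalent_diameter <- function(volume_cc) {
  if (any(volume_cc <= 0))
    stop("equivalent_diameter: volume must be > 0")
  (6 * volume_cc * 1000 / pi)^(1 / 3)
}

#' Evaluate one patient
#'
#' @param gt Ground-truth disease `binary_mask` on the original grid.
#' @param pred Prediction `binary_mask` on the same grid.
#' @param connectivity Component connectivity (default 26).
#' @param min_overlap Detection threshold (default 0.45).
#' @return A `patient_result`: patient DSC, median surface distance,
#'   false-positive statistics and a per-site data.frame.
#' @export
evaluate_patient <- function(gt, pred, connectivity = 26, min_overlap = 0.45) {
  stop_grid_mismatch(gt, pred, "evaluate_patient")
  gt_cs <- label_components(gt, connectivity = connectivity)
  pred_cs <- label_components(pred, connectivity = connectivity)
  matches <- match_sites(gt_cs, pred_cs)
  fp <- false_positive_metrics(gt, pred, connectivity = connectivity)

  site_rows <- lapply(seq_len(gt_cs$count), function(k) {
    gt_k <- component_mask(gt_cs, k)
    sens <- site_sensitivity(gt_k, pred, min_overlap = min_overlap)
    pid <- matches$pred_id[k]
    if (is.na(pid)) {
      site_dsc <- 0
      msd <- NA_real_
    } else {
      pred_k <- component_mask(pred_cs, pid, kind = "prediction")
      site_dsc <- dice(gt_k, pred_k)
      msd <- median_surface_distance(gt_k, pred_k)
    }
    data.frame(
      gt_component_id = k, matched_pred_component_id = pid,
      centroid_distance_mm = matches$centroid_distance_mm[k],
      dsc = site_dsc, median_surface_distance_mm = msd,
      gt_overlap_fraction = sens$fraction, detected = sens$detected,
      equivalent_diameter_mm = equivalent_diameter(gt_cs$volumes_cc[k])
    )
  })
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gt_component_id = integer(0))
  structure(
    list(patient_id = gt$patient_id,
         dsc = dice(gt, pred),
         median_surface_distance_mm = median_surface_distance(gt, pred),
         false_positive_discoveries = fp$discoveries,
         false_positive_volume_cc = fp$fp_cc,
         erroneous_fp_volume_cc = fp$erroneous_cc,
         oversegmentation_fp_volume_cc = fp$overseg_cc,
         site_results = sites),
    class = "patient_result"
  )
}

#' @export
print.patient_result <- function(x, ...) {
  cat(sprintf("<patient_result> %s: DSC %.3f, MSD %s mm, FP %.2f cc (%d discoveries)\n",
              x$patient_id, x$dsc,
              ifelse(is.na(x$median_surface_distance_mm), "NA",
                     sprintf("%.2f", x$median_surface_distance_mm)),
              x$false_positive_volume_cc, x$false_positive_discoveries))
  invisible(x)
}

#' Evaluate a cohort at original image resolution
#'
#' All metrics are computed on each case's original grid; predictions made on
#' a resampled grid must be mapped back with nearest-neighbor interpolation
#' first (see [resample_mask_to_grid()]), which this function does
#' automatically when a prediction's grid differs from its ground truth's.
#'
#' @param cases List of `list(gt = binary_mask, pred = binary_mask)` pairs on
#'   (or mappable to) original grids.
#' @param diameter_bins Bin edges (mm) for the size-stratified site summary;
#'   the default `15` gives the two strata < 15 mm and >= 15 mm. Use
#'   `c(10, 15, 20)` for a finer breakdown.
#' @param connectivity Component connectivity.
#' @param min_overlap Detection threshold.
#' @return A `cohort_result` with per-patient results, `global_dsc`, a
#'   patient-level summary data.frame and a size-stratified site table
#'   (mean/min/max DSC, median/min/max MSD, sensitivity per diameter bin).
#' @export
evaluate_cohort <- function(cases, diameter_bins = 15, connectivity = 26,
                            min_overlap = 0.45) {
  if (length(cases) == 0) stop("evaluate_cohort: empty case list")
  cases <- lapply(cases, function(cs) {
    if (!same_grid(cs$gt, cs$pred))
      cs$pred <- resample_mask_to_grid(cs$pred, cs$gt)
    cs
  })
  patients <- lapply(cases, function(cs)
    evaluate_patient(cs$gt, cs$pred, connectivity = connectivity,
                     min_overlap = min_overlap))
  gdsc <- global_dice(lapply(cases, function(cs) list(cs$gt, cs$pred)))

  sites <- do.call(rbind, lapply(patients, function(p) {
    if (nrow(p$site_results) == 0) return(NULL)
    cbind(patient_id = p$patient_id, p$site_results)
  }))
  edges <- c(0, sort(diameter_bins), Inf)
  site_table <- NULL
  if (!is.null(sites) && nrow(sites) > 0) {
    bin <- cut(sites$equivalent_diameter_mm, edges, right = FALSE)
    site_table <- do.call(rbind, lapply(levels(bin), function(lv) {
      s <- sites[bin == lv, , drop = FALSE]
      if (nrow(s) == 0) return(NULL)
      msd <- s$median_surface_distance_mm
      data.frame(
        diameter_bin = lv, n_sites = nrow(s),
        dsc_mean = mean(s$dsc), dsc_min = min(s$dsc), dsc_max = max(s$dsc),
        msd_median = if (all(is.na(msd))) NA_real_ else median(msd, na.rm = TRUE),
        msd_min = if (all(is.na(msd))) NA_real_ else min(msd, na.rm = TRUE),
        msd_max = if (all(is.na(msd))) NA_real_ else max(msd, na.rm = TRUE),
        sensitivity = mean(s$detected),
        n_detected = sum(s$detected)
      )
    }))
  }
  patient_table <- do.call(rbind, lapply(patients, function(p)
    data.frame(patient_id = p$patient_id, dsc = p$dsc,
               median_surface_distance_mm = p$median_surface_distance_mm,
               false_positive_discoveries = p$false_positive_discoveries,
               false_positive_volume_cc = p$false_positive_volume_cc,
               erroneous_fp_volume_cc = p$erroneous_fp_volume_cc,
               oversegmentation_fp_volume_cc = p$oversegmentation_fp_volume_cc)))
  structure(
    list(patients = patients, global_dsc = gdsc,
         patient_table = patient_table, site_table = site_table,
         sites = sites),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d patient(s), global DSC %.3f, mean patient DSC %.3f\n",
              nrow(x$patient_table), x$global_dsc, mean(x$patient_table$dsc)))
  if (!is.null(x$site_table)) {
    cat("site summary by diameter:\n")
    print(x$site_table, row.names = FALSE)
  }
  invisible(x)
}
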