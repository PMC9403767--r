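# Patient-specific intensity normalization from the in-liver HU histogram.

#' Estimate normalization statistics from the in-liver histogram
#'
#' Builds a histogram of the Hounsfield values inside the liver mask, takes
#' the highest bin as the center (ties broken toward the lowest HU), and
#' measures the full width at half maximum (FWHM) between the linearly
#' interpolated half-maximum crossings nearest the peak. The HU scale `sigma`
#' follows from the Gaussian relation FWHM = 2*sqrt(2*ln 2)*sigma, so the
#' estimate is robust to intensity outliers (vessels, calcifications) that
#' would inflate a plain standard deviation.
#'
#' @param volume A `ct_volume`.
#' @param liver A non-empty liver `binary_mask` on the same grid.
#' @param bin_width Histogram bin width in HU (default 1).
#' @return A `normalization_stats` list with `center` (HU at the histogram
#'   peak), `sigma` (HU) and `fwhm` (HU).
#' @export
fwhm_stats <- function(volume, liver, bin_width = 1) {
  stop_grid_mismatch(volume, liver, "fwhm_stats")
  if (bin_width <= 0) stop("fwhm_stats: bin_width must be > 0")
  vals <- volume$voxels[liver$voxels == 1]
  if (length(vals) == 0) stop("fwhm_stats: liver mask is empty")

  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(
    findInterval(vals, breaks, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = length(breaks) - 1
  )
  centers <- breaks[-length(breaks)] + bin_width / 2

  peak <- which.max(counts)  # which.max returns the first (lowest-HU) tie
  half <- counts[peak] / 2

  # nearest half-maximum crossings on each side, linearly interpolated
  cross <- function(i0, i1) {
    # between bins i0 (>= half) and i1 (< half)
    c0 <- counts[i0]; c1 <- counts[i1]
    centers[i0] + (c0 - half) / (c0 - c1) * (centers[i1] - centers[i0])
  }
  left <- NA_real_
  if (peak > 1) {
    for (i in peak:2) {
      if (counts[i - 1] < half && counts[i] >= half) {
        left <- cross(i, i - 1); break
      }
    }
  }
  right <- NA_real_
  if (peak < length(counts)) {
    for (i in seq(peak, length(counts) - 1)) {
      if (counts[i + 1] < half && counts[i] >= half) {
        right <- cross(i, i + 1); break
      }
    }
  }
  if (is.na(left) || is.na(right))
    stop("fwhm_stats: degenerate histogram (no half-maximum crossing on both sides)")
  fwhm <- right - left
  if (fwhm <= 0) stop("fwhm_stats: degenerate histogram (non-positive FWHM)")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  structure(list(center = centers[peak], sigma = sigma, fwhm = fwhm),
            class = "normalization_stats")
}

#' @export
print.normalization_stats <- function(x, ...) {
  cat(sprintf("<normalization_stats> center %.1f HU, sigma %.2f HU, FWHM %.2f HU\n",
              x$center, x$sigma, x$fwhm))
  invisible(x)
}

#' Normalize a CT volume inside the liver mask
#'
#' Inside the liver, intensities become `(HU - center) / sigma`; every voxel
#' outside the liver is set to exactly 0, which assigns background to
#' out-of-liver anatomy before the image reaches the model.
#'
#' @param volume A `ct_volume`.
#' @param liver A liver `binary_mask` on the same grid.
#' @param stats A `normalization_stats` object with `sigma > 0`.
#' @return A normalized `ct_volume`.
#' @export
normalize_in_mask <- function(volume, liver, stats) {
  stop_grid_mismatch(volume, liver, "normalize_in_mask")
  if (!is.list(stats) || is.null(stats$sigma) || stats$sigma <= 0)
    stop("normalize_in_mask: stats$sigma must be > 0")
  out <- (volume$voxels - stats$center) / stats$sigma
  out[liver$voxels == 0] <- 0
  ct_volume(out, volume$spacing, volume$origin, volume$patient_id)
}

#' Preprocess one patient for training or inference
#'
#' Convenience wrapper: resample image and masks to a common spacing, clip
#' disease labels to the liver, estimate FWHM statistics and normalize.
#'
#' @param image A `ct_volume`.
#' @param liver Liver `binary_mask`.
#' @param disease Optional disease/ablation `binary_mask`.
#' @param target_spacing Target spacing in mm (default `c(1, 0.75, 0.75)`,
#'   i.e. 1 mm slices and 0.75 mm in-plane).
#' @param bin_width Histogram bin width in HU for [fwhm_stats()].
#' @return List with `image` (normalized), `liver`, `disease` (or `NULL`) and
#'   `stats`.
#' @export
preprocess_patient <- function(image, liver, disease = NULL,
                               target_spacing = c(1, 0.75, 0.75),
                               bin_width = 1) {
  img_r <- resample_to_spacing(image, target_spacing)
  liv_r <- resample_to_spacing(liver, target_spacing)
  dis_r <- NULL
  if (!is.null(disease)) {
    dis_r <- resample_to_spacing(disease, target_spacing)
    dis_r <- clip_disease_to_liver(dis_r, liv_r)
  }
  stats <- fwhm_stats(img_r, liv_r, bin_width = bin_width)
  list(image = normalize_in_mask(img_r, liv_r, stats), liver = liv_r,
       disease = dis_r, stats = stats)
}

#' Clip disease labels to the liver mask
#'
#' Disease voxels outside the liver are untrainable because the model input is
#' masked by the liver; they are removed with a warning.
#'
#' @param disease Disease `binary_mask`.
#' @param liver Liver `binary_mask` on the same grid.
#' @return The intersected disease mask.
#' @export
clip_disease_to_liver <- function(disease, liver) {
  stop_grid_mismatch(disease, liver, "clip_disease_to_liver")
  outside <- sum(disease$voxels == 1 & liver$voxels == 0)
  if (outside > 0) {
    warning(sprintf(
      "clip_disease_to_liver: %d disease voxel(s) outside the liver removed (patient %s)",
      outside, disease$patient_id))
    disease$voxels <- disease$voxels * liver$voxels
  }
  disease
}
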