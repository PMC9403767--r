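# Volume/mask data model, NIfTI I/O, resampling.
#
# Arrays are stored (slice, row, column) = (z, y, x); spacing is mm/voxel in
# the same order, so spacing[1] is the slice thickness. Voxel (i, j, k)
# (1-based) has physical center ((i-1, j-1, k-1) * spacing + origin) mm.

#' Construct a CT volume
#'
#' A CT volume is a 3D array of Hounsfield-unit intensities in
#' (slice, row, column) order, together with its voxel spacing (mm) and
#' physical origin.
#'
#' @param voxels 3D numeric array ordered (slice, row, column).
#' @param spacing Numeric length-3, mm per voxel in the same axis order
#'   (slice thickness first). All components must be positive.
#' @param origin Numeric length-3 physical offset in mm.
#' @param patient_id Opaque identifier carried through the pipeline.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), patient_id = "") {
  voxels <- check_voxel_array(voxels)
  if (any(!is.finite(voxels)))
    stop("ct_volume: voxels must be finite (no NaN/Inf)")
  spacing <- check_spacing(spacing)
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         patient_id = as.character(patient_id)),
    class = "ct_volume"
  )
}

#' Construct a binary mask aligned to a CT volume grid
#'
#' @inheritParams ct_volume
#' @param voxels 3D array with values exactly 0 or 1.
#' @param kind One of `"liver"`, `"disease"`, `"ablation"`, `"prediction"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0), patient_id = "",
                        kind = c("liver", "disease", "ablation", "prediction")) {
  kind <- match.arg(kind)
  voxels <- check_voxel_array(voxels)
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1)))
    stop("binary_mask: values must be exactly 0 or 1")
  spacing <- check_spacing(spacing)
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         patient_id = as.character(patient_id), kind = kind),
    class = "binary_mask"
  )
}

#' Construct a per-voxel probability map
#'
#' @inheritParams ct_volume
#' @param voxels 3D array of values in \[0, 1\].
#' @param model Optional reference to the model that produced the map.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(voxels, spacing, origin = c(0, 0, 0),
                            patient_id = "", model = NULL) {
  voxels <- check_voxel_array(voxels)
  if (min(voxels) < 0 || max(voxels) > 1)
    stop("probability_map: values must lie in [0, 1]")
  spacing <- check_spacing(spacing)
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         patient_id = as.character(patient_id), model = model),
    class = "probability_map"
  )
}

check_voxel_array <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array ordered (slice, row, column)")
  storage.mode(voxels) <- "double"
  voxels
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive lengths (mm/voxel)")
  spacing
}

is_grid_object <- function(x) {
  inherits(x, c("ct_volume", "binary_mask", "probability_map"))
}

#' Test whether two volumes share a grid
#'
#' Two objects share a grid when shape, spacing and origin agree (spacing and
#' origin to 1e-6 mm).
#'
#' @param a,b `ct_volume`, `binary_mask` or `probability_map` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < 1e-6) &&
    all(abs(a$origin - b$origin) < 1e-6)
}

stop_grid_mismatch <- function(a, b, what) {
  if (!same_grid(a, b))
    stop(sprintf("%s: grids do not match (shape/spacing/origin)", what))
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s: %s voxels, spacing %s mm\n",
              x$patient_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s> %s: %s voxels, %d foreground\n",
              x$kind, x$patient_id, paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s: %s voxels, range [%.3f, %.3f]\n",
              x$patient_id, paste(dim(x$voxels), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1/NIfTI-2 image and normalizes the axis order to
#' (slice, row, column); spacing and origin come from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind `NULL` for a CT volume, `"prob"` for a probability map, or a
#'   mask kind (`"liver"`, `"disease"`, `"ablation"`, `"prediction"`).
#' @param patient_id Identifier to attach; defaults to the file stem.
#' @return A `ct_volume`, `binary_mask` or `probability_map`.
#' @export
read_volume <- function(path, kind = NULL, patient_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("read_volume: cannot read NIfTI file '%s'", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("read_volume: '%s' is not a readable NIfTI file (%s)",
                                 path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf("read_volume: '%s' is %dD; a 3D image is required",
                 path, length(d)))
  pix <- RNifti::pixdim(img)
  voxels <- aperm(array(as.numeric(img), dim = d), c(3, 2, 1))
  spacing <- rev(pix[seq_len(3)])
  org <- attr(img, "origin")
  origin <- if (is.null(org)) c(0, 0, 0) else rev(as.numeric(org)[seq_len(3)])
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (is.null(kind))
    ct_volume(voxels, spacing, origin, patient_id)
  else if (identical(kind, "prob"))
    probability_map(voxels, spacing, origin, patient_id)
  else
    binary_mask(voxels, spacing, origin, patient_id, kind = kind)
}

#' Write a volume, mask or probability map to NIfTI
#'
#' Integer masks are stored as unsigned 8-bit and round-trip exactly; other
#' volumes are stored as doubles.
#'
#' @param volume A `ct_volume`, `binary_mask` or `probability_map`.
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  if (!is_grid_object(volume))
    stop("write_volume: not a hepaseg volume object")
  if (!dir.exists(dirname(path)))
    stop(sprintf("write_volume: directory '%s' does not exist", dirname(path)))
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  dt <- if (inherits(volume, "binary_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Resample a volume to a target voxel spacing
#'
#' The output size along each axis is `round(n * spacing_old / spacing_new)`
#' (minimum 1). Images use trilinear interpolation; binary masks are
#' interpolated linearly and thresholded at 0.5, mirroring how ground-truth
#' segmentations are resampled alongside their images. Use
#' `mode = "nearest"` to map predictions back to an original grid without
#' blending labels.
#'
#' @param volume A `ct_volume`, `binary_mask` or `probability_map`.
#' @param target_spacing Numeric length-3, mm/voxel (slice, row, column).
#' @param mode `"linear"` (default) or `"nearest"`.
#' @return An object of the same class on the new grid.
#' @export
resample_to_spacing <- function(volume, target_spacing,
                                mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  target_spacing <- check_spacing(target_spacing)
  d <- dim(volume$voxels)
  out_d <- pmax(1L, as.integer(round(d * volume$spacing / target_spacing)))
  vals <- cpp_resample3d(as.numeric(volume$voxels), as.integer(d),
                         volume$spacing, out_d, target_spacing,
                         mode == "nearest")
  arr <- array(vals, dim = out_d)
  if (inherits(volume, "binary_mask")) {
    if (mode == "linear") arr <- (arr >= 0.5) + 0
    binary_mask(arr, target_spacing, volume$origin, volume$patient_id,
                kind = volume$kind)
  } else if (inherits(volume, "probability_map")) {
    probability_map(pmin(pmax(arr, 0), 1), target_spacing, volume$origin,
                    volume$patient_id, model = volume$model)
  } else {
    ct_volume(arr, target_spacing, volume$origin, volume$patient_id)
  }
}

#' Resample a mask onto the grid of a reference volume
#'
#' Nearest-neighbor resampling used to map predictions back to a patient's
#' original image grid before computing metrics.
#'
#' @param mask A `binary_mask`.
#' @param reference A `ct_volume` (or any grid object) defining the target
#'   grid.
#' @return A `binary_mask` on the reference grid.
#' @export
resample_mask_to_grid <- function(mask, reference) {
  d_out <- dim(reference$voxels)
  vals <- cpp_resample3d(as.numeric(mask$voxels), as.integer(dim(mask$voxels)),
                         mask$spacing, as.integer(d_out), reference$spacing,
                         TRUE)
  binary_mask(array(vals, dim = d_out), reference$spacing, reference$origin,
              mask$patient_id, kind = mask$kind)
}
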