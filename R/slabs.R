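# Connected-component analysis and class-balanced training slabs.
#
# Each non-connected disease site is treated as an independent case, and one
# fixed-size slab is sampled per site so that every training sample contains
# both disease and normal liver.

#' Label connected components of a binary mask
#'
#' @param mask A `binary_mask`.
#' @param connectivity 26 (default; diagonal touches merge) or 6
#'   (face-adjacency only).
#' @return A `component_set`: `labels` (3D integer array, 0 = background,
#'   k = component id), `count`, `centroids` (count x 3 matrix of physical
#'   mm coordinates), `volumes_cc` (physical volumes in cc) and
#'   `voxel_counts`.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26))
    stop("label_components: connectivity must be 6 or 26")
  d <- dim(mask$voxels)
  lab <- cpp_label_components(as.integer(mask$voxels != 0), as.integer(d),
                              as.integer(connectivity))
  count <- attr(lab, "n_components")
  labels <- array(as.integer(lab), dim = d)
  vox_vol <- prod(mask$spacing)
  centroids <- matrix(numeric(0), nrow = 0, ncol = 3)
  counts <- integer(0)
  if (count > 0) {
    idx <- which(labels > 0)
    comp <- labels[idx]
    zyx <- arrayInd(idx, d)  # 1-based indices
    counts <- tabulate(comp, nbins = count)
    centroids <- matrix(0, nrow = count, ncol = 3)
    for (a in 1:3) {
      phys <- (zyx[, a] - 1) * mask$spacing[a] + mask$origin[a]
      centroids[, a] <- rowsum(phys, comp)[, 1] / counts
    }
  }
  structure(
    list(labels = labels, count = count, centroids = centroids,
         volumes_cc = counts * vox_vol / 1000, voxel_counts = counts,
         spacing = mask$spacing, origin = mask$origin,
         patient_id = mask$patient_id, connectivity = connectivity),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s), connectivity %d\n",
              x$count, x$connectivity))
  invisible(x)
}

#' Extract one component of a component set as a binary mask
#'
#' @param components A `component_set`.
#' @param id Component id in `1:count`.
#' @param kind Mask kind for the result.
#' @return A `binary_mask` containing only that component.
#' @export
component_mask <- function(components, id, kind = "disease") {
  if (id < 1 || id > components$count)
    stop("component_mask: id out of range")
  binary_mask((components$labels == id) + 0, components$spacing,
              components$origin, components$patient_id, kind = kind)
}

#' Construct a training slab
#'
#' @param image,liver,label 3D arrays of identical shape (normalized image,
#'   liver indicator, disease indicator).
#' @param source_patient Patient identifier.
#' @param site_index Index (>= 1) of the disease component that seeded the
#'   slab.
#' @param offset Voxel offset (0-based) of the slab window in its source
#'   volume, used to map labels back.
#' @return An object of class `slab`.
#' @export
new_slab <- function(image, liver, label, source_patient = "",
                     site_index = 1L, offset = c(0L, 0L, 0L)) {
  stopifnot(identical(dim(image), dim(liver)),
            identical(dim(image), dim(label)))
  if (any(label == 1 & liver == 0))
    stop("slab: label must be a subset of the liver")
  structure(
    list(image = image, liver = liver, label = label,
         source_patient = source_patient, site_index = as.integer(site_index),
         offset = as.integer(offset)),
    class = "slab"
  )
}

#' @export
print.slab <- function(x, ...) {
  cat(sprintf("<slab> %s site %d: %s voxels, %d disease\n",
              x$source_patient, x$site_index,
              paste(dim(x$image), collapse = "x"), sum(x$label)))
  invisible(x)
}

# Window start positions (0-based) covering [lo, hi] (0-based bounding range)
# with windows of length w inside a volume of length n: centered when the
# extent fits, tiled with minimal overlap when it does not, clamped inward at
# the volume boundary.
window_starts <- function(lo, hi, w, n, center) {
  extent <- hi - lo + 1
  if (extent <= w) {
    s <- round(center) - w %/% 2
    s <- min(max(s, 0), max(n - w, 0))
    return(s)
  }
  k <- ceiling(extent / w)
  starts <- round(seq(lo, hi - w + 1, length.out = k))
  pmin(pmax(starts, 0), max(n - w, 0))
}

#' Extract class-balanced training slabs
#'
#' One window per connected disease site, centered on the site centroid
#' (rounded to voxels) and shifted inward when it would cross the volume
#' boundary. Sites larger than the window are covered with
#' `ceiling(extent/window)` tiles of minimal overlap. The slab label contains
#' every disease voxel inside the window, regardless of which site seeded it.
#' Volumes smaller than the slab along an axis are zero-padded.
#'
#' @param image Normalized `ct_volume`.
#' @param liver Liver `binary_mask` on the same grid.
#' @param disease Disease `binary_mask` on the same grid.
#' @param slab_shape Window shape in voxels, default `c(32, 120, 120)`.
#' @param connectivity Connectivity for site labeling (default 26).
#' @return List of `slab` objects (empty, with a warning, if the disease mask
#'   is empty).
#' @export
extract_slabs <- function(image, liver, disease,
                          slab_shape = c(32, 120, 120), connectivity = 26) {
  stop_grid_mismatch(image, liver, "extract_slabs")
  stop_grid_mismatch(image, disease, "extract_slabs")
  slab_shape <- as.integer(slab_shape)
  comps <- label_components(disease, connectivity = connectivity)
  if (comps$count == 0) {
    warning("extract_slabs: disease mask is empty; no slabs extracted")
    return(list())
  }
  d <- dim(image$voxels)
  lab_arr <- disease$voxels * liver$voxels  # labels are liver-restricted
  slabs <- list()
  for (k in seq_len(comps$count)) {
    idx <- which(comps$labels == k)
    zyx <- arrayInd(idx, d) - 1L  # 0-based
    starts <- vector("list", 3)
    for (a in 1:3) {
      ctr <- (comps$centroids[k, a] - disease$origin[a]) / disease$spacing[a]
      starts[[a]] <- window_starts(min(zyx[, a]), max(zyx[, a]),
                                   slab_shape[a], d[a], ctr)
    }
    for (s1 in starts[[1]]) for (s2 in starts[[2]]) for (s3 in starts[[3]]) {
      s <- c(s1, s2, s3)
      take <- lapply(1:3, function(a)
        seq(s[a] + 1, min(s[a] + slab_shape[a], d[a])))
      pad_take <- function(arr) {
        out <- array(0, dim = slab_shape)
        out[seq_along(take[[1]]), seq_along(take[[2]]), seq_along(take[[3]])] <-
          arr[take[[1]], take[[2]], take[[3]]]
        out
      }
      slabs[[length(slabs) + 1]] <- new_slab(
        pad_take(image$voxels), pad_take(liver$voxels), pad_take(lab_arr),
        source_patient = image$patient_id, site_index = k, offset = s
      )
    }
  }
  slabs
}

#' Map slab labels back into volume coordinates
#'
#' Returns the union of all slab labels placed at their source offsets; used
#' to verify that no ground-truth disease voxel is lost by slab sampling.
#'
#' @param slabs List of `slab` objects from one volume.
#' @param volume_dim Shape of the source volume.
#' @return 3D 0/1 array of `volume_dim`.
#' @export
slab_label_union <- function(slabs, volume_dim) {
  out <- array(0, dim = volume_dim)
  for (s in slabs) {
    d <- dim(s$label)
    rng <- lapply(1:3, function(a)
      seq(s$offset[a] + 1, min(s$offset[a] + d[a], volume_dim[a])))
    sub <- s$label[seq_along(rng[[1]]), seq_along(rng[[2]]),
                   seq_along(rng[[3]]), drop = FALSE]
    out[rng[[1]], rng[[2]], rng[[3]]] <-
      pmax(out[rng[[1]], rng[[2]], rng[[3]]], sub)
  }
  out
}

#' Flip/mirror augmentation of a slab
#'
#' Applies the same reflection to image, liver and label. With explicit
#' `axes`, the reflection is deterministic (an involution: applying it twice
#' restores the slab). With `axes = NULL`, each axis is flipped independently
#' with probability `prob` under `rng_seed`.
#'
#' @param slab A `slab`.
#' @param axes Character subset of `c("slice", "row", "column")`, or `NULL`
#'   for random flips.
#' @param rng_seed Seed used when `axes` is `NULL`.
#' @param prob Per-axis flip probability for random augmentation.
#' @return The augmented `slab` (metadata preserved).
#' @export
flip_mirror_augment <- function(slab, axes = NULL, rng_seed = NULL,
                                prob = 0.5) {
  all_axes <- c("slice", "row", "column")
  if (is.null(axes)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    axes <- all_axes[runif(3) < prob]
  } else if (length(axes) > 0 && !all(axes %in% all_axes)) {
    stop("flip_mirror_augment: axes must be a subset of slice/row/column")
  }
  flip <- function(arr) {
    if ("slice" %in% axes) arr <- arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
    if ("row" %in% axes) arr <- arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]
    if ("column" %in% axes) arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
    arr
  }
  slab$image <- flip(slab$image)
  slab$liver <- flip(slab$liver)
  slab$label <- flip(slab$label)
  slab
}
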