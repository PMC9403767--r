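# Synthetic contrast-enhanced CT liver phantom.
#
# Emulates the structure of portal-venous CECT of the liver: an ellipsoidal
# liver at parenchymal enhancement, hypo-dense spherical lesions (optionally
# with a bright enhancing rim, the typical appearance of colorectal liver
# metastases), Gaussian image noise, and air-valued background. Masks are
# exact and noise-free.

#' Specify a synthetic liver phantom
#'
#' @param volume_shape Integer length-3, voxels (slice, row, column).
#' @param spacing Numeric length-3, mm/voxel.
#' @param liver List with `center` (mm) and `semiaxes` (mm) of the liver
#'   ellipsoid.
#' @param parenchyma_hu Mean liver parenchyma intensity (default 100 HU,
#'   a plausible portal-venous value).
#' @param lesions List of lesions; each a list with `center` (mm),
#'   `diameter` (sphere-equivalent diameter, mm), `hu_offset` (must be
#'   negative: lesions are hypo-enhancing) and optional
#'   `rim = list(width, hu_offset)` with a positive rim offset.
#' @param noise_sd Additive Gaussian noise, HU (default 15).
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape, spacing, liver,
                         parenchyma_hu = 100, lesions = list(),
                         noise_sd = 15, rng_seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  spacing <- check_spacing(spacing)
  stopifnot(length(liver$center) == 3, length(liver$semiaxes) == 3,
            all(liver$semiaxes > 0))
  for (les in lesions) {
    if (les$hu_offset >= 0)
      stop("phantom_spec: lesion hu_offset must be negative (hypo-enhancing)")
    r <- les$diameter / 2
    # conservative containment: scaled center distance plus scaled radius
    sd_c <- sqrt(sum(((les$center - liver$center) / liver$semiaxes)^2))
    if (sd_c + r / min(liver$semiaxes) > 1)
      stop("phantom_spec: lesion not entirely inside the liver ellipsoid")
    if (!is.null(les$rim) && les$rim$hu_offset <= 0)
      stop("phantom_spec: rim hu_offset must be positive")
  }
  if (length(lesions) > 1) {
    for (i in seq_len(length(lesions) - 1))
      for (j in seq(i + 1, length(lesions))) {
        d <- sqrt(sum((lesions[[i]]$center - lesions[[j]]$center)^2))
        if (d <= (lesions[[i]]$diameter + lesions[[j]]$diameter) / 2)
          stop("phantom_spec: lesions overlap")
      }
  }
  structure(
    list(volume_shape = volume_shape, spacing = spacing, liver = liver,
         parenchyma_hu = parenchyma_hu, lesions = lesions,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

# physical voxel-center coordinate arrays for a grid
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

#' Generate a synthetic liver phantom
#'
#' Rasterization assigns a voxel to a shape when its center lies inside.
#'
#' @param spec A `phantom_spec`.
#' @return List with `image` (`ct_volume`), `liver` and `disease`
#'   (`binary_mask`); the disease mask is the union of the lesion spheres.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$volume_shape
  co <- grid_coords(d, spec$spacing)
  # squared scaled distance to the liver ellipsoid center, separable build
  liver_arr <- array(0, dim = d)
  sz <- ((co[[1]] - spec$liver$center[1]) / spec$liver$semiaxes[1])^2
  sy <- ((co[[2]] - spec$liver$center[2]) / spec$liver$semiaxes[2])^2
  sx <- ((co[[3]] - spec$liver$center[3]) / spec$liver$semiaxes[3])^2
  ell <- outer(outer(sz, sy, "+"), sx, "+")
  liver_arr[ell <= 1] <- 1

  img <- array(-1000, dim = d)
  img[liver_arr == 1] <- spec$parenchyma_hu
  disease_arr <- array(0, dim = d)
  for (les in spec$lesions) {
    r <- les$diameter / 2
    dz <- (co[[1]] - les$center[1])^2
    dy <- (co[[2]] - les$center[2])^2
    dx <- (co[[3]] - les$center[3])^2
    dist2 <- outer(outer(dz, dy, "+"), dx, "+")
    inside <- dist2 <= r^2
    disease_arr[inside] <- 1
    core_r <- if (is.null(les$rim)) r else max(r - les$rim$width, 0)
    img[dist2 <= core_r^2] <- spec$parenchyma_hu + les$hu_offset
    if (!is.null(les$rim))
      img[inside & dist2 > core_r^2] <- spec$parenchyma_hu + les$rim$hu_offset
  }
  set.seed(spec$rng_seed)
  img <- img + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
  pid <- sprintf("phantom-%d", spec$rng_seed)
  list(
    image = ct_volume(img, spec$spacing, patient_id = pid),
    liver = binary_mask(liver_arr, spec$spacing, patient_id = pid,
                        kind = "liver"),
    disease = binary_mask(disease_arr, spec$spacing, patient_id = pid,
                          kind = "disease")
  )
}

#' Synthesize a probability map from a disease mask
#'
#' Stands in for model output when exercising post-processing and evaluation:
#' the binary disease indicator is blurred with an isotropic Gaussian (sigma
#' in mm, converted to voxels per axis) and perturbed with clipped Gaussian
#' noise. With `blur_sigma_mm = 0` and `noise_sd = 0` the map equals the mask
#' exactly.
#'
#' @param disease A disease `binary_mask`.
#' @param blur_sigma_mm Gaussian blur sigma in mm (>= 0).
#' @param noise_sd Standard deviation of additive noise on the probability
#'   scale (>= 0).
#' @param rng_seed Integer seed.
#' @return A `probability_map` on the same grid.
#' @export
synth_probability_map <- function(disease, blur_sigma_mm = 2, noise_sd = 0.05,
                                  rng_seed = 1L) {
  stopifnot(blur_sigma_mm >= 0, noise_sd >= 0)
  arr <- disease$voxels + 0
  d <- dim(arr)
  if (blur_sigma_mm > 0) {
    for (a in 1:3) {
      sig <- blur_sigma_mm / disease$spacing[a]
      half <- max(1L, ceiling(3 * sig))
      k <- exp(-0.5 * ((-half):half / sig)^2)
      k <- k / sum(k)
      arr <- array(cpp_blur1d(as.numeric(arr), as.integer(d), a - 1L, k),
                   dim = d)
    }
  }
  if (noise_sd > 0) {
    set.seed(rng_seed)
    arr <- arr + array(rnorm(prod(d), sd = noise_sd), dim = d)
  }
  probability_map(pmin(pmax(arr, 0), 1), disease$spacing, disease$origin,
                  disease$patient_id, model = "synthetic")
}

#' Generate a small cohort of random phantoms
#'
#' Convenience generator for tests and examples: each phantom carries 1-3
#' lesions with sphere-equivalent diameters drawn from `diameter_range`,
#' placed at random inside the liver ellipsoid without overlap.
#'
#' @param n Number of phantoms.
#' @param rng_seed Integer seed; phantom `i` uses `rng_seed + i`.
#' @param volume_shape,spacing Grid of each phantom.
#' @param diameter_range Lesion diameter range in mm.
#' @param n_lesions_range Range for the per-phantom lesion count.
#' @param noise_sd Image noise in HU.
#' @return List of phantoms as returned by [generate_phantom()].
#' @export
phantom_cohort <- function(n, rng_seed = 1L,
                           volume_shape = c(24, 64, 64),
                           spacing = c(2, 1.5, 1.5),
                           diameter_range = c(14, 24),
                           n_lesions_range = c(1, 3),
                           noise_sd = 15) {
  extent <- volume_shape * spacing
  liver <- list(center = extent / 2, semiaxes = extent * 0.42)
  lapply(seq_len(n), function(i) {
    set.seed(rng_seed + i)
    n_les <- sample(seq(n_lesions_range[1], n_lesions_range[2]), 1)
    lesions <- list()
    tries <- 0
    while (length(lesions) < n_les && tries < 200) {
      tries <- tries + 1
      dia <- runif(1, diameter_range[1], diameter_range[2])
      u <- runif(3, -0.6, 0.6)
      ctr <- liver$center + u * liver$semiaxes
      ok <- sqrt(sum(((ctr - liver$center) / liver$semiaxes)^2)) +
        (dia / 2) / min(liver$semiaxes) <= 0.98
      for (les in lesions)
        ok <- ok && sqrt(sum((ctr - les$center)^2)) >
          (dia + les$diameter) / 2 + 2
      if (ok) lesions[[length(lesions) + 1]] <-
          list(center = ctr, diameter = dia, hu_offset = -40)
    }
    spec <- phantom_spec(volume_shape, spacing, liver, lesions = lesions,
                         noise_sd = noise_sd, rng_seed = rng_seed + i)
    generate_phantom(spec)
  })
}
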