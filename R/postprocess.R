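# Seed-and-threshold region growing on probability maps.
#
# The most inferior/superior extents of a disease site often carry lower
# probability than its center; plain thresholding either clips those ends or
# floods low-confidence noise. Growth therefore starts only from
# high-confidence seed voxels (prob >= seed) and floods through connected
# voxels above a lower threshold.

#' Growth parameters
#'
#' Defaults are the tuned operating point seed 0.67 / threshold 0.30.
#'
#' @param seed Seed probability in (0, 1]; components are kept only if they
#'   contain a voxel with probability >= `seed`.
#' @param threshold Growth threshold in (0, seed].
#' @param connectivity 6 or 26 (default 26).
#' @return A `grow_params` object.
#' @export
grow_params <- function(seed = 0.67, threshold = 0.30, connectivity = 26) {
  if (!(threshold > 0 && threshold <= seed && seed <= 1))
    stop("grow_params: need 0 < threshold <= seed <= 1")
  if (!connectivity %in% c(6, 26))
    stop("grow_params: connectivity must be 6 or 26")
  structure(list(seed = seed, threshold = threshold,
                 connectivity = connectivity), class = "grow_params")
}

#' Grow a segmentation from seed voxels on a probability map
#'
#' The output is the union, over all seed voxels (prob >= seed), of their
#' connected components within the super-threshold set (prob >= threshold).
#' Every output component therefore contains at least one seed voxel, and the
#' output is a subset of the super-threshold set.
#'
#' @param prob A `probability_map`.
#' @param params A `grow_params` object.
#' @return A prediction `binary_mask` on the same grid.
#' @export
seed_threshold_grow <- function(prob, params = grow_params()) {
  stopifnot(inherits(params, "grow_params"))
  d <- dim(prob$voxels)
  above <- prob$voxels >= params$threshold
  lab <- cpp_label_components(as.integer(above), as.integer(d),
                              as.integer(params$connectivity))
  lab <- array(as.integer(lab), dim = d)
  keep <- unique(lab[prob$voxels >= params$seed])
  out <- array(0, dim = d)
  if (length(keep) > 0) out[lab %in% keep] <- 1
  binary_mask(out, prob$spacing, prob$origin, prob$patient_id,
              kind = "prediction")
}

#' Tune seed and threshold by exhaustive grid search
#'
#' Evaluates every (seed, threshold) pair with seed >= threshold on paired
#' probability maps and reference masks, and returns the pair maximizing the
#' objective (ties broken toward the smallest seed, then the smallest
#' threshold). The default grids are seeds 0.25-0.95 and thresholds 0.20-0.80,
#' both in 0.01 increments.
#'
#' @param probs List of `probability_map`s.
#' @param refs List of reference `binary_mask`s, paired with `probs`.
#' @param seed_grid,threshold_grid Numeric grids.
#' @param objective `"mean_patient_dsc"` (default) or `"global_dsc"`.
#' @param connectivity Growth connectivity.
#' @return List with `params` (the best `grow_params`), `objective`,
#'   `score` and `table` (data.frame of seed, threshold, score for every
#'   evaluated pair).
#' @export
tune_seed_threshold <- function(probs, refs,
                                seed_grid = seq(0.25, 0.95, by = 0.01),
                                threshold_grid = seq(0.20, 0.80, by = 0.01),
                                objective = c("mean_patient_dsc", "global_dsc"),
                                connectivity = 26) {
  objective <- match.arg(objective)
  if (length(probs) == 0 || length(probs) != length(refs))
    stop("tune_seed_threshold: need equal-length non-empty probs/refs lists")
  if (length(seed_grid) == 0 || length(threshold_grid) == 0)
    stop("tune_seed_threshold: grids must be non-empty")
  seed_grid <- sort(round(seed_grid, 10))
  threshold_grid <- sort(round(threshold_grid, 10))

  # per-case component labelings are reused across the seed grid: for fixed
  # threshold, varying the seed only changes which components are kept.
  rows <- list()
  best <- list(score = -Inf, seed = NA, threshold = NA)
  for (thr in threshold_grid) {
    seeds_ok <- seed_grid[seed_grid >= thr]
    if (length(seeds_ok) == 0) next
    case_info <- lapply(seq_along(probs), function(i) {
      p <- probs[[i]]
      lab <- cpp_label_components(as.integer(p$voxels >= thr),
                                  as.integer(dim(p$voxels)),
                                  as.integer(connectivity))
      n_comp <- attr(lab, "n_components")
      lab <- as.integer(lab)
      ref <- as.integer(refs[[i]]$voxels) == 1L
      # per-component voxel count, overlap with reference, and max probability
      if (n_comp > 0) {
        sizes <- tabulate(lab[lab > 0], nbins = n_comp)
        inter <- tabulate(lab[lab > 0 & ref], nbins = n_comp)
        maxp <- rep(-Inf, n_comp)
        sel <- lab > 0
        agg <- tapply(p$voxels[sel], lab[sel], max)
        maxp[as.integer(names(agg))] <- agg
      } else {
        sizes <- inter <- maxp <- numeric(0)
      }
      list(sizes = sizes, inter = inter, maxp = maxp, ref_n = sum(ref))
    })
    for (sd in seeds_ok) {
      num <- den <- 0
      dscs <- numeric(length(case_info))
      for (i in seq_along(case_info)) {
        ci <- case_info[[i]]
        keep <- ci$maxp >= sd
        a <- sum(ci$sizes[keep])
        inter <- sum(ci$inter[keep])
        dscs[i] <- if (a + ci$ref_n == 0) 1 else 2 * inter / (a + ci$ref_n)
        num <- num + 2 * inter
        den <- den + a + ci$ref_n
      }
      score <- if (objective == "mean_patient_dsc") mean(dscs)
               else if (den == 0) 1 else num / den
      rows[[length(rows) + 1]] <-
        data.frame(seed = sd, threshold = thr, score = score)
      if (score > best$score ||
          (score == best$score &&
           (sd < best$seed || (sd == best$seed && thr < best$threshold)))) {
        best <- list(score = score, seed = sd, threshold = thr)
      }
    }
  }
  table <- do.call(rbind, rows)
  list(params = grow_params(best$seed, best$threshold, connectivity),
       objective = objective, score = best$score, table = table)
}
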