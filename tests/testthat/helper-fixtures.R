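# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no data files.

# small grid object builders ---------------------------------------------------

mask_from_array <- function(arr, spacing = c(1, 1, 1), kind = "disease") {
  binary_mask(arr, spacing = spacing, kind = kind)
}

zeros3 <- function(d) array(0, dim = d)

random_mask <- function(d, p = 0.3, spacing = c(1, 1, 1), kind = "disease") {
  mask_from_array(array(rbinom(prod(d), 1, p), dim = d), spacing, kind)
}

random_prob_map <- function(d, spacing = c(1, 1, 1)) {
  probability_map(array(runif(prod(d)), dim = d), spacing)
}

small_phantom <- function(seed = 1, shape = c(16, 48, 48),
                          spacing = c(2, 1.5, 1.5), dia = c(16, 22)) {
  phantom_cohort(1, rng_seed = seed, volume_shape = shape, spacing = spacing,
                 diameter_range = dia)[[1]]
}

tiny_hybrid_config <- function(features2d = 8) {
  arch_config("hybrid_wnet", layers = 2, conv_blocks_initial = 2,
              conv_block_increase = 1, filters_initial = 4,
              encoder2d = "simple", filters2d = 4, layers2d = 2,
              features2d = features2d)
}

# independent connected-components oracle built on igraph ----------------------

oracle_components <- function(arr, connectivity = 26) {
  d <- dim(arr)
  idx <- which(arr != 0)
  lab <- array(0L, dim = d)
  if (length(idx) == 0) return(list(labels = lab, count = 0L))
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  zyx <- arrayInd(idx, d)
  key <- function(m) (m[, 1] - 1) + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  inside <- array(FALSE, dim = d)
  inside[idx] <- TRUE
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(zyx, 2, as.numeric(offs[r, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_idx <- key(nb[ok, , drop = FALSE]) + 1
    src <- idx[ok]
    keep <- inside[nb_idx]
    edges[[r]] <- cbind(src[keep], nb_idx[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(rbind(edges, cbind(idx, idx))), ncol = 2),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[as.integer(names(memb))] <- as.integer(memb)
  list(labels = lab, count = max(memb))
}

# two labelings describe the same partition of the foreground
same_partition <- function(lab_a, lab_b) {
  fg <- which(lab_a > 0)
  if (!identical(which(lab_b > 0), fg)) return(FALSE)
  pairs <- unique(cbind(lab_a[fg], lab_b[fg]))
  !(any(duplicated(pairs[, 1])) || any(duplicated(pairs[, 2])))
}

# independent seeded-growth oracle: keep oracle components containing a seed
oracle_grow <- function(pvox, seed, threshold, connectivity = 26) {
  comp <- oracle_components((pvox >= threshold) + 0, connectivity)
  keep <- unique(comp$labels[pvox >= seed])
  keep <- keep[keep > 0]
  out <- array(0, dim = dim(pvox))
  out[comp$labels %in% keep] <- 1
  out
}

# exhaustive median surface distance oracle ------------------------------------

oracle_surface <- function(arr) {
  d <- dim(arr)
  pad <- array(0, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  shifted <- function(dz, dy, dx)
    pad[2:(d[1] + 1) + dz, 2:(d[2] + 1) + dy, 2:(d[3] + 1) + dx]
  nb_min <- pmin(shifted(-1, 0, 0), shifted(1, 0, 0), shifted(0, -1, 0),
                 shifted(0, 1, 0), shifted(0, 0, -1), shifted(0, 0, 1))
  which(arr == 1 & nb_min == 0)
}

oracle_msd <- function(a, b, spacing) {
  sa <- oracle_surface(a)
  sb <- oracle_surface(b)
  pa <- sweep(arrayInd(sa, dim(a)) - 1, 2, spacing, "*")
  pb <- sweep(arrayInd(sb, dim(b)) - 1, 2, spacing, "*")
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  median(c(apply(dmat, 1, min), apply(dmat, 2, min)))
}

# misc -------------------------------------------------------------------------

dice_vox <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) 1 else 2 * sum(a * b) / s
}
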