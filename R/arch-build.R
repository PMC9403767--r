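# Graph construction for the four architecture families.
#
# A model is a declarative graph of typed nodes in topological order. The
# graph is what gets counted (parameter accounting is closed-form per node)
# and what the engine executes, so the analytic count and the instantiated
# weight count agree by construction.

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

node_ch <- function(g, id) g$nodes[[id]]$out_channels

g_add <- function(g, op, inputs = integer(0), group = NA_character_,
                  kernel = NULL, stride = c(1L, 1L, 1L), bias = FALSE,
                  out_channels = NULL, factor = NULL, channel = NULL,
                  name = NULL) {
  in_ch <- if (length(inputs) == 0) 0L else
    if (op == "concat") sum(vapply(inputs, function(i) node_ch(g, i),
                                   integer(1)))
    else node_ch(g, inputs[[1]])
  scale <- if (length(inputs) == 0) c(1L, 1L, 1L) else
    g$nodes[[inputs[[1]]]]$scale
  out_ch <- switch(op,
    input = out_channels,
    conv = out_channels,
    bn = in_ch,
    relu = in_ch,
    add = in_ch,
    concat = in_ch,
    maxpool = in_ch,
    avgpool = in_ch,
    upsample = in_ch,
    channel_select = length(channel),
    softmax = in_ch,
    stop("unknown op: ", op)
  )
  if (op %in% c("maxpool", "avgpool")) scale <- scale * factor
  if (op == "upsample") {
    stopifnot(all(scale %% factor == 0))
    scale <- scale %/% factor
  }
  if (op == "conv") scale <- scale * stride
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(
    id = id, op = op, inputs = as.integer(inputs), group = group,
    kernel = if (is.null(kernel)) NULL else as.integer(kernel),
    stride = as.integer(stride), bias = isTRUE(bias),
    in_channels = as.integer(in_ch), out_channels = as.integer(out_ch),
    factor = if (is.null(factor)) NULL else as.integer(factor),
    channel = channel, scale = as.integer(scale),
    name = if (is.null(name)) op else name
  )
  id
}

conv_bn_relu <- function(g, x, f, kernel, group, bias = TRUE, name = "conv") {
  y <- g_add(g, "conv", x, group = group, kernel = kernel, bias = bias,
             out_channels = f, name = name)
  y <- g_add(g, "bn", y, group = group)
  g_add(g, "relu", y)
}

# One convolution block in the chosen style. `level_outputs` (dense style)
# is the running list of same-level output ids to concatenate.
style_block <- function(g, x, style, f, kernel, group, level_outputs = NULL) {
  if (style == "standard") {
    conv_bn_relu(g, x, f, kernel, group)
  } else if (style == "residual") {
    y <- g_add(g, "conv", x, group = group, kernel = kernel, bias = TRUE,
               out_channels = f)
    y <- g_add(g, "bn", y, group = group)
    sc <- x
    if (node_ch(g, x) != f)  # 1x1x1 projection to matching channels
      sc <- g_add(g, "conv", x, group = group, kernel = c(1L, 1L, 1L),
                  bias = FALSE, out_channels = f, name = "proj")
    y <- g_add(g, "add", c(sc, y))
    g_add(g, "relu", y)
  } else {  # dense: concatenate all previous same-level outputs
    src <- if (length(level_outputs) > 1)
      g_add(g, "concat", level_outputs) else level_outputs[[1]]
    conv_bn_relu(g, src, f, kernel, group)
  }
}

finish_spec <- function(g, config, input, output, aux2d = NULL,
                        feat2d = NULL) {
  scales <- vapply(g$nodes, function(n) n$scale, integer(3))
  spec <- structure(
    list(config = config, nodes = g$nodes, input = input, output = output,
         aux2d = aux2d, feat2d = feat2d,
         pad_multiple = apply(scales, 1, max),
         accepts_variable_size = TRUE),
    class = "model_spec"
  )
  spec$parameter_counts <- count_parameters(spec)
  spec
}

#' Build a standard, residual or dense 3D U-Net
#'
#' Encoder-decoder with `layers` poolings (factor 2 per axis), skip
#' connections between matching levels, 3x3x3 convolution blocks with batch
#' normalization and ReLU, and a final 1x1x1 convolution to `classes`
#' channels with per-voxel softmax normalization. The residual style adds the
#' block input to the convolution output before activation (with a 1x1x1
#' projection when channel counts differ); the dense style concatenates all
#' previous block outputs within a level before each convolution.
#'
#' @param config An `arch_config` with style `"standard"`, `"residual"` or
#'   `"dense"`.
#' @return A `model_spec`.
#' @export
build_unet3d <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  if (!config$style %in% c("standard", "residual", "dense"))
    stop("build_unet3d: style must be standard, residual or dense")
  style <- config$style
  kernel <- c(3L, 3L, 3L)
  g <- new_graph()
  input <- g_add(g, "input", out_channels = config$input_channels,
                 name = "input")

  dense_f <- function(level) {
    f <- filters_at_layer(config, level)
    if (style == "dense" && !is.null(config$growth_rate) &&
        config$growth_rate > 0) config$growth_rate else f
  }
  run_level <- function(x, level) {
    outs <- x
    for (b in seq_len(blocks_at_layer(config, level))) {
      x <- style_block(g, x, style, dense_f(level), kernel, "net",
                       level_outputs = outs)
      outs <- c(outs, x)
    }
    x
  }
  skips <- integer(0)
  x <- input
  for (level in seq_len(config$layers) - 1L) {
    x <- run_level(x, level)
    skips <- c(skips, x)
    x <- g_add(g, "maxpool", x, factor = c(2L, 2L, 2L))
  }
  x <- run_level(x, config$layers)
  for (level in rev(seq_len(config$layers) - 1L)) {
    x <- g_add(g, "upsample", x, factor = c(2L, 2L, 2L))
    x <- g_add(g, "concat", c(x, skips[[level + 1]]))
    x <- run_level(x, level)
  }
  x <- g_add(g, "conv", x, group = "net", kernel = c(1L, 1L, 1L),
             bias = TRUE, out_channels = config$classes, name = "head")
  out <- g_add(g, "softmax", x)
  finish_spec(g, config, input, out)
}

# DenseNet-121 topology on (1, k, k) kernels and (1, 2, 2) striding so each
# slice of a slab is processed as an independent 2D image. Returns the ids of
# the stage outputs used as decoder skips.
densenet121_encoder <- function(g, x, group = "enc2d") {
  growth <- 32L
  k1 <- c(1L, 1L, 1L)
  k3 <- c(1L, 3L, 3L)
  s2 <- c(1L, 2L, 2L)
  conv1 <- g_add(g, "conv", x, group = group, kernel = c(1L, 7L, 7L),
                 stride = s2, bias = FALSE, out_channels = 64L,
                 name = "conv1")
  b <- g_add(g, "bn", conv1, group = group)
  relu1 <- g_add(g, "relu", b)
  x <- g_add(g, "maxpool", relu1, factor = s2)
  skips <- c(relu1)
  c_in <- 64L
  feats <- x
  for (blk in seq_along(c(6L, 12L, 24L, 16L))) {
    n_layers <- c(6L, 12L, 24L, 16L)[blk]
    for (l in seq_len(n_layers)) {
      y <- g_add(g, "bn", feats, group = group)
      y <- g_add(g, "relu", y)
      y <- g_add(g, "conv", y, group = group, kernel = k1, bias = FALSE,
                 out_channels = 4L * growth)
      y <- g_add(g, "bn", y, group = group)
      y <- g_add(g, "relu", y)
      y <- g_add(g, "conv", y, group = group, kernel = k3, bias = FALSE,
                 out_channels = growth)
      feats <- g_add(g, "concat", c(feats, y))
      c_in <- c_in + growth
    }
    if (blk < 4) {
      skips <- c(skips, feats)
      y <- g_add(g, "bn", feats, group = group)
      y <- g_add(g, "relu", y)
      y <- g_add(g, "conv", y, group = group, kernel = k1, bias = FALSE,
                 out_channels = c_in %/% 2L, name = "transition")
      feats <- g_add(g, "avgpool", y, factor = s2)
      c_in <- c_in %/% 2L
    }
  }
  y <- g_add(g, "bn", feats, group = group)
  top <- g_add(g, "relu", y)
  list(top = top, skips = rev(skips))  # deepest skip first
}

# Small plain 2D U-Net encoder for desk-scale hybrids.
simple2d_encoder <- function(g, x, config, group = "enc2d") {
  k3 <- c(1L, 3L, 3L)
  s2 <- c(1L, 2L, 2L)
  f <- config$filters2d
  skips <- integer(0)
  for (level in seq_len(config$layers2d)) {
    fl <- f * 2^(level - 1)
    x <- conv_bn_relu(g, x, fl, k3, group)
    x <- conv_bn_relu(g, x, fl, k3, group)
    skips <- c(skips, x)
    x <- g_add(g, "maxpool", x, factor = s2)
  }
  x <- conv_bn_relu(g, x, f * 2^config$layers2d, k3, group)
  list(top = x, skips = rev(skips))
}

#' Build the Hybrid-WNet
#'
#' Two coupled networks. (a) A 2D U-Net whose encoder is the DenseNet-121
#' topology applied slice-wise (the single normalized-CT channel is
#' replicated to the three channels the pretrained first layer expects; the
#' liver mask enters the 3D network only) and whose decoder upsamples back to
#' input resolution, ending in `features2d` (default 32) feature maps per
#' slice. (b) A 3D dense network consuming the image/liver channels
#' concatenated with the per-slice 2D features. The 3D dense connections are
#' global: every convolution at a given spatial scale receives the
#' concatenation of all previous same-scale outputs across the whole 3D
#' network, encoder and decoder alike. The forward pass accepts variable
#' spatial sizes (inputs are reflect-padded to pooling multiples and outputs
#' cropped back).
#'
#' Pretrained encoder weights are not bundled; instantiation uses random
#' initialization unless a weight file is supplied explicitly (see
#' [instantiate_network()]).
#'
#' @param config An `arch_config` with `style = "hybrid_wnet"`, e.g. from
#'   [hybrid_wnet_config()].
#' @return A `model_spec` whose `feat2d` node is the 2D feature tensor and
#'   whose `aux2d` node (if `aux_head2d`) is the standalone 2D prediction.
#' @export
build_hybrid_wnet <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  if (config$style != "hybrid_wnet")
    stop("build_hybrid_wnet: config style must be hybrid_wnet")
  g <- new_graph()
  input <- g_add(g, "input", out_channels = config$input_channels,
                 name = "input")
  img <- g_add(g, "channel_select", input, channel = 1L, name = "image_ch")

  if (config$encoder2d == "densenet121") {
    x2 <- g_add(g, "concat", c(img, img, img), name = "replicate3")
    enc <- densenet121_encoder(g, x2)
  } else {
    enc <- simple2d_encoder(g, img, config)
  }

  # 2D decoder: one upsampling stage per encoder downsampling stage, skip
  # concatenation, convs_per_stage2d 3x3 conv+BN+ReLU per stage, channel
  # schedule ending in features2d.
  k3 <- c(1L, 3L, 3L)
  s2 <- c(1L, 2L, 2L)
  n_up <- as.integer(round(log2(g$nodes[[enc$top]]$scale[2])))
  sched <- config$decoder2d_channels
  if (config$encoder2d == "simple")
    sched <- config$filters2d * 2^(rev(seq_len(max(n_up - 1, 0))) - 1)
  sched <- c(sched[seq_len(min(n_up - 1, length(sched)))], config$features2d)
  x <- enc$top
  for (i in seq_len(n_up)) {
    x <- g_add(g, "upsample", x, factor = s2)
    if (i <= length(enc$skips))
      x <- g_add(g, "concat", c(x, enc$skips[[i]]))
    f <- sched[min(i, length(sched))]
    for (j in seq_len(config$convs_per_stage2d))
      x <- conv_bn_relu(g, x, f, k3, "dec2d")
  }
  feat2d <- x
  aux2d <- NULL
  if (config$aux_head2d) {
    h <- g_add(g, "conv", feat2d, group = "dec2d", kernel = c(1L, 1L, 1L),
               bias = TRUE, out_channels = config$classes, name = "head2d")
    aux2d <- g_add(g, "softmax", h)
  }

  # 3D dense network with global same-scale connectivity.
  k333 <- c(3L, 3L, 3L)
  x <- g_add(g, "concat", c(input, feat2d), name = "join2d3d")
  scale_outputs <- list()  # per-scale registry of all outputs
  run3d_level <- function(x, level, n_blocks) {
    key <- as.character(level)
    if (is.null(scale_outputs[[key]])) scale_outputs[[key]] <<- integer(0)
    scale_outputs[[key]] <<- c(scale_outputs[[key]], x)
    f <- filters_at_layer(config, level)
    if (!is.null(config$growth_rate) && config$growth_rate > 0)
      f <- config$growth_rate
    for (b in seq_len(n_blocks)) {
      src <- if (length(scale_outputs[[key]]) > 1)
        g_add(g, "concat", scale_outputs[[key]]) else scale_outputs[[key]][[1]]
      x <- conv_bn_relu(g, src, f, k333, "net3d")
      scale_outputs[[key]] <<- c(scale_outputs[[key]], x)
    }
    x
  }
  n_levels <- config$layers  # levels 0..layers-1; one pooling between each
  for (level in seq_len(n_levels - 1L) - 1L) {
    x <- run3d_level(x, level, blocks_at_layer(config, level))
    x <- g_add(g, "maxpool", x, factor = c(2L, 2L, 2L))
  }
  x <- run3d_level(x, n_levels - 1L, blocks_at_layer(config, n_levels - 1L))
  for (level in rev(seq_len(n_levels - 1L) - 1L)) {
    x <- g_add(g, "upsample", x, factor = c(2L, 2L, 2L))
    x <- run3d_level(x, level, blocks_at_layer(config, level))
  }
  x <- g_add(g, "conv", x, group = "net3d", kernel = c(1L, 1L, 1L),
             bias = TRUE, out_channels = config$classes, name = "head3d")
  out <- g_add(g, "softmax", x)
  finish_spec(g, config, input, out, aux2d = aux2d, feat2d = feat2d)
}

#' Count model parameters
#'
#' Closed-form accounting over the graph: a convolution holds
#' `prod(kernel) * in_channels * out_channels` weights plus `out_channels`
#' biases when biased; a batch-normalization layer holds `4 * channels`
#' parameters of which the two running statistics per channel
#' (`2 * channels`) are never trainable. Frozen groups move their otherwise
#' trainable parameters into the non-trainable count; the total is invariant.
#'
#' @param model A `model_spec` or an instantiated `network`.
#' @param frozen Character vector of frozen group names.
#' @return Named list `total`, `trainable`, `non_trainable` with a
#'   `by_group` data.frame attribute.
#' @export
count_parameters <- function(model, frozen = character(0)) {
  spec <- if (inherits(model, "network")) model$spec else model
  stopifnot(inherits(spec, "model_spec"))
  rows <- list()
  for (n in spec$nodes) {
    if (n$op == "conv") {
      w <- prod(n$kernel) * n$in_channels * n$out_channels
      b <- if (n$bias) n$out_channels else 0L
      is_frozen <- n$group %in% frozen
      rows[[length(rows) + 1]] <- data.frame(
        group = n$group, trainable = ifelse(is_frozen, 0, w + b),
        non_trainable = ifelse(is_frozen, w + b, 0))
    } else if (n$op == "bn") {
      is_frozen <- n$group %in% frozen
      tr <- if (is_frozen) 0 else 2 * n$in_channels
      rows[[length(rows) + 1]] <- data.frame(
        group = n$group, trainable = tr,
        non_trainable = 4 * n$in_channels - tr)
    }
  }
  tab <- do.call(rbind, rows)
  by_group <- stats::aggregate(cbind(trainable, non_trainable) ~ group, tab,
                               sum)
  out <- list(total = sum(tab$trainable) + sum(tab$non_trainable),
              trainable = sum(tab$trainable),
              non_trainable = sum(tab$non_trainable))
  attr(out, "by_group") <- by_group
  out
}

#' Reshape a 5D slab batch into a stacked 2D slice batch
#'
#' `(B, N, H, W, C)` becomes `(B*N, H, W, C)` with slices ordered
#' patient-major, then slice index; [reshape_2d_to_3d()] is its exact
#' inverse.
#'
#' @param batch 5D array `(batch, slices, height, width, channels)`.
#' @return 4D array `(batch*slices, height, width, channels)`.
#' @export
reshape_3d_to_2d <- function(batch) {
  d <- dim(batch)
  stopifnot(length(d) == 5)
  y <- aperm(batch, c(2, 1, 3, 4, 5))
  dim(y) <- c(d[1] * d[2], d[3], d[4], d[5])
  y
}

#' Restore a stacked 2D slice batch to its 5D slab form
#'
#' @param slices 4D array from [reshape_3d_to_2d()].
#' @param n_slices Number of slices per patient.
#' @return 5D array `(batch, slices, height, width, channels)`.
#' @export
reshape_2d_to_3d <- function(slices, n_slices) {
  d <- dim(slices)
  stopifnot(length(d) == 4, d[1] %% n_slices == 0)
  dim(slices) <- c(n_slices, d[1] %/% n_slices, d[2], d[3], d[4])
  aperm(slices, c(2, 1, 3, 4, 5))
}

#' @export
print.model_spec <- function(x, ...) {
  pc <- x$parameter_counts
  cat(sprintf("<model_spec> %s: %d nodes\n", x$config$style, length(x$nodes)))
  cat(sprintf("  parameters: %s total (%s trainable, %s non-trainable)\n",
              format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ",")))
  cat(sprintf("  pad multiple (z,y,x): %s\n",
              paste(x$pad_multiple, collapse = ",")))
  invisible(x)
}

#' Describe a model graph
#'
#' @param spec A `model_spec`.
#' @return data.frame with one row per node (op, kernel, channels,
#'   parameters, group), invisibly printed.
#' @export
describe_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  rows <- lapply(spec$nodes, function(n) {
    params <- if (n$op == "conv")
      prod(n$kernel) * n$in_channels * n$out_channels +
        if (n$bias) n$out_channels else 0L
    else if (n$op == "bn") 4L * n$in_channels else 0L
    data.frame(id = n$id, op = n$op, name = n$name,
               kernel = if (is.null(n$kernel)) "" else
                 paste(n$kernel, collapse = "x"),
               in_ch = n$in_channels, out_ch = n$out_channels,
               params = params,
               group = ifelse(is.na(n$group), "", n$group))
  })
  do.call(rbind, rows)
}
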