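# Declarative architecture configuration.
#
# The hyper-parameter grid spans four families: standard, residual and dense
# 3D U-Nets built from one shared encoder-decoder framework, and the hybrid
# 2D-3D dense W-Net. "Layers" counts pooling levels; the filter count doubles
# after each pooling (capped by filters_max) and the number of convolution
# blocks per level grows by conv_block_increase per deeper level (capped by
# conv_blocks_max).

#' Architecture configuration
#'
#' @param style One of `"standard"`, `"residual"`, `"dense"`,
#'   `"hybrid_wnet"`.
#' @param layers Number of pooling levels (>= 1).
#' @param conv_blocks_initial Convolution blocks at layer 0 (>= 1).
#' @param conv_block_increase Extra blocks per deeper layer (the
#'   "convolution lambda").
#' @param conv_blocks_max Cap on blocks per layer.
#' @param filters_initial Channels at layer 0 (>= 1).
#' @param filters_max Channel cap (may be `Inf` for dense styles with a
#'   growth rate).
#' @param growth_rate Channels added per dense concatenation; dense styles
#'   only. With a positive growth rate every dense convolution emits
#'   `growth_rate` channels; with `growth_rate = NULL`/0 it emits the layer's
#'   filter count.
#' @param input_channels Input channels (default 2: image + liver mask).
#' @param classes Output classes (default 2: normal, disease).
#' @param encoder2d Hybrid only: `"densenet121"` (DenseNet-121 topology) or
#'   `"simple"` (a small plain 2D U-Net encoder for desk-scale work).
#' @param features2d Hybrid only: channels of the 2D feature tensor handed to
#'   the 3D network (default 32).
#' @param decoder2d_channels Hybrid only: channel schedule of the 2D decoder
#'   stages (one per encoder downsampling stage; the final stage always emits
#'   `features2d`).
#' @param convs_per_stage2d Hybrid only: convolutions per 2D decoder stage.
#' @param filters2d,layers2d Hybrid + `encoder2d = "simple"` only: size of
#'   the small 2D encoder.
#' @param aux_head2d Hybrid only: keep the auxiliary 2D prediction head used
#'   when the 2D sub-network is trained on its own (default `TRUE`).
#' @return An `arch_config` object.
#' @export
arch_config <- function(style = c("standard", "residual", "dense",
                                  "hybrid_wnet"),
                        layers = 2, conv_blocks_initial = 2,
                        conv_block_increase = 0, conv_blocks_max = 4,
                        filters_initial = 8, filters_max = 128,
                        growth_rate = NULL, input_channels = 2, classes = 2,
                        encoder2d = c("densenet121", "simple"),
                        features2d = 32,
                        decoder2d_channels = c(256, 128, 64, 32),
                        convs_per_stage2d = 2,
                        filters2d = 8, layers2d = 2, aux_head2d = TRUE) {
  style <- match.arg(style)
  encoder2d <- match.arg(encoder2d)
  if (layers < 1) stop("arch_config: layers must be >= 1")
  if (filters_initial < 1) stop("arch_config: filters_initial must be >= 1")
  if (conv_blocks_initial < 1)
    stop("arch_config: conv_blocks_initial must be >= 1")
  if (style %in% c("dense", "hybrid_wnet") && is.infinite(filters_max) &&
      (is.null(growth_rate) || growth_rate <= 0))
    stop("arch_config: dense style with unbounded filters requires a growth_rate")
  structure(
    list(style = style, layers = as.integer(layers),
         conv_blocks_initial = as.integer(conv_blocks_initial),
         conv_block_increase = as.integer(conv_block_increase),
         conv_blocks_max = as.integer(conv_blocks_max),
         filters_initial = as.integer(filters_initial),
         filters_max = filters_max, growth_rate = growth_rate,
         input_channels = as.integer(input_channels),
         classes = as.integer(classes),
         encoder2d = encoder2d, features2d = as.integer(features2d),
         decoder2d_channels = as.integer(decoder2d_channels),
         convs_per_stage2d = as.integer(convs_per_stage2d),
         filters2d = as.integer(filters2d), layers2d = as.integer(layers2d),
         aux_head2d = isTRUE(aux_head2d)),
    class = "arch_config"
  )
}

#' Effective filters at a layer
#'
#' `min(filters_initial * 2^layer, filters_max)`: the filter count doubles
#' after each pooling up to the cap.
#'
#' @param config An `arch_config`.
#' @param layer Layer index (0-based).
#' @return Integer filter count.
#' @export
filters_at_layer <- function(config, layer) {
  as.integer(min(config$filters_initial * 2^layer, config$filters_max))
}

#' Effective convolution blocks at a layer
#'
#' `min(conv_blocks_initial + layer * conv_block_increase, conv_blocks_max)`.
#'
#' @inheritParams filters_at_layer
#' @return Integer block count.
#' @export
blocks_at_layer <- function(config, layer) {
  as.integer(min(config$conv_blocks_initial +
                   layer * config$conv_block_increase,
                 config$conv_blocks_max))
}

#' Canonical Hybrid-WNet configuration
#'
#' The published description of the final model admits two readings of the 3D
#' sub-network: the architecture figure specifies eight initial filters with
#' two and three convolution blocks on its two layers, while the results
#' prose says "32 filters" with a convolution lambda of two. Both are
#' constructible; the figure reading is the default.
#'
#' @param reading `"figure"` (8 initial filters, blocks 2 and 3) or
#'   `"results"` (32 initial filters, blocks 2 and 4).
#' @return An `arch_config` with `style = "hybrid_wnet"`.
#' @export
hybrid_wnet_config <- function(reading = c("figure", "results")) {
  reading <- match.arg(reading)
  if (reading == "figure")
    arch_config("hybrid_wnet", layers = 2, conv_blocks_initial = 2,
                conv_block_increase = 1, conv_blocks_max = 4,
                filters_initial = 8, filters_max = 128)
  else
    arch_config("hybrid_wnet", layers = 2, conv_blocks_initial = 2,
                conv_block_increase = 2, conv_blocks_max = 4,
                filters_initial = 32, filters_max = 128)
}

#' Read an architecture configuration from YAML
#'
#' Field names mirror [arch_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return An `arch_config`.
#' @export
read_arch_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(arch_config, vals)
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("<arch_config> style %s: %d layer(s), blocks %s, filters %s\n",
              x$style, x$layers,
              paste(vapply(0:(x$layers), function(l) blocks_at_layer(x, l),
                           integer(1)), collapse = "/"),
              paste(vapply(0:(x$layers), function(l) filters_at_layer(x, l),
                           integer(1)), collapse = "/")))
  invisible(x)
}
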