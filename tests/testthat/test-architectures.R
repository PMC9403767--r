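# Declarative model graphs, parameter accounting and tensor reshaping.

test_that("filter and block schedules double and cap as configured", {
  cfg <- arch_config("standard", layers = 4, filters_initial = 8,
                     filters_max = 128, conv_blocks_initial = 1,
                     conv_block_increase = 2, conv_blocks_max = 4)
  expect_equal(filters_at_layer(cfg, 0), 8L)
  expect_equal(filters_at_layer(cfg, 2), 32L)
  expect_equal(filters_at_layer(cfg, 4), 128L)
  expect_equal(filters_at_layer(cfg, 5), 128L)   # capped
  expect_equal(blocks_at_layer(cfg, 0), 1L)
  expect_equal(blocks_at_layer(cfg, 1), 3L)
  expect_equal(blocks_at_layer(cfg, 3), 4L)      # capped
  expect_error(arch_config("dense", filters_max = Inf), "growth_rate")
  expect_error(arch_config("standard", layers = 0), "layers")
})

test_that("the first standard block carries the closed-form parameter count", {
  cfg <- arch_config("standard", layers = 1, conv_blocks_initial = 1,
                     filters_initial = 8, input_channels = 2)
  df <- describe_model(build_unet3d(cfg))
  conv1 <- df[df$op == "conv", ][1, ]
  bn1 <- df[df$op == "bn", ][1, ]
  expect_equal(conv1$params, 2 * 27 * 8 + 8)  # k^3 * c_in * c_out + bias
  expect_equal(bn1$params, 4 * 8)             # gamma, beta, two running stats
})

test_that("analytic counts equal instantiated weight counts on all styles", {
  configs <- list(
    arch_config("standard", layers = 1, conv_blocks_initial = 1,
                filters_initial = 8),
    arch_config("standard", layers = 2, conv_blocks_initial = 2,
                conv_block_increase = 1, filters_initial = 4),
    arch_config("residual", layers = 2, conv_blocks_initial = 2,
                filters_initial = 8, filters_max = 16),
    arch_config("dense", layers = 2, conv_blocks_initial = 2,
                filters_initial = 8, growth_rate = 4),
    arch_config("dense", layers = 1, conv_blocks_initial = 3,
                filters_initial = 6),
    tiny_hybrid_config()
  )
  for (cfg in configs) {
    spec <- if (cfg$style == "hybrid_wnet") build_hybrid_wnet(cfg)
            else build_unet3d(cfg)
    pc <- count_parameters(spec)
    expect_equal(pc$total, pc$trainable + pc$non_trainable)
    net <- instantiate_network(spec, rng_seed = 1)
    n_alloc <- sum(vapply(net$weights, function(w)
      sum(vapply(w, length, numeric(1))), numeric(1)))
    expect_equal(n_alloc, pc$total)
    # the trainable subset excludes exactly the running statistics
    n_bn <- sum(vapply(spec$nodes, function(n)
      if (n$op == "bn") n$in_channels else 0L, numeric(1)))
    expect_equal(pc$non_trainable, 2 * n_bn)
  }
})

test_that("freezing moves trainable counts without changing the total", {
  spec <- build_hybrid_wnet(tiny_hybrid_config())
  pc0 <- count_parameters(spec)
  pc1 <- count_parameters(spec, frozen = "enc2d")
  expect_equal(pc1$total, pc0$total)
  expect_lt(pc1$trainable, pc0$trainable)
  grp <- attr(pc0, "by_group")
  enc <- grp[grp$group == "enc2d", ]
  expect_equal(pc0$trainable - pc1$trainable, enc$trainable)
})

test_that("dense connectivity grows conv input channels linearly", {
  g <- 4L
  cfg <- arch_config("dense", layers = 1, conv_blocks_initial = 4,
                     filters_initial = 8, growth_rate = g)
  df <- describe_model(build_unet3d(cfg))
  enc_convs <- df[df$op == "conv" & df$kernel == "3x3x3", ]
  # within the first level, input channels increase by the growth rate
  in_ch <- enc_convs$in_ch[1:4]
  expect_equal(diff(in_ch), rep(g, 3))
})

test_that("the hybrid 2D feature tensor has the configured channel count", {
  spec32 <- build_hybrid_wnet(hybrid_wnet_config())
  expect_equal(spec32$nodes[[spec32$feat2d]]$out_channels, 32L)
  spec8 <- build_hybrid_wnet(tiny_hybrid_config(features2d = 8))
  expect_equal(spec8$nodes[[spec8$feat2d]]$out_channels, 8L)
})

test_that("both published readings of the full hybrid are constructible", {
  fig <- build_hybrid_wnet(hybrid_wnet_config("figure"))
  res <- build_hybrid_wnet(hybrid_wnet_config("results"))
  for (spec in list(fig, res)) {
    pc <- count_parameters(spec)
    expect_equal(pc$total, pc$trainable + pc$non_trainable)
    expect_gt(pc$total, 7e6)  # dominated by the DenseNet-121 encoder
  }
  # the 3D sub-network is larger under the 32-filter reading
  g_fig <- attr(count_parameters(fig), "by_group")
  g_res <- attr(count_parameters(res), "by_group")
  expect_gt(g_res$trainable[g_res$group == "net3d"],
            g_fig$trainable[g_fig$group == "net3d"])
  # the 2D sub-network (DenseNet-121 topology) is shared between readings
  expect_equal(g_fig[g_fig$group == "enc2d", ], g_res[g_res$group == "enc2d", ])
})

test_that("builds are deterministic in their counts", {
  a <- count_parameters(build_hybrid_wnet(hybrid_wnet_config()))
  b <- count_parameters(build_hybrid_wnet(hybrid_wnet_config()))
  expect_identical(a$total, b$total)
  expect_identical(a$trainable, b$trainable)
})

test_that("forward output is a per-voxel probability over classes", {
  set.seed(4)
  net <- instantiate_network(build_hybrid_wnet(tiny_hybrid_config()),
                             rng_seed = 7)
  x <- array(rnorm(8 * 16 * 16 * 2), dim = c(8, 16, 16, 2))
  out <- network_forward(net, x)$output[[1]]
  expect_equal(dim(out), c(8, 16, 16, 2))
  expect_lt(max(abs(apply(out, 1:3, sum) - 1)), 1e-5)
  expect_gte(min(out), 0)
})

test_that("variable input sizes are padded and cropped transparently", {
  set.seed(5)
  net <- instantiate_network(build_hybrid_wnet(tiny_hybrid_config()),
                             rng_seed = 3)
  dnet <- instantiate_network(
    build_unet3d(arch_config("dense", layers = 2, conv_blocks_initial = 2,
                             filters_initial = 4, growth_rate = 4)),
    rng_seed = 3)
  for (i in 1:5) {
    d <- c(sample(5:12, 1), sample(9:24, 1), sample(9:24, 1))
    x <- array(rnorm(prod(d) * 2), dim = c(d, 2))
    for (n in list(net, dnet)) {
      out <- network_forward(n, x)$output[[1]]
      expect_equal(dim(out), c(d, 2))
    }
  }
})

test_that("slab batches reshape to stacked slices and back exactly", {
  d <- c(3, 4, 5, 6, 2)
  x <- array(seq_len(prod(d)), dim = d)
  y <- reshape_3d_to_2d(x)
  expect_equal(dim(y), c(12, 5, 6, 2))
  # patient-major ordering: slices of patient 1 come first, in order
  expect_equal(y[1, , , ], x[1, 1, , , ])
  expect_equal(y[4, , , ], x[1, 4, , , ])
  expect_equal(y[5, , , ], x[2, 1, , , ])
  expect_identical(reshape_2d_to_3d(y, n_slices = 4), x)
  # a batch of 8 slabs of 32 slices flattens to 256 slice images
  x2 <- array(0, dim = c(8, 32, 6, 6, 1))
  expect_equal(dim(reshape_3d_to_2d(x2)), c(256, 6, 6, 1))
  # single-slice degenerate case
  x3 <- array(rnorm(20), dim = c(1, 1, 4, 5, 1))
  y3 <- reshape_3d_to_2d(x3)
  expect_equal(dim(y3), c(1, 4, 5, 1))
  expect_identical(reshape_2d_to_3d(y3, 1), x3)
})

test_that("missing pretrained weight files are a hard error", {
  spec <- build_hybrid_wnet(tiny_hybrid_config())
  expect_error(instantiate_network(spec, weights_file = "no/such/file.rds"),
               "not found")
  # explicit random initialization works and checkpoints round-trip
  td <- withr::local_tempdir()
  net <- instantiate_network(spec, rng_seed = 1)
  save_network(net, file.path(td, "ckpt.rds"))
  net2 <- instantiate_network(spec, rng_seed = 99,
                              weights_file = file.path(td, "ckpt.rds"))
  expect_identical(net2$weights, net$weights)
})
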