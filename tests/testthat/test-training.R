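# Cyclical learning rate, range finder, phase training and model selection.

test_that("the cyclical learning rate is a triangular periodic wave", {
  expect_equal(cyclical_lr(0, 1e-4, 1e-2, 20), 1e-4)
  expect_equal(cyclical_lr(10, 1e-4, 1e-2, 20), 1e-2)
  expect_equal(cyclical_lr(5, 1e-4, 1e-2, 20), (1e-4 + 1e-2) / 2)
  steps <- 0:100
  lrs <- cyclical_lr(steps, 2e-4, 8e-4, 20)
  expect_true(all(lrs >= 2e-4 - 1e-15 & lrs <= 8e-4 + 1e-15))
  expect_equal(cyclical_lr(steps, 2e-4, 8e-4, 20),
               cyclical_lr(steps + 20, 2e-4, 8e-4, 20))
  expect_error(cyclical_lr(0, 1e-2, 1e-4, 20), "lr_min")
  expect_error(cyclical_lr(0, 1e-4, 1e-2, 15), "even")
})

test_that("the range finder stops before a planted divergence point", {
  lrs <- exp(seq(log(1e-5), log(1), length.out = 60))
  r_star <- 0.03
  losses <- ifelse(lrs < r_star, 1 / (1 + lrs * 50),
                   1 + 50 * (lrs - r_star))
  rng <- lr_range_from_trace(lrs, losses)
  expect_lte(rng$lr_max, r_star)
  expect_equal(rng$lr_min, rng$lr_max / 10)

  flat <- rep(1, 60)
  expect_warning(rf <- lr_range_from_trace(lrs, flat), "never diverged")
  expect_equal(rf$lr_max, lrs[60])
})

make_training_fixture <- function(n_phantoms = 2, seed = 21) {
  cases <- lapply(seq_len(n_phantoms), function(i) {
    ph <- small_phantom(seed = seed + i, shape = c(12, 32, 32),
                        dia = c(14, 20))
    st <- fwhm_stats(ph$image, ph$liver)
    list(image = normalize_in_mask(ph$image, ph$liver, st), liver = ph$liver,
         disease = ph$disease)
  })
  slabs <- unlist(lapply(cases, function(cs)
    extract_slabs(cs$image, cs$liver, cs$disease, slab_shape = c(8, 24, 24))),
    recursive = FALSE)
  list(slabs = slabs, cases = cases)
}

tiny_net <- function(seed = 1) {
  instantiate_network(build_hybrid_wnet(tiny_hybrid_config()), rng_seed = seed)
}

test_that("find_lr_range returns a finite decade on a real model", {
  fx <- make_training_fixture()
  net <- tiny_net()
  batch <- list(xs = lapply(fx$slabs[1:2], hepaseg:::slab_input),
                labels = lapply(fx$slabs[1:2], `[[`, "label"))
  rng <- suppressWarnings(find_lr_range(net, list(batch), lr_lo = 1e-4,
                                        lr_hi = 3, n_steps = 10))
  expect_true(is.finite(rng$lr_max) && rng$lr_max > 0)
  expect_equal(rng$lr_min, rng$lr_max / 10)
  expect_true(all(is.finite(rng$trace$loss[seq_len(5)])))
  expect_error(find_lr_range(net, list(batch), lr_lo = 1, lr_hi = 0.1),
               "lr_lo")
})

test_that("a fully frozen phase leaves every weight bit-identical", {
  fx <- make_training_fixture()
  net <- tiny_net()
  phase <- training_phase("end_to_end", lr_min = 1e-3, lr_max = 1e-2,
                          max_epochs = 1, steps_per_epoch = 3,
                          frozen_scope = c("enc2d", "dec2d", "net3d"))
  before <- net$weights
  res <- train_phase(net, phase, fx$slabs, list(), rng_seed = 2,
                     batch_size = 1)
  expect_identical(res$net$weights, before)
})

test_that("unknown frozen scopes are a configuration error", {
  fx <- make_training_fixture()
  net <- tiny_net()
  phase <- training_phase("dense3d_only", lr_min = 1e-3, lr_max = 1e-2,
                          frozen_scope = "bogus_subnet")
  expect_error(train_phase(net, phase, fx$slabs, list(), rng_seed = 1),
               "unknown sub-network")
})

test_that("phase freezing protects exactly the frozen groups", {
  fx <- make_training_fixture()
  net <- tiny_net()
  phase <- training_phase("dense3d_only", lr_min = 5e-3, lr_max = 2e-2,
                          max_epochs = 1, steps_per_epoch = 4)
  res <- train_phase(net, phase, fx$slabs, list(), rng_seed = 3,
                     batch_size = 1)
  expect_identical(group_weights(res$net, "enc2d"),
                   group_weights(net, "enc2d"))
  expect_identical(group_weights(res$net, "dec2d"),
                   group_weights(net, "dec2d"))
  expect_false(identical(group_weights(res$net, "net3d"),
                         group_weights(net, "net3d")))
})

test_that("the staged schedule enforces its order and trains end to end", {
  fx <- make_training_fixture()
  sched <- default_schedule(lr_min = 2e-3, lr_max = 1e-2, max_epochs = 1,
                            steps_per_epoch = 3)
  bad <- sched[c(2, 1, 3, 4)]
  net <- tiny_net()
  expect_error(staged_train(net, bad, list(train_slabs = fx$slabs,
                                           val_cases = list())),
               "order")
  run <- staged_train(net, sched,
                      list(train_slabs = fx$slabs, val_cases = fx$cases[1]),
                      rng_seed = 5, batch_size = 1)
  expect_length(run$records, 4)
  # the end-to-end phase may move every sub-network
  for (grp in c("enc2d", "dec2d", "net3d"))
    expect_false(identical(group_weights(run$net, grp),
                           group_weights(net, grp)))
  expect_true(is.finite(run$best_validation_dsc))
})

test_that("training losses are reproducible under a fixed seed", {
  fx <- make_training_fixture()
  phase <- training_phase("end_to_end", lr_min = 1e-3, lr_max = 5e-3,
                          max_epochs = 1, steps_per_epoch = 4)
  r1 <- train_phase(tiny_net(7), phase, fx$slabs, list(), rng_seed = 11,
                    batch_size = 1)
  r2 <- train_phase(tiny_net(7), phase, fx$slabs, list(), rng_seed = 11,
                    batch_size = 1)
  expect_identical(r1$record$history$loss, r2$record$history$loss)
  expect_identical(r1$net$weights, r2$net$weights)
})

test_that("select_best maximizes validation DSC with seed tie-breaks", {
  runs <- list(list(run_seed = 1, best_validation_dsc = 0.5),
               list(run_seed = 2, best_validation_dsc = 0.7),
               list(run_seed = 3, best_validation_dsc = 0.6))
  expect_equal(select_best(runs)$run_seed, 2)
  expect_equal(select_best(runs[1])$run_seed, 1)
  tie <- list(list(run_seed = 5, best_validation_dsc = 0.7),
              list(run_seed = 4, best_validation_dsc = 0.7))
  expect_equal(select_best(tie)$run_seed, 4)
  expect_error(select_best(list()), "empty")
  # the default number of random restarts is 3
  expect_equal(eval(formals(run_restarts)$n_runs), 3)
})
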