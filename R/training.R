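# Staged training protocol: cyclical learning rate with a range finder,
# four freeze/unfreeze phases for the hybrid model, random restarts, and
# model selection by validation Dice.

#' Triangular cyclical learning rate
#'
#' Rises linearly from `lr_min` to `lr_max` over the first half cycle and
#' falls linearly back over the second; periodic with period
#' `steps_per_cycle`.
#'
#' @param step Step index (>= 0; step 0 is the cycle start at `lr_min`).
#' @param lr_min,lr_max Positive learning-rate bounds.
#' @param steps_per_cycle Even integer >= 2.
#' @return Learning rate(s); vectorized over `step`.
#' @export
cyclical_lr <- function(step, lr_min, lr_max, steps_per_cycle) {
  if (lr_min > lr_max) stop("cyclical_lr: lr_min must be <= lr_max")
  if (lr_min <= 0) stop("cyclical_lr: rates must be positive")
  if (steps_per_cycle < 2 || steps_per_cycle %% 2 != 0)
    stop("cyclical_lr: steps_per_cycle must be even and >= 2")
  pos <- step %% steps_per_cycle
  half <- steps_per_cycle / 2
  up <- pos <= half
  ifelse(up, lr_min + (lr_max - lr_min) * pos / half,
         lr_max - (lr_max - lr_min) * (pos - half) / half)
}

#' Learning-rate range from a sweep trace
#'
#' Given losses recorded along an exponentially increasing learning-rate
#' sweep, smooths the losses (exponential moving average, bias-corrected) to
#' stabilize the running minimum, and returns the largest rate before the
#' loss exceeds `(1 + tol)` times that running minimum; `lr_min` is a tenth
#' of `lr_max`. Comparing the instantaneous loss against the smoothed
#' minimum reacts within one step of a divergence, which a lagging smoothed
#' loss would overshoot on the short sweeps used here.
#'
#' @param lrs Increasing learning rates of the sweep.
#' @param losses Loss after each sweep step.
#' @param tol Divergence tolerance above the running minimum (default 0.2).
#' @param smooth Exponential smoothing factor (default 0.98).
#' @return List with `lr_min`, `lr_max` and the smoothed trace.
#' @export
lr_range_from_trace <- function(lrs, losses, tol = 0.2, smooth = 0.98) {
  stopifnot(length(lrs) == length(losses), length(lrs) >= 2)
  sm <- numeric(length(losses))
  acc <- 0
  for (i in seq_along(losses)) {
    acc <- smooth * acc + (1 - smooth) * losses[i]
    sm[i] <- acc / (1 - smooth^i)
  }
  runmin <- cummin(sm)
  diverged <- which(losses > (1 + tol) * runmin)
  diverged <- diverged[diverged > 1]
  if (length(diverged) == 0) {
    warning("lr_range_from_trace: loss never diverged; returning the widest stable range")
    lr_max <- lrs[length(lrs)]
  } else {
    lr_max <- lrs[min(diverged) - 1]
  }
  list(lr_min = lr_max / 10, lr_max = lr_max,
       trace = data.frame(lr = lrs, loss = losses, smoothed = sm))
}

# one optimization step; returns updated net/state and the batch loss
train_step <- function(net, xs, labels, lr, adam_state, output = "3d") {
  fwd <- network_forward(net, xs, train = TRUE, keep_acts = TRUE)
  out_id <- if (output == "2d") net$spec$aux2d else net$spec$output
  if (is.null(out_id))
    stop("train_step: model has no output for phase target '", output, "'")
  probs <- fwd$acts[[out_id]]
  labs <- lapply(seq_along(labels), function(b) {
    l <- labels[[b]]
    dim(l) <- c(dim(l), 1)
    lab <- pad_reflect(l, dim(probs[[b]]))
    lab[, , , 1]
  })
  xe <- softmax_xent(probs, labs)
  logits_id <- net$spec$nodes[[out_id]]$inputs[1]
  seeds <- setNames(list(xe$dlogits), as.character(logits_id))
  wg <- network_backward(net, fwd, seeds)
  net <- update_bn_running(net, fwd)
  upd <- adam_update(net, wg, adam_state, lr)
  list(net = upd$net, state = upd$state, loss = xe$loss)
}

slab_input <- function(slab) {
  d <- dim(slab$image)
  array(c(slab$image, slab$liver), dim = c(d, 2))
}

#' Find a learning-rate range by exponential sweep
#'
#' Runs training steps with exponentially increasing rates between `lr_lo`
#' and `lr_hi` on a throwaway copy of the network, and extracts the range
#' with [lr_range_from_trace()].
#'
#' @param net A `network`.
#' @param batches List of `list(xs, labels)` training batches (recycled).
#' @param lr_lo,lr_hi Sweep bounds, `lr_lo < lr_hi`.
#' @param n_steps Number of sweep steps.
#' @param output `"3d"` or `"2d"` (auxiliary head) loss target.
#' @param tol,smooth Passed to [lr_range_from_trace()].
#' @return As [lr_range_from_trace()].
#' @export
find_lr_range <- function(net, batches, lr_lo = 1e-4, lr_hi = 0.02,
                          n_steps = 15, output = "3d", tol = 0.2,
                          smooth = 0.98) {
  if (lr_lo >= lr_hi) stop("find_lr_range: need lr_lo < lr_hi")
  lrs <- exp(seq(log(lr_lo), log(lr_hi), length.out = n_steps))
  # the loss observed at step i reflects the update made at step i-1, so an
  # extra forward-only step closes the sweep and losses are paired with the
  # rate whose update produced them
  losses <- numeric(n_steps)
  state <- new_adam_state()
  probe <- net
  for (i in seq_len(n_steps + 1)) {
    b <- batches[[(i - 1) %% length(batches) + 1]]
    lr_i <- if (i <= n_steps) lrs[i] else 0
    res <- train_step(probe, b$xs, b$labels, lr_i, state, output = output)
    probe <- res$net
    state <- res$state
    if (i == 1) {
      if (!is.finite(res$loss))
        stop("find_lr_range: loss not finite at lr_lo; model or loss misconfigured")
      next
    }
    losses[i - 1] <- res$loss
    if (!is.finite(res$loss)) {
      lrs <- lrs[seq_len(i - 1)]
      losses[i - 1] <- max(losses[seq_len(i - 2)]) * 10
      losses <- losses[seq_len(i - 1)]
      break
    }
  }
  lr_range_from_trace(lrs, losses, tol = tol, smooth = smooth)
}

PHASE_NAMES <- c("decoder2d_only", "full_2d", "dense3d_only", "end_to_end")

#' Define a training phase
#'
#' The hybrid model is trained in four ordered phases: (1) only the new 2D
#' decoder (pretrained encoder frozen), (2) the entire 2D network, (3) only
#' the 3D network consuming the frozen 2D features, (4) end-to-end. Freezing
#' earlier stages lets high learning rates be used without untraining them.
#'
#' @param name One of `"decoder2d_only"`, `"full_2d"`, `"dense3d_only"`,
#'   `"end_to_end"`.
#' @param lr_min,lr_max Cyclical learning-rate bounds; `NULL` to determine
#'   them with [find_lr_range()] at the start of the phase.
#' @param steps_per_cycle Cyclical learning-rate period.
#' @param max_epochs Maximum validation epochs in the phase.
#' @param steps_per_epoch Optimization steps between validation evaluations.
#' @param patience Stop the phase after this many evaluations without
#'   validation improvement.
#' @param frozen_scope Frozen group names; `NULL` picks the default for the
#'   phase name.
#' @return A `training_phase`.
#' @export
training_phase <- function(name, lr_min = NULL, lr_max = NULL,
                           steps_per_cycle = 20L, max_epochs = 3L,
                           steps_per_epoch = 10L, patience = 5L,
                           frozen_scope = NULL) {
  name <- match.arg(name, PHASE_NAMES)
  if (!is.null(lr_min) && !is.null(lr_max) &&
      !(lr_min > 0 && lr_min <= lr_max))
    stop("training_phase: need 0 < lr_min <= lr_max")
  if (is.null(frozen_scope))
    frozen_scope <- switch(name,
      decoder2d_only = c("enc2d", "net3d"),
      full_2d = "net3d",
      dense3d_only = c("enc2d", "dec2d"),
      end_to_end = character(0))
  structure(
    list(name = name, frozen_scope = frozen_scope, lr_min = lr_min,
         lr_max = lr_max, steps_per_cycle = as.integer(steps_per_cycle),
         max_epochs = as.integer(max_epochs),
         steps_per_epoch = as.integer(steps_per_epoch),
         patience = as.integer(patience),
         output = if (name %in% c("decoder2d_only", "full_2d")) "2d" else "3d"),
    class = "training_phase"
  )
}

#' Default four-phase schedule
#'
#' @param ... Arguments forwarded to every [training_phase()].
#' @return List of the four phases in order.
#' @export
default_schedule <- function(...) {
  lapply(PHASE_NAMES, function(nm) training_phase(nm, ...))
}

dice_arrays <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a * b) / s
}

validation_dsc <- function(net, val_cases, threshold = 0.5, output = "3d") {
  mean(vapply(val_cases, function(cs) {
    d <- dim(cs$image$voxels)
    x <- array(c(cs$image$voxels, cs$liver$voxels), dim = c(d, 2))
    fwd <- network_forward(net, x, train = FALSE)
    probs <- if (output == "2d") fwd$aux2d[[1]] else fwd$output[[1]]
    dice_arrays((probs[, , , 2] >= threshold) + 0, cs$disease$voxels)
  }, numeric(1)))
}

#' Train one phase
#'
#' Optimizes the per-voxel two-class cross entropy with the Adam optimizer
#' under a triangular cyclical learning rate. Weights in the phase's frozen
#' scope are bit-identical before and after. Validation is evaluated on whole
#' livers (the architectures accept variable input sizes), not on slabs.
#'
#' @param net A `network`.
#' @param phase A `training_phase`.
#' @param train_slabs List of `slab` objects.
#' @param val_cases List of `list(image, liver, disease)` whole-liver cases
#'   (image already normalized).
#' @param rng_seed Seed for batch sampling and augmentation.
#' @param batch_size Slabs per step; the reference protocol used 8-16,
#'   smaller batches are accepted for reduced problem sizes.
#' @param augment Apply random flip/mirror augmentation on the fly.
#' @param snapshot_dir Optional directory for periodic prediction snapshots
#'   (PNG grids of image / ground truth / prediction for the first
#'   validation case).
#' @return List with the trained `net` and a `run_record`.
#' @export
train_phase <- function(net, phase, train_slabs, val_cases, rng_seed = 1L,
                        batch_size = 8L, augment = TRUE,
                        snapshot_dir = NULL) {
  stopifnot(inherits(phase, "training_phase"))
  groups <- network_groups(net)
  unknown <- setdiff(phase$frozen_scope, groups)
  if (length(unknown) > 0)
    stop("train_phase: frozen_scope names unknown sub-network(s): ",
         paste(unknown, collapse = ", "))
  if (batch_size < 1) stop("train_phase: batch_size must be >= 1")
  net$frozen <- phase$frozen_scope

  lr_min <- phase$lr_min
  lr_max <- phase$lr_max
  lr_trace <- NULL
  set.seed(rng_seed)
  if (is.null(lr_min) || is.null(lr_max)) {
    idx <- sample.int(length(train_slabs),
                      min(batch_size, length(train_slabs)))
    batch <- list(xs = lapply(train_slabs[idx], slab_input),
                  labels = lapply(train_slabs[idx], `[[`, "label"))
    rng <- find_lr_range(net, list(batch), output = phase$output)
    lr_min <- rng$lr_min
    lr_max <- rng$lr_max
    lr_trace <- rng$trace
  }

  state <- new_adam_state()
  history <- list()
  val_history <- list()
  best <- -Inf
  best_weights <- net$weights
  stale <- 0
  step <- 0
  for (epoch in seq_len(phase$max_epochs)) {
    for (s in seq_len(phase$steps_per_epoch)) {
      idx <- sample.int(length(train_slabs), batch_size, replace = TRUE)
      slabs <- train_slabs[idx]
      if (augment)
        slabs <- lapply(slabs, flip_mirror_augment, axes = NULL)
      lr <- cyclical_lr(step, lr_min, lr_max, phase$steps_per_cycle)
      res <- train_step(net, lapply(slabs, slab_input),
                        lapply(slabs, `[[`, "label"), lr, state,
                        output = phase$output)
      net <- res$net
      state <- res$state
      history[[length(history) + 1]] <-
        data.frame(step = step, lr = lr, loss = res$loss)
      step <- step + 1
    }
    vd <- if (length(val_cases) > 0)
      validation_dsc(net, val_cases, output = phase$output) else NA
    val_history[[length(val_history) + 1]] <-
      data.frame(epoch = epoch, val_dsc = vd)
    if (!is.null(snapshot_dir) && length(val_cases) > 0)
      write_prediction_snapshot(
        file.path(snapshot_dir,
                  sprintf("%s-epoch%02d.png", phase$name, epoch)),
        val_cases[[1]], network_predict(net, val_cases[[1]]$image,
                                        val_cases[[1]]$liver))
    if (!is.na(vd) && vd > best) {
      best <- vd
      best_weights <- net$weights
      stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= phase$patience) break
    }
  }
  record <- structure(
    list(run_seed = rng_seed, phase = phase$name,
         history = do.call(rbind, history),
         val_history = do.call(rbind, val_history),
         best_validation_dsc = if (is.finite(best)) best else NA_real_,
         lr_min = lr_min, lr_max = lr_max, lr_trace = lr_trace),
    class = "run_record"
  )
  if (is.finite(best) && length(val_cases) > 0) net$weights <- best_weights
  net$frozen <- character(0)
  list(net = net, record = record)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> seed %d%s: best validation DSC %s\n",
              x$run_seed,
              if (!is.null(x$phase)) paste0(" (", x$phase, ")") else "",
              format(x$best_validation_dsc, digits = 3)))
  invisible(x)
}

#' Run the staged four-phase training schedule
#'
#' Phases must appear in the canonical order (2D decoder only, full 2D,
#' 3D only, end to end); weights are carried forward and, unless a phase
#' fixes its rates, the learning-rate range is re-determined at the start of
#' each phase.
#'
#' @param net A `network` (hybrid W-Net for the full schedule).
#' @param schedule List of four `training_phase`s in order.
#' @param data List with `train_slabs` and `val_cases` as in
#'   [train_phase()].
#' @param rng_seed Integer seed.
#' @param ... Passed to [train_phase()].
#' @return List with the trained `net`, per-phase `records`, and
#'   `best_validation_dsc` from the final phase.
#' @export
staged_train <- function(net, schedule, data, rng_seed = 1L, ...) {
  names_in <- vapply(schedule, function(p) p$name, character(1))
  if (!identical(names_in, PHASE_NAMES))
    stop("staged_train: schedule must be the four phases in order: ",
         paste(PHASE_NAMES, collapse = ", "))
  records <- list()
  for (k in seq_along(schedule)) {
    res <- train_phase(net, schedule[[k]], data$train_slabs, data$val_cases,
                       rng_seed = rng_seed + k, ...)
    net <- res$net
    records[[k]] <- res$record
  }
  structure(
    list(net = net, records = records, run_seed = rng_seed,
         best_validation_dsc = records[[length(records)]]$best_validation_dsc),
    class = "staged_run"
  )
}

#' Select the best of several runs
#'
#' @param runs Non-empty list of run records (anything with
#'   `best_validation_dsc` and `run_seed`).
#' @return The run with maximal validation DSC; ties resolve to the lowest
#'   `run_seed`.
#' @export
select_best <- function(runs) {
  if (length(runs) == 0) stop("select_best: empty run list")
  dsc <- vapply(runs, function(r) r$best_validation_dsc, numeric(1))
  seeds <- vapply(runs, function(r) as.numeric(r$run_seed), numeric(1))
  best <- max(dsc)
  cand <- which(dsc == best)
  runs[[cand[which.min(seeds[cand])]]]
}

#' Train with random restarts
#'
#' Runs the full staged schedule `n_runs` times from independent random
#' initializations (default 3) and returns all runs plus the selection by
#' validation DSC.
#'
#' @param spec A `model_spec`.
#' @param schedule List of four `training_phase`s.
#' @param data As in [staged_train()].
#' @param n_runs Number of restarts (default 3).
#' @param rng_seed Base seed; run `i` initializes with `rng_seed + 100 * i`.
#' @param ... Passed to [train_phase()].
#' @return List with `runs` and `best`.
#' @export
run_restarts <- function(spec, schedule, data, n_runs = 3, rng_seed = 1L,
                         ...) {
  runs <- lapply(seq_len(n_runs), function(i) {
    seed_i <- rng_seed + 100L * i
    net <- instantiate_network(spec, rng_seed = seed_i)
    staged_train(net, schedule, data, rng_seed = seed_i, ...)
  })
  list(runs = runs, best = select_best(runs))
}

# PNG grid: image / ground truth / prediction for a few axial slices.
write_prediction_snapshot <- function(path, case, prob, n_slices = 4,
                                      threshold = 0.5) {
  if (!requireNamespace("png", quietly = TRUE)) return(invisible(NULL))
  img <- case$image$voxels
  gt <- case$disease$voxels
  pr <- (prob$voxels >= threshold) + 0
  nz <- dim(img)[1]
  picks <- unique(round(seq(1, nz, length.out = n_slices)))
  norm01 <- function(a) {
    rng <- range(a)
    if (diff(rng) == 0) a * 0 else (a - rng[1]) / diff(rng)
  }
  rows <- lapply(list(norm01(img), gt, pr), function(vol)
    do.call(cbind, lapply(picks, function(z) vol[z, , ])))
  grid <- do.call(rbind, rows)
  png::writePNG(grid, path)
  invisible(path)
}
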