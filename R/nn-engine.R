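# Network engine: instantiation, forward/backward passes and the Adam
# optimizer over the declarative model graph. Tensors are single-sample R
# arrays (z, y, x, c); a batch is a list of samples, joined only where batch
# statistics require it (batch normalization).

BN_EPS <- 1e-3
# running-statistics momentum: 0.9 keeps inference statistics usable after
# the short training phases this package targets on CPU
BN_MOMENTUM <- 0.9

#' Instantiate a network from a model specification
#'
#' Convolution weights use He initialization (`sd = sqrt(2 / fan_in)`),
#' biases start at zero, batch-norm gains at one. Pretrained weights are
#' loaded only from an explicitly supplied file; if the file is missing this
#' is an error, so falling back to random initialization is always an
#' explicit choice of the caller.
#'
#' @param spec A `model_spec`.
#' @param rng_seed Integer seed for the random initialization.
#' @param weights_file Optional path to a checkpoint saved with
#'   [save_network()] whose weights (matching node ids) seed this network.
#' @return A `network` object.
#' @export
instantiate_network <- function(spec, rng_seed = 1L, weights_file = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(rng_seed)
  weights <- list()
  for (n in spec$nodes) {
    key <- as.character(n$id)
    if (n$op == "conv") {
      fan_in <- prod(n$kernel) * n$in_channels
      weights[[key]] <- list(
        w = matrix(rnorm(fan_in * n$out_channels, sd = sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = n$out_channels),
        b = if (n$bias) numeric(n$out_channels) else NULL
      )
    } else if (n$op == "bn") {
      c_ <- n$in_channels
      weights[[key]] <- list(gamma = rep(1, c_), beta = numeric(c_),
                             rmean = numeric(c_), rvar = rep(1, c_))
    }
  }
  if (!is.null(weights_file)) {
    if (!file.exists(weights_file))
      stop(sprintf("instantiate_network: pretrained weight file '%s' not found; pass weights_file = NULL to request random initialization explicitly",
                   weights_file))
    saved <- readRDS(weights_file)
    src <- if (inherits(saved, "network")) saved$weights else saved
    for (key in intersect(names(weights), names(src)))
      weights[[key]] <- src[[key]]
  }
  structure(list(spec = spec, weights = weights, frozen = character(0)),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  pc <- count_parameters(x$spec, frozen = x$frozen)
  cat(sprintf("<network> %s: %s parameters (%s trainable), frozen groups: %s\n",
              x$spec$config$style, format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ","),
              if (length(x$frozen)) paste(x$frozen, collapse = ",") else "none"))
  invisible(x)
}

#' Extract the weights of one parameter group
#'
#' Used to verify the freeze contract: a frozen group's weights must be
#' identical before and after a training phase.
#'
#' @param net A `network`.
#' @param group Group name (e.g. `"enc2d"`, `"dec2d"`, `"net3d"`).
#' @return Named list of weight tensors.
#' @export
group_weights <- function(net, group) {
  ids <- vapply(net$spec$nodes, function(n)
    if (!is.na(n$group) && n$group == group &&
        n$op %in% c("conv", "bn")) n$id else NA_integer_, integer(1))
  net$weights[as.character(ids[!is.na(ids)])]
}

#' Names of the parameter groups of a network
#'
#' @param net A `network` or `model_spec`.
#' @return Character vector of group names.
#' @export
network_groups <- function(net) {
  spec <- if (inherits(net, "network")) net$spec else net
  gr <- vapply(spec$nodes, function(n) n$group %||% NA_character_,
               character(1))
  unique(gr[!is.na(gr)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a network checkpoint
#'
#' @param net A `network`.
#' @param path Checkpoint path (RDS). A JSON sidecar `<path>.json` records
#'   the configuration and parameter counts.
#' @return Invisibly, `path`.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  pc <- net$spec$parameter_counts
  jsonlite::write_json(
    list(style = net$spec$config$style, parameters = pc,
         frozen = net$frozen),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "network"))
  net
}

# reflect-pad a sample at the high end of each spatial axis to `target` dims
pad_reflect <- function(a, target) {
  d <- dim(a)
  for (ax in 1:3) {
    extra <- target[ax] - d[ax]
    if (extra > 0) {
      src <- pmax(d[ax] - seq_len(extra), 1)
      idx <- c(seq_len(d[ax]), src)
      a <- switch(ax,
                  a[idx, , , , drop = FALSE],
                  a[, idx, , , drop = FALSE],
                  a[, , idx, , drop = FALSE])
      d <- dim(a)
    }
  }
  a
}

crop_to <- function(a, dims) {
  a[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), , drop = FALSE]
}

upsample_nearest <- function(a, f) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = f[1]),
    rep(seq_len(d[2]), each = f[2]),
    rep(seq_len(d[3]), each = f[3]), , drop = FALSE]
}

downsample_sum <- function(a, f) {
  # adjoint of nearest upsampling: sum over each f-block
  d <- dim(a)
  out_d <- c(d[1:3] %/% f, d[4])
  out <- array(0, dim = out_d)
  for (dz in seq_len(f[1])) for (dy in seq_len(f[2])) for (dx in seq_len(f[3]))
    out <- out + a[seq(dz, d[1], by = f[1]), seq(dy, d[2], by = f[2]),
                   seq(dx, d[3], by = f[3]), , drop = FALSE]
  out
}

softmax4 <- function(a) {
  d <- dim(a)
  A <- matrix(a, ncol = d[4])
  m <- A[, 1]
  for (c_ in seq_len(d[4])[-1]) m <- pmax(m, A[, c_])
  E <- exp(A - m)
  array(E / rowSums(E), dim = d)
}

#' Run a forward pass
#'
#' Inputs of arbitrary spatial size are reflect-padded to the network's
#' pooling multiple and the outputs cropped back, so the output spatial shape
#' always equals the input spatial shape.
#'
#' @param net A `network`.
#' @param xs One sample array `(z, y, x, channels)` or a list of samples.
#' @param train Use batch statistics (and produce caches for the backward
#'   pass) instead of running statistics.
#' @param keep_acts Keep all activations (required for the backward pass).
#' @return List with `output` (list of per-sample class-probability arrays),
#'   `aux2d` and `feat2d` outputs where the graph defines them, and, when
#'   `keep_acts`, the internal state.
#' @export
network_forward <- function(net, xs, train = FALSE, keep_acts = FALSE) {
  spec <- net$spec
  if (!is.list(xs)) xs <- list(xs)
  orig_dims <- lapply(xs, dim)
  mult <- spec$pad_multiple
  xs <- lapply(xs, function(a) {
    d <- dim(a)
    pad_reflect(a, c(ceiling(d[1:3] / mult) * mult, d[4]))
  })
  B <- length(xs)
  acts <- vector("list", length(spec$nodes))
  caches <- vector("list", length(spec$nodes))
  for (n in spec$nodes) {
    id <- n$id
    key <- as.character(id)
    ins <- lapply(n$inputs, function(i) acts[[i]])
    acts[[id]] <- switch(n$op,
      input = xs,
      channel_select = lapply(ins[[1]], function(a)
        a[, , , n$channel, drop = FALSE]),
      concat = lapply(seq_len(B), function(b) {
        parts <- lapply(ins, `[[`, b)
        d <- dim(parts[[1]])
        array(unlist(parts, use.names = FALSE),
              dim = c(d[1:3], sum(vapply(parts, function(p) dim(p)[4],
                                         numeric(1)))))
      }),
      add = lapply(seq_len(B), function(b) ins[[1]][[b]] + ins[[2]][[b]]),
      relu = lapply(ins[[1]], function(a) {
        a[a < 0] <- 0
        a
      }),
      conv = {
        w <- net$weights[[key]]
        lapply(ins[[1]], function(a)
          cpp_conv3d_fw(as.numeric(a), as.integer(dim(a)), w$w,
                        if (is.null(w$b)) numeric(0) else w$b,
                        n$kernel, n$stride))
      },
      bn = {
        w <- net$weights[[key]]
        xcat <- ins[[1]]
        nch <- n$in_channels
        frozen_bn <- !is.na(n$group) && n$group %in% net$frozen
        if (train && !frozen_bn) {
          mats <- lapply(xcat, function(a) matrix(a, ncol = nch))
          X <- if (length(mats) == 1) mats[[1]] else do.call(rbind, mats)
          mu <- colMeans(X)
          va <- colMeans(X^2) - mu^2
        } else {
          mu <- w$rmean
          va <- w$rvar
        }
        inv <- 1 / sqrt(pmax(va, 0) + BN_EPS)
        scl <- inv * w$gamma
        off <- w$beta - mu * scl
        out <- lapply(xcat, function(a) {
          d <- dim(a)
          A <- matrix(a, ncol = nch)
          array(sweep(A, 2, scl, "*") + rep(off, each = nrow(A)), dim = d)
        })
        if (train)
          caches[[id]] <- list(mu = mu, va = va, inv = inv,
                               frozen = frozen_bn)
        out
      },
      maxpool = {
        res <- lapply(ins[[1]], function(a)
          cpp_maxpool_fw(as.numeric(a), as.integer(dim(a)), n$factor))
        if (keep_acts)
          caches[[id]] <- list(argmax = lapply(res, `[[`, "argmax"),
                               in_dims = lapply(ins[[1]], dim))
        lapply(res, `[[`, "out")
      },
      avgpool = {
        if (keep_acts) caches[[id]] <- list(in_dims = lapply(ins[[1]], dim))
        lapply(ins[[1]], function(a)
          cpp_avgpool_fw(as.numeric(a), as.integer(dim(a)), n$factor))
      },
      upsample = lapply(ins[[1]], function(a) upsample_nearest(a, n$factor)),
      softmax = lapply(ins[[1]], softmax4),
      stop("unknown op in forward: ", n$op)
    )
  }
  crop_all <- function(id) {
    if (is.null(id)) return(NULL)
    lapply(seq_len(B), function(b) crop_to(acts[[id]][[b]], orig_dims[[b]]))
  }
  out <- list(output = crop_all(spec$output),
              aux2d = crop_all(spec$aux2d),
              feat2d = crop_all(spec$feat2d))
  if (keep_acts) {
    out$acts <- acts
    out$caches <- caches
    out$padded_dims <- lapply(xs, dim)
    out$orig_dims <- orig_dims
  }
  out
}

#' Per-voxel two-class cross-entropy loss and logit gradient
#'
#' Sparse categorical cross entropy: labels are class indices (0 = normal,
#' 1 = disease) and probabilities come from the softmax output. The returned
#' gradient is with respect to the softmax input (logits), averaged over all
#' voxels of the batch.
#'
#' @param probs List of per-sample probability arrays `(z, y, x, classes)`.
#' @param labels List of per-sample integer arrays `(z, y, x)`.
#' @return List with `loss` and `dlogits` (list of per-sample arrays).
#' @export
softmax_xent <- function(probs, labels) {
  B <- length(probs)
  total_vox <- sum(vapply(probs, function(p) prod(dim(p)[1:3]), numeric(1)))
  loss <- 0
  dlogits <- vector("list", B)
  for (b in seq_len(B)) {
    p <- probs[[b]]
    d <- dim(p)
    nvox <- prod(d[1:3])
    lab <- as.integer(labels[[b]])
    sel <- seq_len(nvox) + nvox * lab
    loss <- loss - sum(log(pmax(p[sel], 1e-12)))
    one <- array(0, dim = d)
    one[sel] <- 1
    dlogits[[b]] <- (p - one) / total_vox
  }
  list(loss = loss / total_vox, dlogits = dlogits)
}

# Backward pass: seeds is a named list (node id as character) of output-side
# gradients (each a list of per-sample arrays, on the padded grid). Returns
# per-node weight gradients.
network_backward <- function(net, fwd, seeds) {
  spec <- net$spec
  nn <- length(spec$nodes)
  B <- length(fwd$acts[[spec$input]])
  grads <- vector("list", nn)
  wgrads <- list()
  for (key in names(seeds)) {
    id <- as.integer(key)
    grads[[id]] <- seeds[[key]]
  }
  add_grad <- function(id, g) {
    if (is.null(grads[[id]])) grads[[id]] <<- g
    else grads[[id]] <<- lapply(seq_len(B), function(b)
      grads[[id]][[b]] + g[[b]])
  }
  for (i in rev(seq_len(nn))) {
    n <- spec$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    key <- as.character(n$id)
    switch(n$op,
      input = NULL,
      channel_select = {
        xin <- fwd$acts[[n$inputs[1]]]
        add_grad(n$inputs[1], lapply(seq_len(B), function(b) {
          d <- dim(xin[[b]])
          out <- array(0, dim = d)
          out[, , , n$channel] <- g[[b]]
          out
        }))
      },
      concat = {
        off <- 0L
        for (src in n$inputs) {
          ch <- node_ch_spec(spec, src)
          add_grad(src, lapply(seq_len(B), function(b)
            g[[b]][, , , off + seq_len(ch), drop = FALSE]))
          off <- off + ch
        }
      },
      add = {
        add_grad(n$inputs[1], g)
        add_grad(n$inputs[2], g)
      },
      relu = {
        y <- fwd$acts[[i]]
        add_grad(n$inputs[1], lapply(seq_len(B), function(b)
          g[[b]] * (y[[b]] > 0)))
      },
      conv = {
        w <- net$weights[[key]]
        xin <- fwd$acts[[n$inputs[1]]]
        need_dx <- n$inputs[1] != spec$input
        dw <- matrix(0, nrow = nrow(w$w), ncol = ncol(w$w))
        db <- numeric(ncol(w$w))
        dxs <- if (need_dx) vector("list", B) else NULL
        for (b in seq_len(B)) {
          r <- cpp_conv3d_bw(as.numeric(xin[[b]]),
                             as.integer(dim(xin[[b]])), w$w,
                             as.numeric(g[[b]]), n$kernel, n$stride,
                             need_dx)
          dw <- dw + r$dw
          db <- db + r$db
          if (need_dx) dxs[[b]] <- r$dx
        }
        wgrads[[key]] <- list(w = dw, b = if (is.null(w$b)) NULL else db)
        if (need_dx) add_grad(n$inputs[1], dxs)
      },
      bn = {
        w <- net$weights[[key]]
        cache <- fwd$caches[[i]]
        xin <- fwd$acts[[n$inputs[1]]]
        nch <- n$in_channels
        m <- sum(vapply(xin, function(a) prod(dim(a)[1:3]), numeric(1)))
        XH <- lapply(xin, function(a) {
          A <- matrix(a, ncol = nch)
          (A - rep(cache$mu, each = nrow(A))) *
            rep(cache$inv, each = nrow(A))
        })
        G <- lapply(g, function(a) matrix(a, ncol = nch))
        dgamma <- Reduce(`+`, lapply(seq_len(B), function(b)
          colSums(G[[b]] * XH[[b]])))
        dbeta <- Reduce(`+`, lapply(G, colSums))
        wgrads[[key]] <- list(gamma = dgamma, beta = dbeta)
        gi <- w$gamma * cache$inv
        dx <- if (isTRUE(cache$frozen)) {
          # inference-mode statistics: the affine map is the whole gradient
          lapply(seq_len(B), function(b) {
            d <- dim(g[[b]])
            array(G[[b]] * rep(gi, each = nrow(G[[b]])), dim = d)
          })
        } else {
          lapply(seq_len(B), function(b) {
            d <- dim(g[[b]])
            nr <- nrow(G[[b]])
            array(rep(gi, each = nr) *
                    (G[[b]] - rep(dbeta / m, each = nr) -
                       XH[[b]] * rep(dgamma / m, each = nr)), dim = d)
          })
        }
        add_grad(n$inputs[1], dx)
      },
      maxpool = {
        cache <- fwd$caches[[i]]
        add_grad(n$inputs[1], lapply(seq_len(B), function(b)
          cpp_maxpool_bw(as.numeric(g[[b]]), cache$argmax[[b]],
                         as.integer(cache$in_dims[[b]]))))
      },
      avgpool = {
        cache <- fwd$caches[[i]]
        add_grad(n$inputs[1], lapply(seq_len(B), function(b)
          cpp_avgpool_bw(as.numeric(g[[b]]),
                         as.integer(cache$in_dims[[b]]), n$factor)))
      },
      upsample = {
        add_grad(n$inputs[1], lapply(seq_len(B), function(b)
          downsample_sum(g[[b]], n$factor)))
      },
      softmax = NULL,  # handled by the fused loss (gradients seed its input)
      stop("unknown op in backward: ", n$op)
    )
    grads[i] <- list(NULL)  # release
  }
  wgrads
}

node_ch_spec <- function(spec, id) spec$nodes[[id]]$out_channels

# update running BN statistics from a training forward pass
update_bn_running <- function(net, fwd) {
  for (n in net$spec$nodes) {
    if (n$op != "bn") next
    cache <- fwd$caches[[n$id]]
    if (is.null(cache) || isTRUE(cache$frozen)) next
    key <- as.character(n$id)
    w <- net$weights[[key]]
    w$rmean <- BN_MOMENTUM * w$rmean + (1 - BN_MOMENTUM) * cache$mu
    w$rvar <- BN_MOMENTUM * w$rvar + (1 - BN_MOMENTUM) * cache$va
    net$weights[[key]] <- w
  }
  net
}

new_adam_state <- function() list(t = 0, m = list(), v = list())

adam_update <- function(net, wgrads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  state$t <- state$t + 1
  frozen_ids <- vapply(net$spec$nodes, function(n)
    !is.na(n$group) && n$group %in% net$frozen, logical(1))
  for (key in names(wgrads)) {
    id <- as.integer(key)
    if (frozen_ids[id]) next
    for (pn in names(wgrads[[key]])) {
      gr <- wgrads[[key]][[pn]]
      if (is.null(gr)) next
      skey <- paste0(key, ".", pn)
      if (is.null(state$m[[skey]])) {
        state$m[[skey]] <- gr * 0
        state$v[[skey]] <- gr * 0
      }
      state$m[[skey]] <- beta1 * state$m[[skey]] + (1 - beta1) * gr
      state$v[[skey]] <- beta2 * state$v[[skey]] + (1 - beta2) * gr^2
      mhat <- state$m[[skey]] / (1 - beta1^state$t)
      vhat <- state$v[[skey]] / (1 - beta2^state$t)
      net$weights[[key]][[pn]] <- net$weights[[key]][[pn]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

#' Predict a disease probability map for one patient
#'
#' Builds the two-channel input (normalized image, liver mask), runs the
#' network on the whole volume in inference mode and returns the disease
#' class probability.
#'
#' @param net A trained `network`.
#' @param image Normalized `ct_volume`.
#' @param liver Liver `binary_mask` on the same grid.
#' @return A `probability_map`.
#' @export
network_predict <- function(net, image, liver) {
  stop_grid_mismatch(image, liver, "network_predict")
  d <- dim(image$voxels)
  x <- array(c(image$voxels, liver$voxels), dim = c(d, 2))
  fwd <- network_forward(net, x, train = FALSE)
  p <- fwd$output[[1]][, , , 2]
  probability_map(pmin(pmax(array(p, dim = d), 0), 1), image$spacing,
                  image$origin, image$patient_id, model = "network")
}
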