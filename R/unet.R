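# 3D U-Net encoder-decoder segmentation network.
#
# Architecture: E encoder blocks (default 4), each two 3x3x3 convolutions
# with batch normalization and ReLU; the first E-1 blocks end in 2x2x2 max
# pooling (stride 2). E-1 decoder blocks, each nearest-neighbour x2
# up-sampling, a fusion layer (channel concatenation with the matching
# encoder output), and two 3x3x3 convolutions with BN + ReLU. A final
# 1x1x1 convolution maps to class scores and a per-voxel softmax yields
# probability maps including the background class. Channel widths double
# per encoder block from base_channels. Trained by maximizing soft Dice
# between predicted and one-hot ground-truth probability maps with Adam.

#' U-Net network configuration
#'
#' @param n_classes Number of output classes including background.
#' @param n_encoder_blocks Encoder depth, default 4 (the decoder always has
#'   one block fewer).
#' @param base_channels Channels of the first encoder block, default 8;
#'   widths double per block.
#' @param upsample `"nearest"` (default) or `"transposed"`-style learned
#'   up-sampling (implemented as nearest-neighbour up-sampling followed by
#'   the block's convolutions either way; the switch is kept for
#'   compatibility and affects nothing else).
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(n_classes, n_encoder_blocks = 4, base_channels = 8,
                        upsample = c("nearest", "transposed"), seed = 1L) {
  upsample <- match.arg(upsample)
  stopifnot(n_classes >= 2, n_encoder_blocks >= 2, base_channels >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_encoder_blocks = as.integer(n_encoder_blocks),
                 n_decoder_blocks = as.integer(n_encoder_blocks) - 1L,
                 base_channels = as.integer(base_channels),
                 kernel = c(3L, 3L, 3L), pool_stride = 2L,
                 upsample = upsample, seed = as.integer(seed)),
            class = "unet_config")
}

#' Training configuration for the U-Net
#'
#' @param learning_rate Adam learning rate, default 1e-3.
#' @param n_epochs Number of passes over the training volumes.
#' @param batch_size Volumes per Adam step, default 1.
#' @param smoothing_eps Soft-Dice smoothing constant, default 1.
#' @param seed Integer seed.
#' @return Object of class `unet_train_config`.
#' @export
unet_train_config <- function(learning_rate = 1e-3, n_epochs = 20,
                              batch_size = 1, smoothing_eps = 1, seed = 1L) {
  stopifnot(learning_rate > 0, n_epochs >= 0, batch_size >= 1, smoothing_eps > 0)
  structure(list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 smoothing_eps = smoothing_eps, seed = as.integer(seed)),
            class = "unet_train_config")
}

# channel plan: list of conv layer specs in forward order
.unet_plan <- function(config) {
  E <- config$n_encoder_blocks
  B <- config$base_channels
  enc_out <- B * 2^(seq_len(E) - 1)
  enc_in <- c(1L, enc_out[-E])
  dec <- lapply(seq_len(E - 1), function(d) {
    e <- E - d
    up_ch <- if (d == 1) enc_out[E] else enc_out[E - d + 1]
    list(skip = e, conv1 = c(up_ch + enc_out[e], enc_out[e]),
         conv2 = c(enc_out[e], enc_out[e]))
  })
  list(enc_in = enc_in, enc_out = enc_out, dec = dec)
}

.he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

#' Build a 3D U-Net
#'
#' Initialises all parameters reproducibly from `config$seed` (He-normal
#' convolution weights, unit-gain batch norm). The returned handle maps an
#' intensity volume whose spatial dimensions are divisible by
#' `2^(n_encoder_blocks - 1)` to probability maps of identical spatial
#' shape.
#'
#' @param config A [unet_config()].
#' @return Object of class `unet3d` (untrained).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)
  plan <- .unet_plan(config)
  params <- list(); bn <- list()
  add_conv <- function(name, cin, cout) {
    params[[paste0(name, ".W")]] <<- matrix(.he_init(27 * cin, 27 * cin * cout),
                                            27 * cin, cout)
    params[[paste0(name, ".b")]] <<- numeric(cout)
    params[[paste0(name, ".gamma")]] <<- rep(1, cout)
    params[[paste0(name, ".beta")]] <<- numeric(cout)
    bn[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
  }
  E <- config$n_encoder_blocks
  for (b in seq_len(E)) {
    add_conv(sprintf("enc%d.conv1", b), plan$enc_in[b], plan$enc_out[b])
    add_conv(sprintf("enc%d.conv2", b), plan$enc_out[b], plan$enc_out[b])
  }
  for (d in seq_len(E - 1)) {
    add_conv(sprintf("dec%d.conv1", d), plan$dec[[d]]$conv1[1], plan$dec[[d]]$conv1[2])
    add_conv(sprintf("dec%d.conv2", d), plan$dec[[d]]$conv2[1], plan$dec[[d]]$conv2[2])
  }
  cin_final <- plan$enc_out[1]
  params[["final.W"]] <- matrix(.he_init(cin_final, cin_final * config$n_classes),
                                cin_final, config$n_classes)
  params[["final.b"]] <- numeric(config$n_classes)
  structure(list(config = config, plan = plan, params = params, bn = bn,
                 class_roles = NULL, trained = FALSE, loss_history = numeric(0)),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1))
  cat(sprintf("unet3d: %d encoder / %d decoder blocks, base %d channels, %d classes, %s (%d parameters)\n",
              x$config$n_encoder_blocks, x$config$n_decoder_blocks,
              x$config$base_channels, x$config$n_classes,
              if (x$trained) sprintf("trained (%d epochs)", length(x$loss_history))
              else "untrained", np))
  invisible(x)
}

.check_unet_shape <- function(config, dims) {
  div <- 2^(config$n_encoder_blocks - 1)
  if (any(dims %% div != 0)) {
    pad <- (div - dims %% div) %% div
    stop(sprintf(paste0("unet3d: input spatial dimensions (%s) must each be ",
                        "divisible by %d; pad by (%s) voxels (shape error)"),
                 paste(dims, collapse = "x"), div, paste(pad, collapse = ",")))
  }
}

.as_4d <- function(x) { if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L); x }

# conv + BN + ReLU forward; training mode uses per-volume batch statistics
# and updates running stats (momentum 0.1), eval mode uses running stats.
# The BN affine and ReLU are fused (z = max(0, y*scale + bias)); the im2col
# matrix of the input is cached in training mode for the backward pass.
.cbr_fwd <- function(net, name, x, training, momentum = 0.1, eps = 1e-5) {
  p <- net$params
  W <- p[[paste0(name, ".W")]]
  d4 <- dim(x)
  y <- conv3_fwd(x, W, p[[paste0(name, ".b")]], d4)
  d <- dim(y); n <- prod(d[1:3]); C <- d[4]
  dim(y) <- c(n, C)
  if (training) {
    mu <- colMeans(y)
    va <- colMeans(y^2) - mu^2
    st <- net$bn[[name]]
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va * n / max(n - 1, 1)
    net$bn[[name]] <- st
  } else {
    mu <- net$bn[[name]]$mean
    va <- net$bn[[name]]$var
  }
  inv <- 1 / sqrt(va + eps)
  gamma <- p[[paste0(name, ".gamma")]]
  scale <- gamma * inv
  bias <- p[[paste0(name, ".beta")]] - mu * scale
  z <- affine_relu_fwd(y, scale, bias, d)
  cache <- if (training)
    list(x = x, in_dims = d4, y = y, mu = mu, inv = inv, z = z,
         scale = scale, dims = d) else NULL
  list(out = z, net = net, cache = cache)
}

.cbr_bwd <- function(net, name, cache, dout, grads) {
  p <- net$params
  d <- cache$dims; n <- prod(d[1:3]); C <- d[4]
  gamma <- p[[paste0(name, ".gamma")]]
  mdz <- affine_relu_bwd(cache$z, dout, cache$scale)$masked_dz
  dim(mdz) <- c(n, C)
  xhat <- sweep(sweep(cache$y, 2, cache$mu), 2, cache$inv, "*")
  dgamma <- colSums(mdz * xhat)
  dbeta <- colSums(mdz)
  dxhat <- sweep(mdz, 2, gamma, "*")
  # standard batch-norm backward (batch statistics)
  dy <- sweep(dxhat - matrix(colMeans(dxhat), n, C, byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, C, byrow = TRUE),
              2, cache$inv, "*")
  dim(dy) <- d
  cb <- conv3_bwd(cache$x, p[[paste0(name, ".W")]], dy, cache$in_dims)
  grads[[paste0(name, ".W")]] <- grads[[paste0(name, ".W")]] + cb$dw
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + cb$db
  grads[[paste0(name, ".gamma")]] <- grads[[paste0(name, ".gamma")]] + dgamma
  grads[[paste0(name, ".beta")]] <- grads[[paste0(name, ".beta")]] + dbeta
  list(dx = cb$dx, grads = grads)
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# full forward pass; returns softmax probabilities (n x C matrix), spatial
# dims, and (when training) all caches needed for the backward pass.
.unet_fwd <- function(net, x, training) {
  cfg <- net$config; E <- cfg$n_encoder_blocks
  x <- .as_4d(x)
  .check_unet_shape(cfg, dim(x)[1:3])
  caches <- list(); skips <- list(); pools <- list()
  h <- x
  for (b in seq_len(E)) {
    for (cv in 1:2) {
      nm <- sprintf("enc%d.conv%d", b, cv)
      r <- .cbr_fwd(net, nm, h, training); net <- r$net
      caches[[nm]] <- r$cache; h <- r$out
    }
    if (b < E) {
      skips[[b]] <- h
      mp <- maxpool3_fwd(h, dim(h))
      pools[[b]] <- list(idx = mp$idx, in_dims = dim(h))
      h <- mp$y
    }
  }
  for (d in seq_len(E - 1)) {
    up <- upsample3_fwd(h, dim(h))
    caches[[sprintf("dec%d.updims", d)]] <- dim(h)
    skip <- skips[[E - d]]
    caches[[sprintf("dec%d.upch", d)]] <- dim(up)[4]
    h <- .concat_ch(up, skip)
    for (cv in 1:2) {
      nm <- sprintf("dec%d.conv%d", d, cv)
      r <- .cbr_fwd(net, nm, h, training); net <- r$net
      caches[[nm]] <- r$cache; h <- r$out
    }
  }
  dh <- dim(h); n <- prod(dh[1:3])
  hm <- matrix(h, n, dh[4])
  scores <- sweep(hm %*% net$params[["final.W"]], 2, net$params[["final.b"]], "+")
  m <- scores - apply(scores, 1, max)
  e <- exp(m)
  probs <- e / rowSums(e)
  list(net = net, probs = probs, spatial = dh[1:3], hm = hm,
       caches = caches, pools = pools)
}

.unet_bwd <- function(net, fwd, dprobs) {
  cfg <- net$config; E <- cfg$n_encoder_blocks
  probs <- fwd$probs
  # softmax backward
  dscores <- probs * (dprobs - rowSums(dprobs * probs))
  grads <- lapply(net$params, function(p) p * 0)
  grads[["final.W"]] <- crossprod(fwd$hm, dscores)
  grads[["final.b"]] <- colSums(dscores)
  dh <- dscores %*% t(net$params[["final.W"]])
  last <- fwd$caches[[sprintf("dec%d.conv2", E - 1)]]$dims
  dh <- array(dh, last)
  dskip_acc <- vector("list", E - 1)
  for (d in rev(seq_len(E - 1))) {
    for (cv in 2:1) {
      nm <- sprintf("dec%d.conv%d", d, cv)
      r <- .cbr_bwd(net, nm, fwd$caches[[nm]], dh, grads)
      grads <- r$grads; dh <- r$dx
    }
    upch <- fwd$caches[[sprintf("dec%d.upch", d)]]
    dd <- dim(dh)
    dup <- dh[, , , seq_len(upch), drop = FALSE]
    dskip_acc[[E - d]] <- dh[, , , upch + seq_len(dd[4] - upch), drop = FALSE]
    dh <- upsample3_bwd(dup, fwd$caches[[sprintf("dec%d.updims", d)]])
  }
  for (b in rev(seq_len(E))) {
    if (b < E) {
      dh <- maxpool3_bwd(fwd$pools[[b]]$idx, dh, fwd$pools[[b]]$in_dims)
      dh <- dh + dskip_acc[[b]]
    }
    for (cv in 2:1) {
      nm <- sprintf("enc%d.conv%d", b, cv)
      r <- .cbr_bwd(net, nm, fwd$caches[[nm]], dh, grads)
      grads <- r$grads; dh <- r$dx
    }
  }
  grads
}

#' Per-voxel class probability maps
#'
#' @param maps 4D array (i, j, k, class) of probabilities summing to 1 per
#'   voxel.
#' @param grid The [voxel_grid()] of the input volume.
#' @param class_roles Character vector of roles in class order (background
#'   first).
#' @return Object of class `prob_maps`.
#' @export
prob_maps <- function(maps, grid, class_roles) {
  stopifnot(length(dim(maps)) == 4L, dim(maps)[4] == length(class_roles))
  sums <- rowSums(matrix(maps, prod(dim(maps)[1:3]), dim(maps)[4]))
  if (max(abs(sums - 1)) > 1e-5)
    stop("prob_maps: per-voxel probabilities must sum to 1 within 1e-5")
  structure(list(grid = grid, maps = maps, class_roles = class_roles),
            class = "prob_maps")
}

#' @export
print.prob_maps <- function(x, ...) {
  cat(sprintf("prob_maps: %s, %d classes (%s)\n",
              paste(dim(x$maps)[1:3], collapse = "x"), dim(x$maps)[4],
              paste(x$class_roles, collapse = ", ")))
  invisible(x)
}

# one-hot ground-truth probability maps (values 0 or 1) from a label volume
.one_hot <- function(labels, label_map, class_roles) {
  codes <- label_map[class_roles]
  bad <- setdiff(unique(as.vector(labels)), unname(codes))
  if (length(bad))
    stop("unet3d: label(s) ", paste(bad, collapse = ", "),
         " outside the class set (data error)")
  d <- dim(labels)
  out <- array(0, c(d, length(class_roles)))
  for (ci in seq_along(class_roles))
    out[, , , ci] <- as.numeric(labels == codes[[ci]])
  out
}

#' Soft Dice loss between probability maps
#'
#' `1 - mean over classes of (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`,
#' the multiclass soft Dice objective maximized during training (ground
#' truth is one-hot, i.e. probability maps with values 0 or 1). The value
#' lies in `[0, 1]` and is ~0 exactly when prediction equals truth (up to
#' the epsilon smoothing).
#'
#' @param pred,truth `prob_maps` objects (or 4D arrays) with matching shape
#'   and class count.
#' @param eps Smoothing constant, default 1.
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(pred, truth, eps = 1) {
  p <- if (inherits(pred, "prob_maps")) pred$maps else pred
  g <- if (inherits(truth, "prob_maps")) truth$maps else truth
  if (!identical(dim(p), dim(g)))
    stop("soft_dice_loss: class count or shape mismatch (contract error)")
  C <- dim(p)[4]
  pm <- matrix(p, ncol = C); gm <- matrix(g, ncol = C)
  dice_c <- (2 * colSums(pm * gm) + eps) / (colSums(pm) + colSums(gm) + eps)
  1 - mean(dice_c)
}

# gradient of soft_dice_loss wrt pred (n x C matrix in, n x C matrix out)
.soft_dice_grad <- function(pm, gm, eps) {
  C <- ncol(pm)
  num <- 2 * colSums(pm * gm) + eps
  den <- colSums(pm) + colSums(gm) + eps
  # d/dp of -(1/C) * num/den
  sweep(gm, 2, 2 / den, "*") * (-1 / C) + matrix(num / den^2 / C, nrow(pm), C, byrow = TRUE)
}

#' Train a U-Net by soft-Dice maximization with Adam
#'
#' Runs `n_epochs` passes over the training pairs in a fixed order,
#' accumulating gradients over `batch_size` volumes per Adam step. Ground
#' truth is converted to one-hot probability maps; the class order
#' (background first, then ascending label code) is recorded on the
#' returned handle. Training is deterministic given the configuration
#' seeds.
#'
#' @param net A [build_unet()] handle.
#' @param pairs List of subjects, each `list(intensity, labels)`.
#' @param tconfig A [unet_train_config()].
#' @return The trained `unet3d` handle with `$loss_history` (mean training
#'   loss per epoch).
#' @export
train_unet <- function(net, pairs, tconfig = unet_train_config()) {
  stopifnot(inherits(net, "unet3d"), inherits(tconfig, "unet_train_config"),
            length(pairs) >= 1)
  g0 <- pairs[[1]]$labels$grid
  for (p in pairs) {
    if (!identical(p$labels$grid$shape, g0$shape))
      stop("train_unet: all pairs must share one grid shape (data error)")
  }
  lm <- pairs[[1]]$labels$label_map
  class_roles <- names(sort(lm))
  if (length(class_roles) != net$config$n_classes)
    stop(sprintf("train_unet: label map has %d classes but network expects %d (data error)",
                 length(class_roles), net$config$n_classes))
  net$class_roles <- class_roles
  if (tconfig$n_epochs == 0L) { net$loss_history <- numeric(0); return(net) }
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(tconfig$seed)
  eps <- tconfig$smoothing_eps
  adam_m <- lapply(net$params, function(p) p * 0)
  adam_v <- lapply(net$params, function(p) p * 0)
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  onehots <- lapply(pairs, function(p) .one_hot(p$labels$labels, lm, class_roles))
  history <- numeric(tconfig$n_epochs)
  for (epoch in seq_len(tconfig$n_epochs)) {
    losses <- numeric(length(pairs))
    acc <- NULL; acc_n <- 0
    for (i in seq_along(pairs)) {
      fwd <- .unet_fwd(net, pairs[[i]]$intensity$values, training = TRUE)
      net <- fwd$net
      C <- net$config$n_classes
      gm <- matrix(onehots[[i]], ncol = C)
      dice_c <- (2 * colSums(fwd$probs * gm) + eps) /
        (colSums(fwd$probs) + colSums(gm) + eps)
      losses[i] <- 1 - mean(dice_c)
      dprobs <- .soft_dice_grad(fwd$probs, gm, eps)
      grads <- .unet_bwd(net, fwd, dprobs)
      acc <- if (is.null(acc)) grads
             else mapply(function(a, g) a + g, acc, grads, SIMPLIFY = FALSE)
      acc_n <- acc_n + 1
      if (acc_n == tconfig$batch_size || i == length(pairs)) {
        t_step <- t_step + 1
        lr_t <- tconfig$learning_rate * sqrt(1 - b2^t_step) / (1 - b1^t_step)
        for (nm in names(net$params)) {
          g <- acc[[nm]] / acc_n
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          net$params[[nm]] <- net$params[[nm]] -
            lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + adam_eps)
        }
        acc <- NULL; acc_n <- 0
      }
    }
    history[epoch] <- mean(losses)
  }
  net$loss_history <- history
  net$trained <- TRUE
  net
}

#' Predict class probability maps for a volume
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' returns normalized per-voxel probability maps over all classes,
#' including background, with the same spatial shape as the input.
#'
#' @param net A (usually trained) `unet3d` handle.
#' @param vol An [intensity_volume()] with valid spatial shape.
#' @return A [prob_maps()] object.
#' @export
predict_probabilities <- function(net, vol) {
  stopifnot(inherits(net, "unet3d"), inherits(vol, "intensity_volume"))
  fwd <- .unet_fwd(net, vol$values, training = FALSE)
  maps <- array(fwd$probs, c(fwd$spatial, net$config$n_classes))
  roles <- net$class_roles
  if (is.null(roles)) roles <- paste0("class", seq_len(net$config$n_classes) - 1L)
  prob_maps(maps, vol$grid, roles)
}

#' Hard labels from probability maps
#'
#' Assigns each voxel the class of maximal probability; exact ties go to
#' the lowest class index, so background (class 1) wins ties against
#' foreground classes.
#'
#' @param maps A [prob_maps()] object.
#' @return A [label_volume()] whose label codes are `0..n_classes-1` in
#'   class order (roles from `maps$class_roles` when they are structure
#'   roles, otherwise a `background` + generic map).
#' @export
argmax_labels <- function(maps) {
  stopifnot(inherits(maps, "prob_maps"))
  d <- dim(maps$maps)
  m <- matrix(maps$maps, prod(d[1:3]), d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  roles <- maps$class_roles
  if (all(roles %in% knee_roles()) && !anyDuplicated(roles)) {
    lmap <- stats::setNames(seq_along(roles) - 1L, roles)
  } else {
    lmap <- stats::setNames(seq_along(roles) - 1L,
                            c("background", paste0("class", seq_len(d[4] - 1L)))[seq_along(roles)])
    lmap <- lmap[!duplicated(names(lmap))]
  }
  label_volume(array(lab, d[1:3]), maps$grid, lmap)
}

#' Trainer closure for the hold-out validation harness
#'
#' Packages [build_unet()] + [train_unet()] + [predict_probabilities()] +
#' [argmax_labels()] into the `trainer` interface of
#' [run_holdout_validation()].
#'
#' @param config A [unet_config()].
#' @param tconfig A [unet_train_config()].
#' @return Function `(train_subjects) -> function(intensity_volume) ->
#'   label_volume`.
#' @export
unet_trainer <- function(config, tconfig) {
  force(config); force(tconfig)
  function(train_subjects) {
    net <- build_unet(config)
    net <- train_unet(net, train_subjects, tconfig)
    function(iv) argmax_labels(predict_probabilities(net, iv))
  }
}

#' Save / load a U-Net handle
#'
#' The handle is self-describing: it embeds its [unet_config()], all
#' parameters, batch-norm running statistics and the class-role order.
#'
#' @param net A `unet3d` handle.
#' @param path File path.
#' @return `path` (save) or the restored `unet3d` (load).
#' @export
save_unet <- function(net, path) { saveRDS(net, path); invisible(path) }

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "unet3d"))
  net
}
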