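# Small configurations (base 2 channels, 8^3-16^3 volumes) keep these unit
# tests fast; the scaled-up segmentation-recovery experiment lives in the
# acceptance suite.

tiny_pairs <- function(n, shape = c(16, 16, 16), seed = 3, noise_sd = 8) {
  ds <- generate_segmentation_dataset(n, seed = seed, grid_shape = shape,
                                      noise_sd = noise_sd)
  lapply(ds, function(s) s[c("intensity", "labels")])
}

test_that("network output shape equals input shape across shapes", {
  net <- build_unet(unet_config(n_classes = 3, base_channels = 2, seed = 1))
  for (shape in list(c(8, 8, 8), c(16, 8, 8), c(8, 16, 24))) {
    g <- voxel_grid(shape, c(1, 1, 1))
    set.seed(1)
    iv <- intensity_volume(array(rnorm(prod(shape)), dim = shape), g)
    pm <- predict_probabilities(net, iv)
    expect_identical(dim(pm$maps), as.integer(c(shape, 3L)))
    sums <- rowSums(matrix(pm$maps, ncol = 3))
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
})

test_that("invalid input shape raises an error naming the divisibility", {
  net <- build_unet(unet_config(n_classes = 3, base_channels = 2, seed = 1))
  g <- voxel_grid(c(30, 30, 30), c(1, 1, 1))
  iv <- intensity_volume(array(0, dim = c(30, 30, 30)), g)
  expect_error(predict_probabilities(net, iv), "divisible by 8")
})

test_that("parameter initialization and prediction are deterministic", {
  cfg <- unet_config(n_classes = 4, base_channels = 2, seed = 7)
  n1 <- build_unet(cfg); n2 <- build_unet(cfg)
  expect_identical(n1$params, n2$params)
  n3 <- build_unet(unet_config(n_classes = 4, base_channels = 2, seed = 8))
  expect_false(identical(n1$params, n3$params))
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  iv <- intensity_volume(array(rnorm(512), dim = c(8, 8, 8)), g)
  expect_identical(predict_probabilities(n1, iv)$maps,
                   predict_probabilities(n1, iv)$maps)
})

test_that("soft dice loss: identity, disjoint, uniform-vs-onehot oracle", {
  d <- c(2, 2, 2)
  onehot <- array(0, c(d, 2)); onehot[, , , 1] <- c(1, 1, 1, 1, 0, 0, 0, 0)
  onehot[, , , 2] <- 1 - onehot[, , , 1]
  eps <- 1
  expect_lt(soft_dice_loss(onehot, onehot, eps), eps / (2 * 4 + eps))
  swapped <- onehot[, , , 2:1]
  # completely disjoint prediction
  expect_gt(soft_dice_loss(swapped, onehot, eps), 1 - eps / (4 + eps))
  # uniform prediction against one-hot truth: brute-force per-class sums
  unif <- array(0.5, c(d, 2))
  per_class <- (2 * 0.5 * 4 + eps) / (0.5 * 8 + 4 + eps)
  expect_equal(soft_dice_loss(unif, onehot, eps), 1 - per_class)
  # symmetry for binary maps and range
  expect_equal(soft_dice_loss(swapped, onehot, eps),
               soft_dice_loss(onehot, swapped, eps))
  expect_error(soft_dice_loss(unif, array(0.5, c(d, 3))), "mismatch")
})

test_that("argmax labeling matches an exhaustive per-voxel scan with background ties", {
  set.seed(12)
  d <- c(4, 4, 4); C <- 4
  raw <- array(runif(prod(d) * C), c(d, C))
  norm <- array(apply(raw, 1:3, function(v) v / sum(v)), c(C, d))
  maps_arr <- aperm(norm, c(2, 3, 4, 1))
  g <- voxel_grid(d, c(1, 1, 1))
  pm <- prob_maps(maps_arr, g, c("background", "tibia", "tibial_cartilage",
                                 "medial_meniscus"))
  lab <- argmax_labels(pm)
  m <- matrix(maps_arr, prod(d), C)
  for (v in seq_len(prod(d))) {
    best <- which(m[v, ] == max(m[v, ]))[1] - 1L
    expect_identical(as.vector(lab$labels)[v], best)
  }
  # exact tie between background and a foreground class goes to background
  tied <- array(0, c(2, 2, 2, 2)); tied[, , , 1] <- 0.5; tied[, , , 2] <- 0.5
  pmt <- prob_maps(tied, voxel_grid(c(2, 2, 2), c(1, 1, 1)),
                   c("background", "tibia"))
  expect_true(all(argmax_labels(pmt)$labels == 0L))
})

test_that("zero-epoch training returns an untrained handle with empty history", {
  pairs <- tiny_pairs(1, shape = c(8, 8, 8))
  net <- build_unet(unet_config(n_classes = 4, base_channels = 2, seed = 1))
  out <- train_unet(net, pairs, unet_train_config(n_epochs = 0))
  expect_identical(out$loss_history, numeric(0))
  expect_false(out$trained)
  expect_identical(out$params, net$params)
})

test_that("training is reproducible and reduces the loss on a tiny task", {
  pairs <- tiny_pairs(3)
  cfg <- unet_config(n_classes = 4, base_channels = 2, seed = 5)
  tc <- unet_train_config(learning_rate = 3e-3, n_epochs = 6, seed = 5)
  n1 <- train_unet(build_unet(cfg), pairs, tc)
  n2 <- train_unet(build_unet(cfg), pairs, tc)
  expect_identical(n1$loss_history, n2$loss_history)
  expect_identical(n1$params, n2$params)
  expect_identical(length(n1$loss_history), 6L)
  expect_lt(tail(n1$loss_history, 1), n1$loss_history[1])
})

test_that("labels outside the class set are rejected", {
  pairs <- tiny_pairs(1, shape = c(8, 8, 8))
  net <- build_unet(unet_config(n_classes = 3, base_channels = 2, seed = 1))
  expect_error(train_unet(net, pairs, unet_train_config(n_epochs = 1)),
               "data error")
})

test_that("checkpoints round-trip through save_unet/load_unet", {
  pairs <- tiny_pairs(1, shape = c(8, 8, 8))
  net <- train_unet(build_unet(unet_config(n_classes = 4, base_channels = 2,
                                           seed = 2)),
                    pairs, unet_train_config(n_epochs = 1, seed = 2))
  path <- file.path(withr::local_tempdir(), "net.rds")
  save_unet(net, path)
  back <- load_unet(path)
  expect_identical(back$params, net$params)
  expect_identical(back$class_roles, net$class_roles)
  pm1 <- predict_probabilities(net, pairs[[1]]$intensity)
  pm2 <- predict_probabilities(back, pairs[[1]]$intensity)
  expect_identical(pm1$maps, pm2$maps)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- unet_config(n_classes = 3, base_channels = 2, seed = 5)
  net <- build_unet(cfg)
  set.seed(1)
  x <- array(rnorm(8^3), dim = c(8, 8, 8))
  labs <- array(sample(0:2, 512, TRUE), dim = c(8, 8, 8))
  lm <- c(background = 0L, tibia = 1L, tibial_cartilage = 2L)
  onehot <- kneemorph:::.one_hot(labs, lm, names(lm))
  gm <- matrix(onehot, ncol = 3)
  loss_of <- function(nn) {
    f <- kneemorph:::.unet_fwd(nn, x, training = TRUE)
    1 - mean((2 * colSums(f$probs * gm) + 1) /
               (colSums(f$probs) + colSums(gm) + 1))
  }
  fwd <- kneemorph:::.unet_fwd(net, x, training = TRUE)
  grads <- kneemorph:::.unet_bwd(fwd$net, fwd,
                                 kneemorph:::.soft_dice_grad(fwd$probs, gm, 1))
  for (nm in c("enc1.conv1.W", "enc2.conv2.gamma", "dec3.conv1.W", "final.W",
               "dec1.conv2.beta")) {
    i <- min(3, length(net$params[[nm]]))
    eps <- 1e-5
    up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    fd <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_lt(abs(fd - grads[[nm]][i]) / max(abs(fd), 1e-10), 1e-4)
  }
})
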