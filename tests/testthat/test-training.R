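test_that("training configuration enforces protocol invariants", {
  cfg <- train_config()
  expect_identical(cfg$patch_px, 512L)
  expect_identical(cfg$batch_size, 5L)
  expect_identical(cfg$max_epochs, 500L)
  expect_identical(cfg$iters_per_epoch, 300L)
  expect_equal(cfg$lr_init, 1e-4)
  expect_equal(cfg$lr_factor, 0.5)
  expect_identical(cfg$lr_patience_epochs, 20L)
  expect_identical(cfg$stop_patience_epochs, 50L)
  expect_error(train_config(lr_factor = 1.5), "lr_factor")
  expect_error(train_config(stop_patience_epochs = 10), "stop_patience")
})

test_that("class-balanced sampling draws anchor classes uniformly", {
  set.seed(3)
  tiles <- generate_tile_set(6, shape = c(64, 64), class_set = c(2, 11),
                             seed = 30)
  sampler <- patch_sampler(tiles, patch_px = 32)
  set.seed(99)
  draws <- sample_batch(sampler, 1000)
  anchors <- vapply(draws, function(p) attr(p, "anchor_class"), numeric(1))
  freq <- mean(anchors == 2)
  expect_gt(freq, 0.45)
  expect_lt(freq, 0.55)
  expect_true(all(vapply(draws, function(p) {
    all(dim(p$image) == c(32, 32, 3)) && any(p$mask != 255L)
  }, logical(1))))
})

test_that("sampling is deterministic under a seed and warns on absent classes", {
  tiles <- generate_tile_set(3, shape = c(64, 64), class_set = c(0, 5),
                             seed = 4)
  sampler <- patch_sampler(tiles, patch_px = 64)
  set.seed(11)
  a <- sample_batch(sampler, 5)
  set.seed(11)
  b <- sample_batch(sampler, 5)
  expect_identical(a, b)
  expect_identical(dim(a[[1]]$image), c(64L, 64L, 3L))
  expect_warning(patch_sampler(tiles, classes = c(0, 9)), "absent")
})

test_that("geometric augmentations act identically on image and mask", {
  tiles <- generate_tile_set(1, shape = c(64, 64), class_set = c(0, 3, 13),
                             seed = 6)
  tile <- tiles[[1]]
  # flip is an involution
  f1 <- augment_tile(tile, "flip", params = list(flip_axis = 2))
  f2 <- augment_tile(f1, "flip", params = list(flip_axis = 2))
  expect_equal(f2$image, tile$image)
  expect_identical(f2$mask, tile$mask)
  # four quarter rotations recover the tile
  r <- tile
  for (i in 1:4) r <- augment_tile(r, "rot90", params = list(rot_k = 1))
  expect_equal(r$image, tile$image)
  expect_identical(r$mask, tile$mask)
  # photometric-only pipeline never touches the mask
  set.seed(2)
  ph <- augment_tile(tile, c("gamma", "blur", "contrast", "color", "stain"))
  expect_identical(ph$mask, tile$mask)
  expect_false(identical(ph$image, tile$image))
  # zero-magnitude elastic deformation is the identity
  e0 <- augment_tile(tile, "elastic", params = list(elastic_magnitude = 0))
  expect_equal(e0$image, tile$image)
  expect_identical(e0$mask, tile$mask)
})

test_that("learning rate halves after every patience window without improvement", {
  cfg <- train_config(lr_init = 1e-4, lr_factor = 0.5,
                      lr_patience_epochs = 20L, stop_patience_epochs = 50L)
  # improvement at epoch 1, then flat: one reduction after 20 flat epochs
  expect_equal(schedule_lr(c(1, rep(1, 20)), cfg), 5e-5)
  # improvement resets the patience
  trace <- c(1, rep(1, 18), 0.9, rep(0.9, 19))
  expect_equal(schedule_lr(trace, cfg), 1e-4)
  expect_equal(schedule_lr(c(trace, 0.9), cfg), 5e-5)
  # two full flat windows: two reductions
  expect_equal(schedule_lr(c(1, rep(1, 40)), cfg), 2.5e-5)
  # always of the form lr_init * factor^k
  for (n in c(5, 25, 45, 65)) {
    lr <- schedule_lr(c(1, rep(1, n)), cfg)
    k <- log(lr / cfg$lr_init) / log(cfg$lr_factor)
    expect_equal(k, round(k), tolerance = 1e-12)
  }
})

test_that("a short training run improves the validation loss and is reproducible", {
  tiles <- generate_tile_set(24, shape = c(64, 64),
                             class_set = c(0, 3, 5, 9, 13), seed = 40)
  cfg <- train_config(patch_px = 32, batch_size = 4, max_epochs = 2,
                      iters_per_epoch = 10, lr_init = 1e-3,
                      loss = loss_config("cross_entropy"), seed = 9)
  model <- unet_build(unet_spec(base_filters = 4L, depth = 2L), seed = 9)
  fit <- train_unet(model, tiles[1:20], tiles[21:24], cfg)
  expect_s3_class(fit, "unet_training")
  expect_identical(nrow(fit$history), 2L)
  expect_lt(fit$history$val_loss[2], log(14))   # well below an untrained net
  expect_identical(fit$stop_reason, "max_epochs")
  # identical seeds give identical histories
  fit2 <- train_unet(unet_build(unet_spec(base_filters = 4L, depth = 2L),
                                seed = 9), tiles[1:20], tiles[21:24], cfg)
  expect_equal(fit$history, fit2$history)
  g <- glance(fit)
  expect_identical(g$epochs, 2L)
  expect_error(train_unet(model, list(), tiles[21:24], cfg), "non-empty")
})

test_that("early stopping fires exactly after the patience window", {
  # strictly improving trace never stops
  expect_false(early_stop_due(seq(1, 0.1, length.out = 60), 50))
  # flat after the best epoch: stop only once 50 epochs have elapsed
  trace <- c(1, 0.5, rep(0.6, 49))
  expect_false(early_stop_due(trace, 50))
  expect_true(early_stop_due(c(trace, 0.6), 50))
  # a tie with the best value does not reset the window
  expect_true(early_stop_due(c(1, 0.5, rep(0.5, 50)), 50))
  # a later improvement does reset it
  expect_false(early_stop_due(c(1, 0.5, rep(0.6, 49), 0.4), 50))
})

test_that("training config YAML round-trips", {
  cfg <- train_config(loss = loss_config("focal", alpha = 0.5, gamma = 1),
                      lr_init = 2e-4, seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  cfg2 <- read_train_config(path)
  expect_equal(cfg2$lr_init, 2e-4)
  expect_identical(cfg2$loss$kind, "focal")
  expect_equal(cfg2$loss$alpha, 0.5)
  expect_identical(cfg2$seed, 7L)
})
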