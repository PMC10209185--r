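#' End-to-end segmentation check on the synthetic texture task
#'
#' Trains the network on synthetic textured tiles and reports the held-out
#' mean Dice. This is the package's built-in scaled-down version of the
#' full protocol: 5 tissue classes rendered with distinguishable color and
#' texture, 200 source tiles of 64 x 64 px, 32 px class-balanced patches,
#' a base-8/depth-2 network, and 20 epochs of 30 Adam steps (batch 5) at a
#' learning rate of 1e-3. The task is separable by color/texture by
#' construction, so any of the four losses should reach a high Dice; the
#' run exercises sampling, augmentation, the loss gradients, the
#' optimizer, validation monitoring and tiled evaluation together.
#'
#' @param loss A [loss_config()].
#' @param seed Master seed (tiles, initialization, training).
#' @param n_train,n_val,n_test Tile counts.
#' @param epochs,iters_per_epoch Training length.
#' @param base_filters,depth Network size.
#' @param patch_px Training patch side.
#' @param class_set Classes placed on the tiles.
#' @param verbose Print per-epoch lines.
#' @return A list: `fit` (the [train_unet()] result), `test_dice` (mean
#'   Dice over classes present in the held-out tiles), `test_loss`.
#' @export
segmentation_benchmark <- function(loss = loss_config("cross_entropy"),
                                   seed = 1L, n_train = 200L, n_val = 10L,
                                   n_test = 20L, epochs = 20L,
                                   iters_per_epoch = 30L, base_filters = 8L,
                                   depth = 2L, patch_px = 32L,
                                   class_set = c(0, 3, 5, 9, 13),
                                   verbose = FALSE) {
  tiles <- generate_tile_set(n_train + n_val + n_test, shape = c(64, 64),
                             class_set = class_set, seed = seed)
  train <- tiles[seq_len(n_train)]
  val <- tiles[n_train + seq_len(n_val)]
  test <- tiles[n_train + n_val + seq_len(n_test)]
  spec <- unet_spec(n_classes = 14L, base_filters = base_filters,
                    depth = depth)
  model <- unet_build(spec, seed = seed + 1L)
  cfg <- train_config(
    patch_px = patch_px, batch_size = 5L, max_epochs = epochs,
    iters_per_epoch = iters_per_epoch, lr_init = 1e-3, loss = loss,
    augmentations = c("flip", "rot90"), seed = seed + 2L
  )
  fit <- train_unet(model, train, val, cfg, verbose = verbose)
  loss_fn <- make_loss(cfg$loss)
  ev <- eval_tiles(fit$model, test, loss_fn)
  list(fit = fit, test_dice = ev$dice, test_loss = ev$loss)
}
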