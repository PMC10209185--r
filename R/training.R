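#' Training protocol configuration
#'
#' Bundles the full training protocol for the segmentation network. The
#' defaults reproduce the reference protocol: 512 px patches at 1 um/px,
#' Adam from a learning rate of 1e-4 halved after every 20 epochs without
#' validation improvement, mini-batches of 5, at most 500 epochs of 300
#' iterations, and early stopping after 50 epochs without improvement of
#' the validation loss.
#'
#' @param patch_px Patch side in pixels.
#' @param spacing_um Pixel spacing of training patches (um/px).
#' @param batch_size Patches per optimizer step.
#' @param max_epochs,iters_per_epoch Epoch budget and steps per epoch.
#' @param lr_init,lr_factor Initial learning rate and multiplicative decay.
#' @param lr_patience_epochs Epochs without improvement before the rate is
#'   multiplied by `lr_factor` (the patience also resets after a reduction).
#' @param stop_patience_epochs Epochs without validation improvement before
#'   training stops; must be `>= lr_patience_epochs`.
#' @param augmentations Transform names passed to [augment_tile()].
#' @param loss A [loss_config()].
#' @param monitor `"loss"` (default) or `"dice"`: the validation quantity
#'   driving both the schedule and early stopping.
#' @param seed Integer seed governing sampling, augmentation and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(patch_px = 512L, spacing_um = 1.0, batch_size = 5L,
                         max_epochs = 500L, iters_per_epoch = 300L,
                         lr_init = 1e-4, lr_factor = 0.5,
                         lr_patience_epochs = 20L, stop_patience_epochs = 50L,
                         augmentations = c("flip", "rot90"),
                         loss = loss_config("cross_entropy"),
                         monitor = c("loss", "dice"), seed = 1L) {
  monitor <- match.arg(monitor)
  stopifnot(patch_px > 0, spacing_um > 0, batch_size > 0, max_epochs > 0,
            iters_per_epoch > 0, lr_init > 0)
  if (lr_factor <= 0 || lr_factor >= 1) abort("lr_factor must lie in (0, 1)")
  if (stop_patience_epochs < lr_patience_epochs) {
    abort("stop_patience_epochs must be >= lr_patience_epochs")
  }
  structure(
    list(patch_px = as.integer(patch_px), spacing_um = spacing_um,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         iters_per_epoch = as.integer(iters_per_epoch),
         lr_init = lr_init, lr_factor = lr_factor,
         lr_patience_epochs = as.integer(lr_patience_epochs),
         stop_patience_epochs = as.integer(stop_patience_epochs),
         augmentations = augmentations, loss = loss, monitor = monitor,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Class-balanced patch sampler
#'
#' Training patches are sampled from source tiles with class balancing:
#' each patch is anchored on a pixel of an anchor class drawn uniformly
#' from the classes present in the source set, so rare tissue compartments
#' appear in patches far more often than their pixel share. Every emitted
#' patch contains at least one non-ignored pixel (its anchor).
#'
#' @param tiles List of [labeled_tile()] sources.
#' @param patch_px Patch side in pixels.
#' @param balanced If `FALSE`, patches are anchored uniformly over tiles.
#' @param classes Optional subset of anchor classes; classes absent from
#'   all sources are dropped with a warning.
#' @param ignore_index Label to exclude from anchoring.
#' @return A `patch_sampler` object for [sample_batch()].
#' @export
patch_sampler <- function(tiles, patch_px = 512L, balanced = TRUE,
                          classes = NULL, ignore_index = 255L) {
  if (length(tiles) == 0) abort("no source tiles")
  present <- lapply(tiles, function(t) {
    setdiff(sort(unique(as.vector(t$mask))), ignore_index)
  })
  all_classes <- sort(unique(unlist(present)))
  if (!is.null(classes)) {
    missing <- setdiff(classes, all_classes)
    if (length(missing) > 0) {
      warn(paste0("anchor classes absent from all sources, dropped: ",
                  paste(missing, collapse = ", ")))
    }
    all_classes <- intersect(classes, all_classes)
    if (length(all_classes) == 0) abort("no requested class present")
  }
  by_class <- lapply(all_classes, function(c) {
    which(vapply(present, function(p) c %in% p, logical(1)))
  })
  names(by_class) <- as.character(all_classes)
  structure(
    list(tiles = tiles, patch_px = as.integer(patch_px),
         balanced = balanced, classes = all_classes, by_class = by_class,
         ignore_index = as.integer(ignore_index)),
    class = "patch_sampler"
  )
}

crop_patch <- function(tile, r, c, side) {
  H <- nrow(tile$mask); W <- ncol(tile$mask)
  if (H < side || W < side) {
    abort(sprintf("tile %dx%d smaller than patch size %d", H, W, side))
  }
  r0 <- min(max(r - side %/% 2L, 1L), H - side + 1L)
  c0 <- min(max(c - side %/% 2L, 1L), W - side + 1L)
  labeled_tile(
    tile$image[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , drop = FALSE],
    tile$mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE],
    tile$spacing_um
  )
}

#' Draw a batch of training patches
#'
#' @param sampler A [patch_sampler()].
#' @param n Number of patches.
#' @return List of `n` [labeled_tile()] patches. The anchor class of each
#'   patch is recorded in its `anchor_class` attribute.
#' @export
sample_batch <- function(sampler, n) {
  stopifnot(inherits(sampler, "patch_sampler"))
  lapply(seq_len(n), function(i) {
    if (sampler$balanced) {
      cls <- sampler$classes[sample.int(length(sampler$classes), 1)]
      tix <- sampler$by_class[[as.character(cls)]]
      tile <- sampler$tiles[[tix[sample.int(length(tix), 1)]]]
      pix <- which(tile$mask == cls)
      p <- pix[sample.int(length(pix), 1)]
      r <- ((p - 1L) %% nrow(tile$mask)) + 1L
      c <- ((p - 1L) %/% nrow(tile$mask)) + 1L
    } else {
      tile <- sampler$tiles[[sample.int(length(sampler$tiles), 1)]]
      r <- sample.int(nrow(tile$mask), 1)
      c <- sample.int(ncol(tile$mask), 1)
      cls <- tile$mask[r, c]
    }
    out <- crop_patch(tile, r, c, sampler$patch_px)
    attr(out, "anchor_class") <- cls
    out
  })
}

#' Adaptive learning-rate schedule
#'
#' Replays a history of per-epoch validation values and returns the
#' learning rate the protocol prescribes after the last recorded epoch: the
#' rate is multiplied by `lr_factor` whenever `lr_patience_epochs` epochs
#' have passed without improvement of the monitored value since the last
#' improvement or the last reduction (the patience resets on both events).
#' The resulting rate is always `lr_init * lr_factor^k` for an integer k.
#'
#' @param history A data frame with a `monitor` column of per-epoch
#'   validation values (lower is better), ordered by epoch, or a numeric
#'   vector of such values.
#' @param config A [train_config()].
#' @return The learning rate in force after the last epoch in `history`.
#' @export
schedule_lr <- function(history, config) {
  vals <- if (is.data.frame(history)) history$monitor else as.numeric(history)
  if (length(vals) < 1) abort("need at least one completed epoch")
  lr <- config$lr_init
  best <- Inf
  last_event <- 0L
  for (e in seq_along(vals)) {
    if (vals[e] < best) {
      best <- vals[e]
      last_event <- e
    } else if (e - last_event >= config$lr_patience_epochs) {
      lr <- lr * config$lr_factor
      last_event <- e
    }
  }
  lr
}

#' Early-stopping rule on a validation trace
#'
#' Stopping fires once `patience` epochs have elapsed since the best
#' (lowest) monitored value; ties do not count as improvement, so the
#' first occurrence of the minimum anchors the patience window.
#'
#' @param monitor_vals Per-epoch monitored values (lower is better).
#' @param patience Number of non-improving epochs tolerated.
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
early_stop_due <- function(monitor_vals, patience) {
  length(monitor_vals) - which.min(monitor_vals) >= patience
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

tiles_to_batch <- function(tiles) {
  imgs <- simplify2array(lapply(tiles, function(t) t$image))
  targets <- unlist(lapply(tiles, function(t) as.vector(t$mask)))
  list(x = imgs, targets = as.integer(targets))
}

eval_tiles <- function(model, tiles, loss_fn, chunk = 8L) {
  total <- 0
  dice_acc <- c()
  n <- 0
  for (i in seq(1, length(tiles), by = chunk)) {
    sub <- tiles[i:min(i + chunk - 1L, length(tiles))]
    b <- tiles_to_batch(sub)
    fw <- unet_forward(model, b$x, training = FALSE)
    r <- loss_fn(t(fw$act_matrix), b$targets)
    total <- total + r$value * length(sub)
    n <- n + length(sub)
    pred <- apply_argmax(fw$act_matrix)
    dice_acc <- rbind(dice_acc, dice_counts(pred, b$targets,
                                            nrow(fw$act_matrix)))
  }
  counts <- colSums(dice_acc)
  k <- length(counts) / 3
  inter <- counts[seq_len(k)]
  psum <- counts[k + seq_len(k)]
  rsum <- counts[2 * k + seq_len(k)]
  present <- (psum + rsum) > 0
  dice <- (2 * inter / (psum + rsum))[present & rsum > 0]
  list(loss = total / n, dice = mean(dice))
}

# argmax over channels with lowest-index tie-break (max.col ties are random;
# use explicit comparison)
apply_argmax <- function(act) {
  C <- nrow(act)
  best <- act[1, ]
  lab <- rep(0L, ncol(act))
  for (c in 2:C) {
    upd <- act[c, ] > best
    best[upd] <- act[c, upd]
    lab[upd] <- c - 1L
  }
  lab
}

dice_counts <- function(pred, targets, C, ignore_index = 255L) {
  valid <- targets != ignore_index
  p <- pred[valid]
  r <- targets[valid]
  out <- numeric(3 * C)
  for (c in 0:(C - 1L)) {
    out[c + 1L] <- sum(p == c & r == c)
    out[C + c + 1L] <- sum(p == c)
    out[2L * C + c + 1L] <- sum(r == c)
  }
  matrix(out, nrow = 1)
}

#' Train the segmentation network
#'
#' Runs the full protocol described by [train_config()]: class-balanced
#' patch sampling, augmentation, Adam updates under the configured loss,
#' per-epoch validation, the adaptive learning-rate schedule, and early
#' stopping on the validation loss. The best-validation weights are
#' checkpointed and returned.
#'
#' @param model A built [unet_build()] model.
#' @param train_tiles,val_tiles Disjoint lists of [labeled_tile()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `unet_training` object: `model` (best weights), `history`
#'   (tibble: epoch, train_loss, val_loss, val_dice, lr), `best_epoch`,
#'   `stop_reason`, `config`.
#' @export
train_unet <- function(model, train_tiles, val_tiles, config = train_config(),
                       verbose = FALSE) {
  if (length(train_tiles) == 0 || length(val_tiles) == 0) {
    abort("train and validation sets must be non-empty")
  }
  set.seed(config$seed)
  sampler <- patch_sampler(train_tiles, patch_px = config$patch_px)
  loss_fn <- make_loss(config$loss)
  state <- adam_init(model$params)
  history <- list()
  best <- Inf
  best_epoch <- 0L
  best_params <- model$params
  best_bn <- model$bn
  stop_reason <- "max_epochs"
  monitor_vals <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- if (epoch == 1L) config$lr_init else
      schedule_lr(monitor_vals, config)
    train_loss <- 0
    for (it in seq_len(config$iters_per_epoch)) {
      patches <- sample_batch(sampler, config$batch_size)
      patches <- lapply(patches, augment_tile,
                        transforms = config$augmentations)
      b <- tiles_to_batch(patches)
      fw <- unet_forward(model, b$x, training = TRUE)
      r <- loss_fn(t(fw$act_matrix), b$targets)
      if (!is.finite(r$value)) {
        abort(sprintf("non-finite training loss at epoch %d iter %d",
                      epoch, it))
      }
      train_loss <- train_loss + r$value
      grads <- unet_backward(model, fw$cache, t(r$gradient))
      upd <- adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      model <- apply_bn_updates(model, fw$cache)
    }
    ev <- eval_tiles(model, val_tiles, loss_fn)
    mon <- if (config$monitor == "loss") ev$loss else 1 - ev$dice
    monitor_vals <- c(monitor_vals, mon)
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = train_loss / config$iters_per_epoch,
      val_loss = ev$loss, val_dice = ev$dice, lr = lr
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  dice %.3f  lr %.2e",
        epoch, train_loss / config$iters_per_epoch, ev$loss, ev$dice, lr))
    }
    if (mon < best) {
      best <- mon
      best_epoch <- epoch
      best_params <- model$params
      best_bn <- model$bn
    }
    if (early_stop_due(monitor_vals, config$stop_patience_epochs)) {
      stop_reason <- "early_stop"
      break
    }
  }
  model$params <- best_params
  model$bn <- best_bn
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best_epoch, stop_reason = stop_reason, config = config),
    class = "unet_training"
  )
}

#' @export
print.unet_training <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<unet_training> %d epochs (%s), best epoch %d: val loss %.4f, val dice %.3f\n",
    nrow(h), x$stop_reason, x$best_epoch, h$val_loss[x$best_epoch],
    h$val_dice[x$best_epoch]))
  invisible(x)
}

#' @describeIn train_unet Per-epoch history as a tibble.
#' @method tidy unet_training
#' @param x A `unet_training` object.
#' @param ... Unused.
#' @export
tidy.unet_training <- function(x, ...) x$history

#' @describeIn train_unet One-row run summary.
#' @method glance unet_training
#' @export
glance.unet_training <- function(x, ...) {
  h <- x$history
  tibble(
    epochs = nrow(h), best_epoch = x$best_epoch,
    best_val_loss = min(h$val_loss), final_val_dice = h$val_dice[nrow(h)],
    best_val_dice = max(h$val_dice), stop_reason = x$stop_reason,
    loss = x$config$loss$kind
  )
}
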