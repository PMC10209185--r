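#' Specification of the segmentation network
#'
#' Describes the U-Net variant used for tissue segmentation: an
#' encoder-decoder with `base_filters` filters in the first block, doubled
#' after every 2x2 max-pooling; within every block the block input is
#' concatenated onto the block's last feature map (an intra-block skip that
#' improves gradient flow); and the decoder upsamples by nearest neighbor
#' followed by a 2x2 convolution instead of transposed convolution. All 3x3
#' convolutions are same-padded, each followed by batch normalization and
#' ReLU, so the output grid aligns with the input grid.
#'
#' @param in_channels Input channels (3 for RGB).
#' @param n_classes Output classes (14 for the tissue schema).
#' @param base_filters Filters in the first encoder block (default 32).
#' @param depth Number of pooling levels (default 4; input sides must be
#'   divisible by `2^depth`).
#' @return A `unet_spec` object.
#' @export
unet_spec <- function(in_channels = 3L, n_classes = 14L, base_filters = 32L,
                      depth = 4L) {
  stopifnot(in_channels >= 1, n_classes >= 2, base_filters >= 1, depth >= 1)
  structure(
    list(in_channels = as.integer(in_channels),
         n_classes = as.integer(n_classes),
         base_filters = as.integer(base_filters), depth = as.integer(depth)),
    class = "unet_spec"
  )
}

# Per-conv-unit layout: channel bookkeeping for build/forward/backward.
unet_layout <- function(spec) {
  units <- list()
  add <- function(name, c_in, c_out, k, bn = TRUE, act = TRUE) {
    units[[name]] <<- list(name = name, c_in = c_in, c_out = c_out, k = k,
                           bn = bn, act = act)
  }
  d <- spec$depth
  f <- spec$base_filters * 2^(0:d)
  ch <- spec$in_channels
  enc_ch <- integer(d)                 # block output channels per level
  for (k in seq_len(d)) {
    add(sprintf("enc%d_c1", k), ch, f[k], 3L)
    add(sprintf("enc%d_c2", k), f[k], f[k], 3L)
    ch <- ch + f[k]                    # intra-block concat
    enc_ch[k] <- ch
  }
  add("bott_c1", ch, f[d + 1L], 3L)
  add("bott_c2", f[d + 1L], f[d + 1L], 3L)
  ch <- ch + f[d + 1L]
  for (k in rev(seq_len(d))) {
    add(sprintf("dec%d_up", k), ch, f[k], 2L)
    cat_ch <- f[k] + enc_ch[k]
    add(sprintf("dec%d_c1", k), cat_ch, f[k], 3L)
    add(sprintf("dec%d_c2", k), f[k], f[k], 3L)
    ch <- cat_ch + f[k]
  }
  add("head", ch, spec$n_classes, 1L, bn = FALSE, act = FALSE)
  list(units = units, enc_ch = enc_ch, filters = f)
}

#' Build a segmentation network with seeded initialization
#'
#' Weights use fan-in-scaled Gaussian initialization (`sd = sqrt(2 /
#' fan_in)`), the scheme designed for rectifier networks; biases start at
#' zero, batch-norm scales at one. Construction is fully deterministic given
#' `seed`: two builds with the same seed have bit-identical parameters.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for the initial weights.
#' @return A `unet_model` object.
#' @export
unet_build <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  layout <- unet_layout(spec)
  params <- list()
  bn <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (u in layout$units) {
    fan_in <- u$c_in * u$k^2
    params[[paste0(u$name, ".W")]] <-
      matrix(rnorm(u$c_out * fan_in, sd = sqrt(2 / fan_in)), u$c_out, fan_in)
    params[[paste0(u$name, ".b")]] <- numeric(u$c_out)
    if (u$bn) {
      params[[paste0(u$name, ".g")]] <- rep(1, u$c_out)
      params[[paste0(u$name, ".be")]] <- numeric(u$c_out)
      bn[[u$name]] <- list(rm = numeric(u$c_out), rv = rep(1, u$c_out))
    }
  }
  structure(
    list(spec = spec, layout = layout, params = params, bn = bn, seed = seed),
    class = "unet_model"
  )
}

#' Number of trainable parameters
#' @param model A `unet_model`.
#' @return Integer count of all weights, biases, and batch-norm parameters.
#' @export
unet_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<unet_model> in=%d classes=%d base=%d depth=%d | %s parameters\n",
    s$in_channels, s$n_classes, s$base_filters, s$depth,
    format(unet_n_params(x), big.mark = ",")))
  invisible(x)
}

#' @method tidy unet_model
#' @describeIn unet_build Layer table of a built model (one row per
#'   convolution unit, with channel counts and kernel size).
#' @param x A `unet_model`.
#' @param ... Unused.
#' @export
tidy.unet_model <- function(x, ...) {
  purrr::map_dfr(x$layout$units, ~ tibble(
    unit = .x$name, in_channels = .x$c_in, out_channels = .x$c_out,
    kernel = .x$k, batch_norm = .x$bn, relu = .x$act
  ))
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the architecture spec, weights, batch-norm running
#' statistics and the build seed into one RDS file (a binary runtime
#' artifact, regenerable from code).
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(spec = unclass(model$spec), params = model$params,
               bn = model$bn, seed = model$seed, format_version = 1L), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  x <- readRDS(path)
  spec <- do.call(unet_spec, x$spec)
  model <- unet_build(spec, seed = x$seed)
  stopifnot(identical(names(model$params), names(x$params)))
  model$params <- x$params
  model$bn <- x$bn
  model
}

as_batch_array <- function(x, in_channels) {
  if (is.list(x)) x <- simplify2array(x)
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[3] != in_channels) {
    abort(sprintf("expected %d input channels, got %d", in_channels, d[3]))
  }
  x
}

conv_pads <- function(k) {
  # same-size output: symmetric for odd kernels, extra pad at bottom/right
  # for the even 2x2 decoder convolution
  p <- k - 1L
  c(p %/% 2L, p - p %/% 2L)
}

unit_forward <- function(model, name, X, H, W, N, training, cache) {
  u <- model$layout$units[[name]]
  pp <- conv_pads(u$k)
  geom <- conv_geometry(H, W, N, u$k, u$k, pp[1], pp[2], pp[1], pp[2])
  cf <- conv_forward(X, model$params[[paste0(name, ".W")]],
                     model$params[[paste0(name, ".b")]], geom,
                     keep_cols = !is.null(cache))
  out <- cf$out
  uc <- list(cols = cf$cols, geom = geom, c_in = u$c_in)
  if (u$bn) {
    st <- model$bn[[name]]
    bf <- bn_forward(out, model$params[[paste0(name, ".g")]],
                     model$params[[paste0(name, ".be")]],
                     st$rm, st$rv, training)
    out <- bf$out
    uc$xhat <- bf$xhat
    uc$istd <- bf$istd
    if (training && !is.null(cache)) {
      cache$bn_updates[[name]] <- list(rm = bf$rm, rv = bf$rv)
    }
  }
  if (u$act) {
    uc$pre_relu_pos <- if (!is.null(cache)) out > 0 else NULL
    out <- pmax(out, 0)
  }
  if (!is.null(cache)) cache$units[[name]] <- uc
  out
}

unit_backward <- function(model, name, dOut, cache, grads) {
  u <- model$layout$units[[name]]
  uc <- cache$units[[name]]
  if (u$act) dOut <- dOut * uc$pre_relu_pos
  if (u$bn) {
    bb <- bn_backward(dOut, model$params[[paste0(name, ".g")]],
                      uc$xhat, uc$istd)
    grads[[paste0(name, ".g")]] <- bb$dg
    grads[[paste0(name, ".be")]] <- bb$dbe
    dOut <- bb$dX
  }
  cb <- conv_backward(dOut, uc$cols, model$params[[paste0(name, ".W")]],
                      uc$c_in, uc$geom)
  grads[[paste0(name, ".W")]] <- cb$dW
  grads[[paste0(name, ".b")]] <- cb$db
  list(dX = cb$dX, grads = grads)
}

#' Run the network on one tile or a batch of tiles
#'
#' Input pixels are expected in `[0, 1]` (RGB / 255). The output is one
#' likelihood map per class, softmax-normalized per pixel, aligned with the
#' input grid (same-padded convolutions).
#'
#' @param model A built `unet_model`.
#' @param x Array `H x W x C` (one tile), `H x W x C x N` (a batch), or a
#'   list of `H x W x C` arrays. `H` and `W` must be divisible by
#'   `2^depth`.
#' @param training If `TRUE`, batch statistics are used for normalization
#'   and an internal cache for backpropagation is retained.
#' @return A list with `probabilities` (`H x W x n_classes x N`, dropped to
#'   3 dimensions for a single tile), `activations` (same shape), and, when
#'   `training = TRUE`, the backprop `cache`.
#' @export
unet_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  x <- as_batch_array(x, model$spec$in_channels)
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[4]
  div <- 2^model$spec$depth
  if (H %% div != 0 || W %% div != 0) {
    abort(sprintf("input size %dx%d not divisible by 2^depth = %d", H, W, div))
  }
  X <- matrix(aperm(x, c(3, 1, 2, 4)), d[3], H * W * N)
  cache <- if (training) new.env(parent = emptyenv()) else NULL
  if (training) {
    cache$units <- list()
    cache$bn_updates <- list()
  }
  dep <- model$spec$depth
  e <- vector("list", dep)
  dims <- vector("list", dep + 1L)
  h <- H; w <- W
  cur <- X
  pool_src <- vector("list", dep)
  for (k in seq_len(dep)) {
    dims[[k]] <- c(h, w)
    h1 <- unit_forward(model, sprintf("enc%d_c1", k), cur, h, w, N, training, cache)
    h2 <- unit_forward(model, sprintf("enc%d_c2", k), h1, h, w, N, training, cache)
    e[[k]] <- rbind(cur, h2)
    pg <- pool_geometry(h, w, N)
    mp <- maxpool_forward(e[[k]], pg)
    cur <- mp$out
    if (training) pool_src[[k]] <- list(src = mp$src, n_in = pg$n_in)
    h <- h %/% 2L; w <- w %/% 2L
  }
  dims[[dep + 1L]] <- c(h, w)
  b1 <- unit_forward(model, "bott_c1", cur, h, w, N, training, cache)
  b2 <- unit_forward(model, "bott_c2", b1, h, w, N, training, cache)
  cur <- rbind(cur, b2)
  for (k in rev(seq_len(dep))) {
    ug <- upsample_geometry(h, w, N)
    up <- upsample_forward(cur, ug)
    h <- h * 2L; w <- w * 2L
    u <- unit_forward(model, sprintf("dec%d_up", k), up, h, w, N, training, cache)
    cat_in <- rbind(u, e[[k]])
    h1 <- unit_forward(model, sprintf("dec%d_c1", k), cat_in, h, w, N, training, cache)
    h2 <- unit_forward(model, sprintf("dec%d_c2", k), h1, h, w, N, training, cache)
    cur <- rbind(cat_in, h2)
  }
  act <- unit_forward(model, "head", cur, H, W, N, training, cache)
  probs <- softmax_cols(act)
  to_array <- function(m) {
    arr <- array(m, c(nrow(m), H, W, N))
    arr <- aperm(arr, c(2, 3, 1, 4))
    if (N == 1L) arr <- arr[, , , 1, drop = TRUE]
    arr
  }
  if (training) {
    cache$dims <- c(H = H, W = W, N = N)
    cache$pool_src <- pool_src
    cache$enc_ch <- vapply(e, nrow, integer(1))
    cache$in_ch <- nrow(X)
  }
  list(probabilities = to_array(probs), activations = to_array(act),
       act_matrix = act, cache = cache)
}

# Backpropagate dL/d(activations) [n_classes x (H*W*N)] through the whole
# network; returns the gradient list aligned with model$params.
unet_backward <- function(model, cache, dAct) {
  dep <- model$spec$depth
  H <- cache$dims[["H"]]; W <- cache$dims[["W"]]; N <- cache$dims[["N"]]
  grads <- list()
  ub <- unit_backward(model, "head", dAct, cache, grads)
  grads <- ub$grads
  dcur <- ub$dX
  h <- H; w <- W
  f <- model$layout$filters
  d_e <- vector("list", dep)          # gradient w.r.t. encoder block outputs
  for (k in seq_len(dep)) {
    # decoder level k: cur = rbind(cat_in, h2); cat_in = rbind(u, e[k])
    cat_ch <- f[k] + cache$enc_ch[k]
    d_cat <- dcur[seq_len(cat_ch), , drop = FALSE]
    d_h2 <- dcur[(cat_ch + 1L):nrow(dcur), , drop = FALSE]
    ub <- unit_backward(model, sprintf("dec%d_c2", k), d_h2, cache, grads)
    grads <- ub$grads
    ub <- unit_backward(model, sprintf("dec%d_c1", k), ub$dX, cache, grads)
    grads <- ub$grads
    d_cat <- d_cat + ub$dX
    d_u <- d_cat[seq_len(f[k]), , drop = FALSE]
    d_e[[k]] <- d_cat[(f[k] + 1L):nrow(d_cat), , drop = FALSE]
    ub <- unit_backward(model, sprintf("dec%d_up", k), d_u, cache, grads)
    grads <- ub$grads
    ug <- upsample_geometry(h %/% 2L, w %/% 2L, N)
    dcur <- upsample_backward(ub$dX, ug)
    h <- h %/% 2L; w <- w %/% 2L
  }
  # bottleneck: cur = rbind(pool_out, b2)
  pool_ch <- nrow(dcur) - f[dep + 1L]
  d_pool <- dcur[seq_len(pool_ch), , drop = FALSE]
  d_b2 <- dcur[(pool_ch + 1L):nrow(dcur), , drop = FALSE]
  ub <- unit_backward(model, "bott_c2", d_b2, cache, grads)
  grads <- ub$grads
  ub <- unit_backward(model, "bott_c1", ub$dX, cache, grads)
  grads <- ub$grads
  d_pool <- d_pool + ub$dX
  for (k in rev(seq_len(dep))) {
    ps <- cache$pool_src[[k]]
    d_ek <- maxpool_backward(d_pool, ps$src, nrow(d_pool), ps$n_in) + d_e[[k]]
    in_ch <- if (k == 1L) cache$in_ch else {
      # input of block k = pooled output of block k-1
      cache$enc_ch[k - 1L]
    }
    d_h2 <- d_ek[(in_ch + 1L):nrow(d_ek), , drop = FALSE]
    d_in <- d_ek[seq_len(in_ch), , drop = FALSE]
    ub <- unit_backward(model, sprintf("enc%d_c2", k), d_h2, cache, grads)
    grads <- ub$grads
    ub <- unit_backward(model, sprintf("enc%d_c1", k), ub$dX, cache, grads)
    grads <- ub$grads
    d_pool <- d_in + ub$dX
  }
  grads
}

apply_bn_updates <- function(model, cache) {
  for (name in names(cache$bn_updates)) {
    model$bn[[name]] <- cache$bn_updates[[name]]
  }
  model
}
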