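#' Plan a covering tile grid over a large image
#'
#' Splits an image into `tile_px` write regions that cover it exactly once.
#' Each tile is read with `margin_px` of surrounding context (reflect-padded
#' at the image border) but writes only its center region, so convolution
#' seam artifacts stay outside the written area. Coordinates are 0-based,
#' (row, col), half-open.
#'
#' @param image_shape Integer `c(H, W)` in pixels.
#' @param tile_px Side of the written (non-margin) region.
#' @param margin_px Context margin read around each tile.
#' @return A `tile_grid`: a tibble with one row per tile (write window and
#'   read window), carrying `image_shape`, `tile_px`, `margin_px`
#'   attributes.
#' @export
plan_tiles <- function(image_shape, tile_px = 512L, margin_px = 64L) {
  H <- image_shape[1]; W <- image_shape[2]
  stopifnot(H >= 1, W >= 1, tile_px >= 1, margin_px >= 0)
  starts <- function(n) as.integer(seq(0L, max(n - 1L, 0L), by = tile_px))
  grid <- tidyr::expand_grid(row0 = starts(H), col0 = starts(W))
  grid <- dplyr::mutate(
    grid,
    row1 = pmin(.data$row0 + tile_px, H),
    col1 = pmin(.data$col0 + tile_px, W),
    read_row0 = .data$row0 - margin_px,
    read_col0 = .data$col0 - margin_px,
    read_row1 = .data$row0 + tile_px + margin_px,
    read_col1 = .data$col0 + tile_px + margin_px
  )
  structure(grid, class = c("tile_grid", class(grid)),
            image_shape = c(H, W), tile_px = as.integer(tile_px),
            margin_px = as.integer(margin_px))
}

# reflect-padded crop of [r0, r1) x [c0, c1) (0-based, may overflow image)
reflect_crop <- function(img, r0, r1, c0, c1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ridx <- reflect_index(r0:(r1 - 1L), H)
  cidx <- reflect_index(c0:(c1 - 1L), W)
  img[ridx, cidx, , drop = FALSE]
}

reflect_index <- function(i, n) {
  # 0-based reflection without repeating the border pixel, robust to any
  # overflow depth; degenerate n = 1 maps everything to the single pixel
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i %% p) + p) %% p
  ifelse(j < n, j, p - j) + 1L
}

#' Resample an image to the inference pixel spacing
#'
#' Inference runs at 1 um/px (10x magnification); scans are typically at
#' 0.24 um/px. Downscaling is area-weighted (each output pixel averages the
#' source area it covers), which is the correct antialiasing resampler for
#' label-preserving downscale; upscaling requests are honored with the same
#' weights (then equivalent to bilinear) and logged as a warning.
#'
#' @param image Numeric array `H x W x C` (or matrix).
#' @param native_spacing_um Spacing of `image` (um/px); must be known.
#' @param target_spacing_um Output spacing (default 1.0).
#' @return The resampled image; its output spacing is
#'   `attr(, "spacing_um")`.
#' @export
rescale_to_inference_spacing <- function(image, native_spacing_um,
                                         target_spacing_um = 1.0) {
  if (is.null(native_spacing_um) || is.na(native_spacing_um) ||
      native_spacing_um <= 0) {
    abort("native spacing unknown: refusing to guess")
  }
  if (abs(native_spacing_um - target_spacing_um) < 1e-9) {
    out <- image
    attr(out, "spacing_um") <- target_spacing_um
    return(out)
  }
  if (native_spacing_um > target_spacing_um) {
    warn("upscaling requested (native spacing coarser than target)")
  }
  was_matrix <- is.matrix(image)
  if (was_matrix) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  f <- native_spacing_um / target_spacing_um
  H2 <- max(1L, round(d[1] * f))
  W2 <- max(1L, round(d[2] * f))
  A <- overlap_weights(d[1], H2)
  B <- overlap_weights(d[2], W2)
  out <- array(0, c(H2, W2, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- A %*% image[, , ch] %*% t(B)
  if (was_matrix) out <- out[, , 1]
  attr(out, "spacing_um") <- target_spacing_um
  out
}

# n_out x n_in row-stochastic matrix of interval overlaps: output pixel i
# averages the source pixels its footprint covers
overlap_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      W[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
    }
  }
  W / rowSums(W)
}

#' Segment a large image by tiled inference
#'
#' Runs the network over a covering tile grid and stitches the per-tile
#' likelihoods into a full-resolution map; the per-pixel argmax (ties to
#' the lowest class index) gives the label map. Within `margin_px` of a
#' tile seam, predictions come from the tile whose write region owns the
#' pixel, so every pixel is predicted exactly once.
#'
#' @param model A trained `unet_model`.
#' @param image RGB array in `[0, 1]` at `spacing_um`.
#' @param tile_px,margin_px Grid geometry; the read window
#'   (`tile_px + 2 * margin_px`) must be divisible by `2^depth`.
#' @param spacing_um Spacing of `image`; must equal the model's expected
#'   1 um/px within `spacing_tol` or an error advises rescaling.
#' @param spacing_tol Relative spacing tolerance (default 5%).
#' @param keep_likelihoods Attach the stitched likelihood array.
#' @return A [segmentation_map()].
#' @export
predict_map <- function(model, image, tile_px = 512L, margin_px = 64L,
                        spacing_um = 1.0, spacing_tol = 0.05,
                        keep_likelihoods = FALSE) {
  if (abs(spacing_um - 1.0) > spacing_tol) {
    abort(sprintf(
      "image spacing %.3g um/px; rescale to 1 um/px first (see rescale_to_inference_spacing)",
      spacing_um))
  }
  if (max(image) > 1 + 1e-9) image <- image / 255
  d <- dim(image)
  grid <- plan_tiles(d[1:2], tile_px, margin_px)
  C <- model$spec$n_classes
  labels <- matrix(0L, d[1], d[2])
  lik <- if (keep_likelihoods) array(0, c(d[1], d[2], C)) else NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tile <- reflect_crop(image, g$read_row0, g$read_row1,
                         g$read_col0, g$read_col1)
    fw <- unet_forward(model, tile, training = FALSE)
    probs <- fw$probabilities
    # write region inside the read window
    wr <- (g$row0 - g$read_row0 + 1L):(g$row1 - g$read_row0)
    wc <- (g$col0 - g$read_col0 + 1L):(g$col1 - g$read_col0)
    sub <- probs[wr, wc, , drop = FALSE]
    pm <- matrix(aperm(sub, c(3, 1, 2)), C)
    labs <- matrix(apply_argmax(pm), length(wr), length(wc))
    labels[(g$row0 + 1L):g$row1, (g$col0 + 1L):g$col1] <- labs
    if (keep_likelihoods) {
      lik[(g$row0 + 1L):g$row1, (g$col0 + 1L):g$col1, ] <- sub
    }
  }
  segmentation_map(labels, spacing_um = 1.0, likelihoods = lik)
}
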