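# Data augmentation for labeled tiles. Geometric transforms act identically
# on image and mask (mask resampled nearest-neighbor); photometric
# transforms leave the mask untouched.

flip_image <- function(img, axis) {
  if (axis == 1L) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  else img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

flip_mask <- function(mask, axis) {
  if (axis == 1L) mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  else mask[, rev(seq_len(ncol(mask))), drop = FALSE]
}

rot90_mask <- function(mask, k) {
  k <- k %% 4L
  for (i in seq_len(k)) mask <- t(mask[rev(seq_len(nrow(mask))), , drop = FALSE])
  mask
}

rot90_image <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  d <- dim(img)
  newdim <- if (k %% 2L == 1L) c(d[2], d[1], d[3]) else d
  out <- array(0, newdim)
  for (ch in seq_len(d[3])) {
    out[, , ch] <- rot90_mask(img[, , ch], k)
  }
  out
}

# separable gaussian blur with replicate padding; image only
gaussian_blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2.5 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  blur1 <- function(m, along) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along == 1L) nrow(m) else ncol(m)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      shifted <- if (along == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
      out <- out + w[j + r + 1L] * shifted
    }
    out
  }
  for (ch in seq_len(dim(img)[3])) {
    img[, , ch] <- blur1(blur1(img[, , ch], 1L), 2L)
  }
  img
}

# bilinear warp of an image / nearest warp of a mask by a displacement field
warp_bilinear <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(row(m) + dr, 1), H)
  c <- pmin(pmax(col(m) + dc, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- c - c0
  at <- function(ri, ci) m[cbind(as.vector(ri), as.vector(ci))]
  v <- (1 - fr) * (1 - fc) * at(r0, c0) + fr * (1 - fc) * at(r1, c0) +
    (1 - fr) * fc * at(r0, c1) + fr * fc * at(r1, c1)
  matrix(v, H, W)
}

warp_nearest <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(round(row(m) + dr), 1), H)
  c <- pmin(pmax(round(col(m) + dc), 1), W)
  matrix(m[cbind(as.vector(r), as.vector(c))], H, W)
}

elastic_field <- function(H, W, magnitude, smooth_sigma = 8) {
  if (magnitude <= 0) return(list(dr = matrix(0, H, W), dc = matrix(0, H, W)))
  smooth <- function(noise) {
    a <- array(noise, c(H, W, 1))
    gaussian_blur_image(a, smooth_sigma)[, , 1]
  }
  dr <- smooth(matrix(rnorm(H * W), H, W))
  dc <- smooth(matrix(rnorm(H * W), H, W))
  sc <- magnitude / max(max(abs(dr)), max(abs(dc)), 1e-12)
  list(dr = dr * sc, dc = dc * sc)
}

# Ruifrok-style optical-density stain vectors (hematoxylin, eosin, residual)
HE_STAIN_BASIS <- matrix(
  c(0.650, 0.704, 0.286,
    0.072, 0.990, 0.105,
    0.268, 0.570, 0.776),
  nrow = 3, byrow = TRUE
)

stain_jitter_image <- function(img, scale_sd = 0.05, shift_sd = 0.02) {
  eps <- 1 / 255
  d <- dim(img)
  rgb <- matrix(img, ncol = 3)
  od <- -log(pmax(rgb, eps))
  conc <- od %*% solve(t(HE_STAIN_BASIS))     # per-pixel stain concentrations
  sc <- 1 + rnorm(3, sd = scale_sd)
  sh <- rnorm(3, sd = shift_sd)
  conc <- sweep(sweep(conc, 2, sc, "*"), 2, sh, "+")
  out <- exp(-(conc %*% t(HE_STAIN_BASIS)))
  array(pmin(pmax(out, 0), 1), d)
}

#' Augment a labeled tile
#'
#' Applies the training-time augmentation set: random flipping, rotation by
#' multiples of 90 degrees, elastic deformation, Gaussian blur, brightness
#' (random gamma), stain perturbation in optical-density space, per-channel
#' color jitter, and contrast changes. Geometric transforms are applied
#' identically to image and mask (nearest-neighbor for the mask);
#' photometric transforms never touch the mask. Randomness comes from R's
#' global RNG, so runs are reproducible under `set.seed()`.
#'
#' @param tile A [labeled_tile()].
#' @param transforms Character subset of `c("flip", "rot90", "elastic",
#'   "blur", "gamma", "stain", "color", "contrast")`.
#' @param params Optional pinned parameters overriding the random draws:
#'   `flip_axis` (1, 2 or 0 = none), `rot_k` (0-3), `gamma`, `contrast`,
#'   `blur_sigma`, `elastic_magnitude` (pixels), `color_scale`.
#' @return A [labeled_tile()] of the same shape.
#' @export
augment_tile <- function(tile,
                         transforms = c("flip", "rot90", "gamma", "contrast"),
                         params = list()) {
  stopifnot(inherits(tile, "labeled_tile"))
  img <- tile$image
  mask <- tile$mask
  if ("flip" %in% transforms) {
    axis <- params$flip_axis %||% sample(0:2, 1)
    if (axis > 0) {
      img <- flip_image(img, axis)
      mask <- flip_mask(mask, axis)
    }
  }
  if ("rot90" %in% transforms) {
    k <- params$rot_k %||% sample(0:3, 1)
    if (k %% 4L != 0L) {
      img <- rot90_image(img, k)
      mask <- rot90_mask(mask, k)
    }
  }
  if ("elastic" %in% transforms) {
    mag <- params$elastic_magnitude %||% runif(1, 0, 4)
    if (mag > 0) {
      fld <- elastic_field(nrow(mask), ncol(mask), mag)
      for (ch in seq_len(dim(img)[3])) {
        img[, , ch] <- warp_bilinear(img[, , ch], fld$dr, fld$dc)
      }
      mask <- warp_nearest(mask, fld$dr, fld$dc)
    }
  }
  if ("blur" %in% transforms) {
    sigma <- params$blur_sigma %||% runif(1, 0, 1.2)
    img <- gaussian_blur_image(img, sigma)
  }
  if ("gamma" %in% transforms) {
    g <- params$gamma %||% exp(runif(1, -0.3, 0.3))
    img <- img^g
  }
  if ("stain" %in% transforms) {
    img <- stain_jitter_image(img)
  }
  if ("color" %in% transforms) {
    sc <- params$color_scale %||% (1 + rnorm(3, sd = 0.05))
    for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] * sc[ch], 0), 1)
  }
  if ("contrast" %in% transforms) {
    f <- params$contrast %||% exp(runif(1, -0.2, 0.2))
    img <- pmin(pmax((img - 0.5) * f + 0.5, 0), 1)
  }
  labeled_tile(img, mask, tile$spacing_um)
}
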