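# Internal neural-network primitives.
#
# Feature maps live as dense matrices with one row per channel and one
# column per pixel; columns are ordered row-fastest within an image, images
# concatenated along columns. Convolution is im2col (pure column gathers
# against precomputed index tables) followed by a BLAS matrix product, so
# everything heavy runs inside optimized linear algebra. Padding uses an
# appended all-zero sentinel column.

.geom_cache <- new.env(parent = emptyenv())

geom_key <- function(...) paste(..., sep = "_")

# Index tables for a k x k convolution at stride 1. pads = c(top, bottom,
# left, right). Returns one gather vector per kernel offset: position j holds
# the 1-based source column for output pixel j, or the sentinel (n_cols + 1)
# where the receptive field falls into padding.
conv_geometry <- function(H, W, N, kh, kw, pt, pb, pl, pr) {
  key <- geom_key("conv", H, W, N, kh, kw, pt, pb, pl, pr)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  H_out <- H + pt + pb - kh + 1L
  W_out <- W + pl + pr - kw + 1L
  stopifnot(H_out >= 1, W_out >= 1)
  r_o <- rep_len(0:(H_out - 1L), H_out * W_out)
  c_o <- rep(0:(W_out - 1L), each = H_out)
  n_off <- rep((0:(N - 1L)) * (H * W), each = H_out * W_out)
  sentinel <- H * W * N + 1L
  idx <- vector("list", kh * kw)
  k <- 1L
  for (kj in 0:(kw - 1L)) {
    for (ki in 0:(kh - 1L)) {
      in_r <- r_o - pt + ki
      in_c <- c_o - pl + kj
      base <- in_c * H + in_r + 1L
      base[in_r < 0L | in_r >= H | in_c < 0L | in_c >= W] <- NA_integer_
      full <- rep(base, times = N) + n_off
      full[is.na(full)] <- sentinel
      idx[[k]] <- full
      k <- k + 1L
    }
  }
  # interleaved gather layout: for each output pixel, the K source columns
  # in kernel order (kernel fastest), 0-based; used for one-shot im2col
  Jm1 <- as.vector(t(matrix(unlist(idx), H_out * W_out * N, kh * kw))) - 1L
  out <- list(idx = idx, Jm1 = Jm1, key = key, H_out = H_out, W_out = W_out,
              n_in = H * W * N, n_out = H_out * W_out * N, kh = kh, kw = kw,
              H = H, W = W, N = N, pads = c(pt, pb, pl, pr))
  .geom_cache[[key]] <- out
  out
}

.GATHER_CACHE_MAX <- 3e7

im2col <- function(X, geom) {
  C <- nrow(X)
  K <- geom$kh * geom$kw
  if (length(geom$Jm1) * C <= .GATHER_CACHE_MAX) {
    gkey <- geom_key("g", geom$key, C)
    G <- .geom_cache[[gkey]]
    if (is.null(G)) {
      G <- rep(geom$Jm1 * C, each = C) + seq_len(C)
      .geom_cache[[gkey]] <- G
    }
    Xpv <- c(X, numeric(C))            # sentinel zero column
    return(matrix(Xpv[G], C * K, geom$n_out))
  }
  Xp <- cbind(X, 0)
  cols <- matrix(0, C * K, geom$n_out)
  for (k in seq_len(K)) {
    cols[((k - 1L) * C + 1L):(k * C), ] <- Xp[, geom$idx[[k]], drop = FALSE]
  }
  cols
}

conv_forward <- function(X, W, b, geom, keep_cols = FALSE) {
  cols <- im2col(X, geom)
  out <- W %*% cols + b
  list(out = out, cols = if (keep_cols) cols else NULL)
}

# dX computed as a transposed convolution: gather dOut with the flipped
# kernel geometry and hit it with the rearranged weights in one GEMM. This
# avoids the read-modify-write scatter a col2im would need.
conv_backward <- function(dOut, cols, W, C_in, geom) {
  p <- geom$pads
  geomB <- conv_geometry(geom$H_out, geom$W_out, geom$N, geom$kh, geom$kw,
                         geom$kh - 1L - p[1], geom$kh - 1L - p[2],
                         geom$kw - 1L - p[3], geom$kw - 1L - p[4])
  K <- geom$kh * geom$kw
  C_out <- nrow(W)
  Wt <- matrix(0, C_in, C_out * K)
  for (kp in seq_len(K)) {
    k <- K + 1L - kp
    Wt[, ((kp - 1L) * C_out + 1L):(kp * C_out)] <-
      t(W[, ((k - 1L) * C_in + 1L):(k * C_in), drop = FALSE])
  }
  list(
    dW = tcrossprod(dOut, cols),
    db = rowSums(dOut),
    dX = Wt %*% im2col(dOut, geomB)
  )
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(X, g, be, rm, rv, training) {
  if (training) {
    m <- rowMeans(X)
    v <- rowMeans(X^2) - m^2
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- (X - m) * istd
    list(
      out = g * xhat + be, xhat = xhat, istd = istd,
      rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * m,
      rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
    )
  } else {
    xhat <- (X - rm) / sqrt(rv + BN_EPS)
    list(out = g * xhat + be, xhat = NULL, istd = NULL, rm = rm, rv = rv)
  }
}

bn_backward <- function(dY, g, xhat, istd) {
  n <- ncol(dY)
  dg <- rowSums(dY * xhat)
  dbe <- rowSums(dY)
  dX <- (g * istd / n) * (n * dY - dbe - xhat * dg)
  list(dX = dX, dg = dg, dbe = dbe)
}

# 2 x 2 max pooling, stride 2. Children tables give, for each output pixel,
# the four source columns of its window.
pool_geometry <- function(H, W, N) {
  key <- geom_key("pool", H, W, N)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  r_o <- rep_len(0:(H2 - 1L), H2 * W2)
  c_o <- rep(0:(W2 - 1L), each = H2)
  n_off <- rep((0:(N - 1L)) * (H * W), each = H2 * W2)
  child <- function(dr, dc) {
    rep((2L * c_o + dc) * H + 2L * r_o + dr + 1L, times = N) + n_off
  }
  out <- list(i = list(child(0L, 0L), child(1L, 0L), child(0L, 1L),
                       child(1L, 1L)),
              H2 = H2, W2 = W2, n_in = H * W * N)
  .geom_cache[[key]] <- out
  out
}

maxpool_forward <- function(X, geom) {
  C <- nrow(X)
  out <- X[, geom$i[[1]], drop = FALSE]
  src <- matrix(rep(geom$i[[1]], each = C), nrow = C)
  for (k in 2:4) {
    cand <- X[, geom$i[[k]], drop = FALSE]
    upd <- cand > out              # ties: earlier child wins (deterministic)
    out[upd] <- cand[upd]
    srck <- matrix(rep(geom$i[[k]], each = C), nrow = C)
    src[upd] <- srck[upd]
  }
  list(out = out, src = src)
}

maxpool_backward <- function(dOut, src, C, n_in) {
  dX <- matrix(0, C, n_in)
  dX[cbind(as.vector(row(src)), as.vector(src))] <- as.vector(dOut)
  dX
}

# Nearest-neighbor x2 upsampling: a pure column gather; its adjoint sums the
# four children of each source pixel.
upsample_geometry <- function(H, W, N) {
  key <- geom_key("up", H, W, N)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- 2L * H
  W2 <- 2L * W
  r_o <- rep_len(0:(H2 - 1L), H2 * W2)
  c_o <- rep(0:(W2 - 1L), each = H2)
  n_off <- rep((0:(N - 1L)) * (H * W), each = H2 * W2)
  parent <- rep((c_o %/% 2L) * H + (r_o %/% 2L) + 1L, times = N) + n_off
  out <- list(parent = parent, pool = pool_geometry(H2, W2, N))
  .geom_cache[[key]] <- out
  out
}

upsample_forward <- function(X, geom) X[, geom$parent, drop = FALSE]

upsample_backward <- function(dOut, geom) {
  p <- geom$pool
  dOut[, p$i[[1]], drop = FALSE] + dOut[, p$i[[2]], drop = FALSE] +
    dOut[, p$i[[3]], drop = FALSE] + dOut[, p$i[[4]], drop = FALSE]
}

# column-wise softmax for C x P activation matrices
softmax_cols <- function(A) {
  z <- exp(sweep(A, 2, apply(A, 2, max)))
  sweep(z, 2, colSums(z), "/")
}
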