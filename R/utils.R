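# shared small helpers

shift_matrix <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Connected components of a binary mask
#'
#' Labels connected foreground regions by iterative minimum-label
#' propagation (vectorized over the whole image), with explicit control of
#' the connectivity rule. 4-connectivity never merges regions touching only
#' diagonally; 8-connectivity does.
#'
#' @param fg Logical matrix (foreground = `TRUE`).
#' @param connectivity 4 or 8.
#' @return Integer matrix: 0 for background, components numbered 1..k in
#'   order of their first (column-major) pixel.
#' @export
label_components <- function(fg, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  fg <- as.matrix(fg)
  storage.mode(fg) <- "logical"
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(Inf, H, W)
  lab[fg] <- which(fg)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    nxt <- lab
    for (o in offs) {
      nxt <- pmin(nxt, shift_matrix(lab, o[1], o[2], Inf))
    }
    nxt[!fg] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  out <- matrix(0L, H, W)
  ids <- sort(unique(lab[is.finite(lab)]))
  if (length(ids) > 0) {
    out[fg] <- match(lab[fg], ids)
  }
  out
}
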