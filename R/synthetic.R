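# Synthetic tissue-like data: textured RGB tiles with paired 14-class
# masks, and slide-level cohorts following the four risk categories. The
# generator stands in for H&E appearance: classes are separable by color
# and texture, which is what lets the full pipeline train and be tested
# offline. It does not emulate stain variation across centers, scanner
# differences, or annotation noise.

smooth_field <- function(H, W, scale = 8) {
  h <- max(2L, ceiling(H / scale))
  w <- max(2L, ceiling(W / scale))
  coarse <- matrix(rnorm(h * w), h, w)
  A <- overlap_weights(h, H)   # bilinear-ish smooth upsample via averaging
  B <- overlap_weights(w, W)
  f <- A %*% coarse %*% t(B)
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

disk_sel <- function(H, W, r0, c0, radius) {
  (row(matrix(0, H, W)) - r0)^2 + (col(matrix(0, H, W)) - c0)^2 <= radius^2
}

#' Per-class appearance model for synthetic rendering
#'
#' Assigns each class a base RGB color, a texture kind (`blob` smooth
#' modulation, `gland-ring`, `fiber` stripes, `speckle` fine noise) and a
#' noise level. Distinct classes must be distinguishable: a minimum
#' pairwise color distance is enforced at construction.
#'
#' @param classes Integer class indices the model must cover.
#' @param min_color_dist Minimum pairwise Euclidean RGB distance.
#' @return A `texture_model` tibble (index, r, g, b, kind, noise_sd).
#' @export
texture_model <- function(classes = 0:13, min_color_dist = 0.08) {
  pal <- tibble(
    index = 0:13,
    r = c(0.55, 0.35, 0.55, 0.92, 0.90, 0.75, 0.75, 0.60, 0.25, 0.85,
          0.95, 0.70, 0.85, 0.97),
    g = c(0.35, 0.25, 0.15, 0.72, 0.55, 0.50, 0.85, 0.50, 0.30, 0.25,
          0.92, 0.40, 0.80, 0.97),
    b = c(0.65, 0.60, 0.35, 0.82, 0.55, 0.55, 0.95, 0.40, 0.70, 0.25,
          0.88, 0.45, 0.50, 0.97),
    kind = c("gland-ring", "gland-ring", "gland-ring", "blob", "fiber",
             "blob", "blob", "speckle", "speckle", "speckle", "blob",
             "fiber", "fiber", "blob"),
    noise_sd = 0.03
  )
  out <- pal[pal$index %in% classes, ]
  if (nrow(out) < length(unique(classes))) {
    abort("unknown class index in `classes`")
  }
  cols <- as.matrix(out[c("r", "g", "b")])
  if (nrow(out) > 1) {
    d <- as.matrix(stats::dist(cols))
    diag(d) <- Inf
    if (min(d) < min_color_dist) {
      abort("texture model has indistinguishable classes (color distance)")
    }
  }
  structure(out, class = c("texture_model", class(out)))
}

#' Generate a space-filling synthetic label mask
#'
#' Partitions the canvas into spatially coherent regions, one per requested
#' class, by slicing a smooth random field at class-fraction quantiles;
#' every requested class is guaranteed at least 1% coverage. Optionally,
#' gland classes (0-2) receive ring structures whose interior is flagged as
#' lumen (`attr(mask, "lumen")`); lumen pixels stay labelled with their
#' gland class (benchmark convention: the lumen belongs to the gland) but
#' are rendered near-white so the brightness-based relabeling rule can be
#' exercised.
#'
#' @param shape `c(H, W)`, at least 64 x 64.
#' @param class_set Integer class indices to place.
#' @param fractions Optional target area fractions (defaults to symmetric
#'   Dirichlet draws floored at 2%).
#' @param lumen Add lumen-bearing gland rings for gland classes present.
#' @return Integer mask `H x W` with a logical `lumen` attribute.
#' @export
generate_label_geometry <- function(shape, class_set, fractions = NULL,
                                    lumen = FALSE) {
  H <- shape[1]; W <- shape[2]
  if (H < 64 || W < 64) abort("shape must be at least 64 x 64")
  class_set <- sort(unique(as.integer(class_set)))
  if (length(class_set) == 0) abort("class_set must be non-empty")
  k <- length(class_set)
  if (is.null(fractions)) {
    fractions <- -log(runif(k))
    fractions <- fractions / sum(fractions)
    fractions <- pmax(fractions, 0.02)
    fractions <- fractions / sum(fractions)
  }
  stopifnot(length(fractions) == k)
  f <- smooth_field(H, W, scale = max(6, round(min(H, W) / 10)))
  f <- f + 0.02 * matrix(rnorm(H * W), H, W)   # break quantile ties
  qs <- quantile(f, probs = cumsum(fractions)[-k])
  mask <- matrix(class_set[k], H, W)
  band <- findInterval(f, qs)                   # 0..k-1
  mask[] <- class_set[band + 1L]
  lum <- matrix(FALSE, H, W)
  glands <- intersect(class_set, 0:2)
  if (lumen && length(glands) > 0) {
    for (g in glands) {
      for (i in seq_len(2)) {
        r0 <- sample(seq(10, H - 10), 1)
        c0 <- sample(seq(10, W - 10), 1)
        rad <- sample(6:10, 1)
        sel <- disk_sel(H, W, r0, c0, rad)
        mask[sel] <- g
        lum[disk_sel(H, W, r0, c0, rad / 2.2)] <- TRUE
      }
    }
  }
  # enforce >= 1% coverage per requested class
  min_px <- ceiling(0.01 * H * W)
  for (i in seq_len(k)) {
    short <- min_px - sum(mask == class_set[i])
    if (short > 0) {
      rad <- ceiling(sqrt((short + 10) / pi)) + 1
      r0 <- sample(seq(rad + 1, H - rad), 1)
      c0 <- sample(seq(rad + 1, W - rad), 1)
      sel <- disk_sel(H, W, r0, c0, rad)
      mask[sel] <- class_set[i]
      lum[sel] <- FALSE
    }
  }
  storage.mode(mask) <- "integer"
  attr(mask, "lumen") <- lum
  mask
}

#' Render a synthetic RGB tile from a label mask
#'
#' Paints each class with its base color, modulated by its texture kind,
#' plus additive Gaussian noise. Lumen pixels (from the mask's `lumen`
#' attribute) are rendered near-white with mean RGB above 240/255.
#'
#' @param mask Integer mask from [generate_label_geometry()].
#' @param texture A [texture_model()] covering the mask's classes.
#' @return RGB array `H x W x 3` in `[0, 1]`.
#' @export
render_texture <- function(mask, texture = texture_model()) {
  H <- nrow(mask); W <- ncol(mask)
  img <- array(0, c(H, W, 3))
  mod_blob <- smooth_field(H, W, scale = 6) * 0.16 - 0.08
  stripes <- 0.08 * sin(outer(seq_len(H), seq_len(W), function(r, c)
    (r + 2 * c) / 3))
  for (i in seq_len(nrow(texture))) {
    cls <- texture$index[i]
    sel <- mask == cls
    if (!any(sel)) next
    modu <- switch(texture$kind[i],
      "blob" = mod_blob[sel],
      "gland-ring" = mod_blob[sel],
      "fiber" = stripes[sel],
      "speckle" = 0.10 * rnorm(sum(sel)),
      0)
    base <- c(texture$r[i], texture$g[i], texture$b[i])
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[sel] <- base[ch] + modu
      img[, , ch] <- pl
    }
  }
  lum <- attr(mask, "lumen")
  if (!is.null(lum) && any(lum)) {
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[lum] <- 0.985
      img[, , ch] <- pl
    }
  }
  noise <- array(rnorm(H * W * 3, sd = texture$noise_sd[1]), c(H, W, 3))
  if (!is.null(lum) && any(lum)) {
    # keep lumina unambiguously above the brightness threshold
    for (ch in 1:3) noise[, , ch][lum] <- pmin(noise[, , ch][lum], 0)
  }
  pmin(pmax(img + noise, 0), 1)
}

#' Generate a set of labeled training tiles
#'
#' @param n Number of tiles.
#' @param shape Tile shape `c(H, W)`.
#' @param class_set Classes present across tiles.
#' @param texture A [texture_model()].
#' @param spacing_um Pixel spacing.
#' @param lumen Add lumen-bearing gland rings.
#' @param seed Seed; the set is bit-reproducible.
#' @return List of [labeled_tile()].
#' @export
generate_tile_set <- function(n, shape = c(64, 64), class_set = c(0, 3, 5, 9, 13),
                              texture = texture_model(), spacing_um = 1.0,
                              lumen = FALSE, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mask <- generate_label_geometry(shape, class_set, lumen = lumen)
    img <- render_texture(mask, texture)
    labeled_tile(img, mask, spacing_um)
  })
}

#' Specification of a synthetic slide cohort
#'
#' Slide counts default to the reference cohort composition: 292 high-risk,
#' 693 low-grade dysplasia, 36 hyperplasia and 33 other. Composition rules
#' encode the label semantics: high-risk slides carry at least one tumor
#' cluster of 100 um^2 or more; low-grade slides carry low-grade dysplasia
#' plus tumor only as sub-30 um^2 specks (exercising the cluster filter);
#' hyperplasia has no dysplasia classes but an elevated gland + lamina
#' propria histogram signature (hyperplasia is not a segmentation class, so
#' it must be recognizable from composition alone); "other" is
#' benign stroma-dominated tissue.
#'
#' @param n_slides Named counts per risk class.
#' @param fragments_range Fragments per slide, inclusive range.
#' @param canvas_px Fragment canvas side in pixels.
#' @param spacing_um Pixel spacing of fragment maps.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_slides = c(other = 33, hyperplasia = 36,
                                     low_grade_dysplasia = 693,
                                     high_risk = 292),
                        fragments_range = c(1L, 4L), canvas_px = 96L,
                        spacing_um = 1.0) {
  stopifnot(all(names(n_slides) %in% risk_levels()),
            all(n_slides >= 0), canvas_px >= 64)
  structure(
    list(n_slides = n_slides, fragments_range = as.integer(fragments_range),
         canvas_px = as.integer(canvas_px), spacing_um = spacing_um),
    class = "cohort_spec"
  )
}

runif1 <- function(lo, hi) runif(1, lo, hi)

# composition (class -> tissue fraction) per risk category; fractions are
# over tissue (non-background) pixels
draw_composition <- function(risk) {
  frac <- switch(risk,
    other = c(`0` = runif1(0.10, 0.30), `3` = runif1(0.20, 0.40),
              `5` = runif1(0.10, 0.25), `6` = runif1(0.05, 0.15),
              `8` = runif1(0.05, 0.15), `11` = runif1(0.10, 0.30)),
    hyperplasia = c(`0` = runif1(0.30, 0.60), `5` = runif1(0.25, 0.40),
                    `1` = runif1(0.00, 0.10), `3` = runif1(0.05, 0.20),
                    `8` = runif1(0.02, 0.10)),
    low_grade_dysplasia = c(`1` = runif1(0.12, 0.45), `0` = runif1(0.08, 0.28),
                            `5` = runif1(0.15, 0.35), `3` = runif1(0.05, 0.20),
                            `8` = runif1(0.02, 0.10)),
    high_risk = c(`2` = runif1(0.10, 0.35), `1` = runif1(0.05, 0.20),
                  `4` = runif1(0.10, 0.30), `5` = runif1(0.10, 0.25),
                  `7` = runif1(0.02, 0.10), `3` = runif1(0.05, 0.15))
  )
  frac / sum(frac)
}

generate_fragment_map <- function(risk, canvas_px, spacing_um) {
  H <- canvas_px; W <- canvas_px
  mask <- matrix(13L, H, W)
  # tissue blob: thresholded smooth field around an elliptical core
  f <- smooth_field(H, W, scale = 10)
  ell <- ((row(mask) - H / 2) / (H * runif1(0.30, 0.42)))^2 +
    ((col(mask) - W / 2) / (W * runif1(0.30, 0.42)))^2
  tissue <- ell + 0.4 * (f - 0.5) < 1
  frac <- draw_composition(risk)
  classes <- as.integer(names(frac))
  g <- smooth_field(H, W, scale = 8)
  gt <- g[tissue]
  qs <- quantile(gt, probs = cumsum(frac)[-length(frac)])
  band <- findInterval(g, qs)
  mask[tissue] <- classes[band[tissue] + 1L]
  px_area <- spacing_um^2
  if (risk == "high_risk") {
    # guarantee a surviving tumor cluster of at least 100 um^2
    rad <- ceiling(sqrt(120 / px_area / pi)) + 1
    # keep the cluster in the central third so it stays on the tissue blob
    r0 <- sample(seq(round(H / 3), round(2 * H / 3)), 1)
    c0 <- sample(seq(round(W / 3), round(2 * W / 3)), 1)
    mask[disk_sel(H, W, r0, c0, rad) & tissue] <- 2L
    mask[disk_sel(H, W, r0, c0, rad - 1)] <- 2L
  }
  if (risk == "low_grade_dysplasia") {
    # tumor only as specks below the 30 um^2 filter, spaced so they never
    # merge into a surviving cluster
    n_specks <- sample(2:5, 1)
    max_px <- floor(29.9 / px_area)
    centers_r <- seq(12, H - 12, length.out = n_specks)
    for (i in seq_len(n_specks)) {
      r0 <- round(centers_r[i])
      c0 <- sample(seq(12, W - 12), 1)
      rad <- runif1(1, min(2.5, sqrt(max_px / pi)))
      sel <- disk_sel(H, W, r0, c0, rad)
      if (sum(sel) * px_area < 30) mask[sel] <- 2L
    }
  }
  segmentation_map(mask, spacing_um)
}

#' Generate a synthetic slide cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed; regeneration is bit-identical.
#' @return List of labelled [slide_case()] objects.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  cases <- list()
  for (risk in names(spec$n_slides)) {
    n <- spec$n_slides[[risk]]
    for (i in seq_len(n)) {
      nf <- sample(seq(spec$fragments_range[1], spec$fragments_range[2]), 1)
      frags <- lapply(seq_len(nf), function(j) {
        generate_fragment_map(risk, spec$canvas_px, spec$spacing_um)
      })
      cases[[length(cases) + 1L]] <-
        slide_case(sprintf("%s_%03d", risk, i), frags, risk)
    }
  }
  cases
}

#' Compose a slide-level label map from a case's fragments
#'
#' Places the fragments of a case side by side on a background canvas with
#' padding, for exercising slide-level fragment detection.
#'
#' @param case A [slide_case()].
#' @param pad Background padding between and around fragments (px).
#' @return A [segmentation_map()].
#' @export
compose_slide_map <- function(case, pad = 16L) {
  hs <- vapply(case$fragments, function(f) nrow(f$labels), integer(1))
  ws <- vapply(case$fragments, function(f) ncol(f$labels), integer(1))
  H <- max(hs) + 2L * pad
  W <- sum(ws) + pad * (length(ws) + 1L)
  canvas <- matrix(13L, H, W)
  c0 <- pad
  for (i in seq_along(case$fragments)) {
    f <- case$fragments[[i]]$labels
    canvas[(pad + 1L):(pad + nrow(f)), (c0 + 1L):(c0 + ncol(f))] <- f
    c0 <- c0 + ncol(f) + pad
  }
  segmentation_map(canvas, case$fragments[[1]]$spacing_um)
}
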