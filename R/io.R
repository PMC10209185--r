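#' An RGB tile with paired label mask
#'
#' The atomic training/evaluation unit: an RGB image in `[0, 1]`, an
#' integer mask over the 14-class space (255 = ignore), and the pixel
#' spacing in micrometers per pixel.
#'
#' @param image Numeric array `H x W x 3` in `[0, 1]` (8-bit inputs are
#'   rescaled).
#' @param mask Integer matrix `H x W` with values in `0..13` or 255.
#' @param spacing_um Pixel spacing (um/px).
#' @return A `labeled_tile` object.
#' @export
labeled_tile <- function(image, mask, spacing_um = 1.0) {
  if (length(dim(image)) != 3L) abort("image must be H x W x C")
  if (max(image) > 1 + 1e-9) image <- image / 255
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))  # drop attributes
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort(sprintf("image (%s) and mask (%s) shapes differ",
                  paste(dim(image)[1:2], collapse = "x"),
                  paste(dim(mask), collapse = "x")))
  }
  bad <- setdiff(unique(as.vector(mask)), c(0:13, 255L))
  if (length(bad) > 0) {
    abort(paste0("mask contains labels outside the schema: ",
                 paste(bad, collapse = ", ")))
  }
  if (spacing_um <= 0) abort("spacing_um must be positive")
  structure(list(image = image, mask = mask, spacing_um = spacing_um),
            class = "labeled_tile")
}

#' @export
print.labeled_tile <- function(x, ...) {
  cat(sprintf("<labeled_tile> %dx%d px @ %.3g um/px, classes: %s\n",
              nrow(x$mask), ncol(x$mask), x$spacing_um,
              paste(setdiff(sort(unique(as.vector(x$mask))), 255L),
                    collapse = ",")))
  invisible(x)
}

#' A per-pixel class label map with physical spacing
#'
#' The output container of inference and the input of the slide
#' classifier. `spacing_um` propagates into all area computations
#' (`area_um2 = n_pixels * spacing_um^2`).
#'
#' @param labels Integer matrix of class labels in `0..13`.
#' @param spacing_um Pixel spacing (um/px).
#' @param likelihoods Optional array `H x W x C` of per-class likelihoods.
#' @return A `segmentation_map` object.
#' @export
segmentation_map <- function(labels, spacing_um = 1.0, likelihoods = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 13L)) {
    abort("labels must lie in 0..13")
  }
  if (spacing_um <= 0) abort("spacing_um must be positive")
  if (!is.null(likelihoods) &&
      !all(dim(likelihoods)[1:2] == dim(labels))) {
    abort("likelihoods must match label shape")
  }
  structure(list(labels = labels, spacing_um = spacing_um,
                 likelihoods = likelihoods),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %dx%d px @ %.3g um/px\n",
              nrow(x$labels), ncol(x$labels), x$spacing_um))
  invisible(x)
}

#' Read an image/mask pair from disk
#'
#' @param image_path PNG image path (RGB or RGBA; alpha dropped).
#' @param mask_path Single-channel PNG mask; 8- or 16-bit values are
#'   narrowed to integer labels and validated against the schema.
#' @param spacing_um Pixel spacing of the pair.
#' @return A [labeled_tile()].
#' @export
read_labeled_tile <- function(image_path, mask_path, spacing_um = 1.0) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) abort("image must be RGB")
  img <- img[, , 1:3, drop = FALSE]
  m <- png::readPNG(mask_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  bits <- attr(m, "bit.depth") %||% 8
  mask <- round(m * (2^bits - 1))
  labeled_tile(img, mask, spacing_um)
}

#' @rdname read_labeled_tile
#' @param tile A [labeled_tile()] to write.
#' @export
write_labeled_tile <- function(tile, image_path, mask_path) {
  png::writePNG(tile$image, image_path)
  png::writePNG(tile$mask / 255, mask_path)
  invisible(c(image_path, mask_path))
}

#' Persist / load a segmentation map
#'
#' The label map is written as a single-channel PNG; spacing and schema
#' hash go into a YAML sidecar (`<path>.yaml`). Optional likelihoods are
#' quantized to 8 bits per channel and stored as a vertically stacked
#' grayscale PNG (`<path>.lik.png`), so a round trip preserves labels
#' exactly and likelihoods within 1/255.
#'
#' @param map A [segmentation_map()].
#' @param path Output PNG path.
#' @param schema Schema whose hash tags the sidecar.
#' @return `path`, invisibly.
#' @export
write_segmentation_map <- function(map, path, schema = tissue_schema()) {
  stopifnot(inherits(map, "segmentation_map"))
  png::writePNG(map$labels / 255, path)
  meta <- list(spacing_um = map$spacing_um, schema_hash = schema_hash(schema),
               format_version = 1L)
  lik <- map$likelihoods
  if (!is.null(lik)) {
    d <- dim(lik)
    stacked <- matrix(aperm(lik, c(1, 3, 2)), d[1] * d[3], d[2])
    png::writePNG(pmin(pmax(stacked, 0), 1), paste0(path, ".lik.png"))
    meta$n_channels <- d[3]
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_segmentation_map
#' @param spacing_um Override when the sidecar is missing.
#' @export
read_segmentation_map <- function(path, schema = tissue_schema(),
                                  spacing_um = NULL) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) {
    if (is.null(spacing_um)) {
      abort("missing sidecar: pass `spacing_um` explicitly")
    }
    meta <- list(spacing_um = spacing_um)
  } else {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$schema_hash) &&
        !identical(meta$schema_hash, schema_hash(schema))) {
      warn("schema hash mismatch between sidecar and supplied schema")
    }
  }
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  labels <- round(m * 255)
  lik <- NULL
  likpath <- paste0(path, ".lik.png")
  if (file.exists(likpath) && !is.null(meta$n_channels)) {
    stacked <- png::readPNG(likpath)
    C <- meta$n_channels
    H <- nrow(stacked) / C
    lik <- aperm(array(stacked, c(H, C, ncol(stacked))), c(1, 3, 2))
  }
  segmentation_map(labels, meta$spacing_um, lik)
}

#' Dataset manifest I/O
#'
#' A manifest is a CSV of (image_path, mask_path, spacing_um, split,
#' slide_id) records; paths are validated at load.
#'
#' @param manifest A data frame with those columns.
#' @param path CSV path.
#' @return `read_manifest` returns a tibble.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_files Error if a referenced file is missing.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("image_path", "mask_path", "spacing_um")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    abort(paste0("manifest lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (any(m$spacing_um <= 0)) abort("manifest spacing_um must be positive")
  if (check_files) {
    paths <- c(m$image_path, m$mask_path)
    gone <- paths[!file.exists(paths)]
    if (length(gone) > 0) {
      abort(paste0("missing files: ", paste(head(gone, 3), collapse = ", ")))
    }
  }
  m
}

# directory dialects used by the CLI (the layouts `simulate` writes)

read_tile_dir <- function(dir, spacing_um = 1.0) {
  masks <- sort(list.files(dir, pattern = "_mask\\.png$", full.names = TRUE))
  if (length(masks) == 0) abort(paste0("no *_mask.png files in ", dir))
  lapply(masks, function(mp) {
    read_labeled_tile(sub("_mask\\.png$", ".png", mp), mp, spacing_um)
  })
}

read_cohort_dir <- function(dir, labelled = TRUE) {
  maps <- sort(list.files(dir, pattern = "_f[0-9]+\\.png$",
                          full.names = TRUE))
  if (length(maps) == 0) abort(paste0("no fragment maps in ", dir))
  sid <- sub("_f[0-9]+\\.png$", "", basename(maps))
  labels <- NULL
  if (labelled) {
    lp <- file.path(dir, "labels.csv")
    if (!file.exists(lp)) abort("labels.csv missing")
    labels <- read.csv(lp, stringsAsFactors = FALSE)
  }
  lapply(unique(sid), function(s) {
    frags <- lapply(maps[sid == s], read_segmentation_map)
    slide_case(s, frags,
               label = if (labelled) labels$label[labels$slide_id == s][1])
  })
}

#' Serialize / load a training configuration as YAML
#'
#' @param config A [train_config()].
#' @param path YAML path.
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  x <- unclass(config)
  x$loss <- unclass(x$loss)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("patch_px", "batch_size", "lr_init", "loss")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("training config lacks fields: ",
                 paste(miss, collapse = ", ")))
  }
  lc <- do.call(loss_config, x$loss[intersect(names(x$loss), names(formals(loss_config)))])
  x$loss <- NULL
  args <- x[intersect(names(x), names(formals(train_config)))]
  args$loss <- lc
  do.call(train_config, args)
}
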