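#' The 14-class colorectal tissue label space
#'
#' Builds the canonical ordered label space used throughout the package:
#' fourteen tissue compartments annotated in H&E whole-slide images, indexed
#' `0..13` in a fixed order, plus an ignore label (255) for unannotated
#' pixels. "Background" is a real, trained class (index 13); the ignore label
#' is not a class and never appears in model targets.
#'
#' @return A `tissue_schema` object: a list with
#'   * `classes`: a tibble with columns `index` (0-based), `name`, `color`
#'     (hex RGB used for rendering label maps),
#'   * `ignore_index`: integer 255.
#' @examples
#' schema <- tissue_schema()
#' schema$classes$name[3] # "high-grade dysplasia/tumor"
#' @export
tissue_schema <- function() {
  names <- c(
    "normal glands", "low-grade dysplasia", "high-grade dysplasia/tumor",
    "submucosal stroma", "desmoplastic stroma", "stroma lamina propria",
    "mucus", "necrosis and debris", "lymphocytes", "erythrocytes",
    "adipose tissue", "muscle", "nerve", "background"
  )
  colors <- c(
    "#1f77b4", "#ff7f0e", "#d62728", "#8c564b", "#e377c2", "#2ca02c",
    "#17becf", "#7f7f7f", "#9467bd", "#bcbd22", "#f7b6d2", "#aec7e8",
    "#ffbb78", "#f0f0f0"
  )
  structure(
    list(
      classes = tibble(index = 0:13, name = names, color = colors),
      ignore_index = 255L
    ),
    class = "tissue_schema"
  )
}

#' @export
print.tissue_schema <- function(x, ...) {
  cat("<tissue_schema> ", nrow(x$classes), " classes, ignore_index = ",
      x$ignore_index, "\n", sep = "")
  print(x$classes, n = nrow(x$classes))
  invisible(x)
}

#' @export
length.tissue_schema <- function(x) nrow(x$classes)

#' Ordinal biopsy risk categories
#'
#' Slide-level diagnostic categories in increasing clinical risk:
#' `other < hyperplasia < low_grade_dysplasia < high_risk`. The order drives
#' worst-grade aggregation across tissue fragments and the quadratic kappa
#' weighting.
#'
#' @return Character vector of the four levels, lowest risk first.
#' @export
risk_levels <- function() {
  c("other", "hyperplasia", "low_grade_dysplasia", "high_risk")
}

#' Coerce to an ordered risk factor
#'
#' @param x Character or factor of risk labels.
#' @return An ordered factor over [risk_levels()].
#' @export
risk_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), risk_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown risk labels: ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = risk_levels(), ordered = TRUE)
}

new_merge_map <- function(mapping, targets, name) {
  stopifnot(length(mapping) == 14L, all(mapping %in% targets$index))
  # idempotence: every target label must be a fixed point of the map
  stopifnot(all(mapping[targets$index + 1L] == targets$index))
  structure(
    list(mapping = as.integer(mapping), targets = targets, name = name),
    class = "class_merge_map"
  )
}

#' @export
print.class_merge_map <- function(x, ...) {
  cat("<class_merge_map> ", x$name, ": 14 classes -> {",
      paste(sprintf("%s=%d", x$targets$name, x$targets$index),
            collapse = ", "), "}\n", sep = "")
  invisible(x)
}

check_default_schema <- function(schema) {
  if (!inherits(schema, "tissue_schema")) {
    abort("`schema` must be a tissue_schema")
  }
  ref <- tissue_schema()
  if (!identical(schema$classes$name, ref$classes$name)) {
    abort("merge maps are defined for the default 14-class schema only")
  }
  invisible(schema)
}

#' Class merging for gland-segmentation benchmark comparison
#'
#' Benchmarks that segment glands as a single entity need the epithelial
#' classes collapsed. The binary merge pools normal glands, low-grade
#' dysplasia and high-grade dysplasia/tumor into one "gland" label and
#' everything else into "non-gland". The three-class merge keeps benign
#' epithelium (normal glands + low-grade dysplasia) separate from malignant
#' epithelium (tumor), with all remaining classes as "non-gland".
#'
#' Reduced labels are encoded as fixed points of the map (the gland label
#' reuses index 0, malignant epithelium index 2, non-gland index 3), which
#' makes applying a map to an already merged mask a no-op (idempotence).
#'
#' @param schema The default [tissue_schema()].
#' @return A `class_merge_map`: `mapping` (source index 0..13 to reduced
#'   index) plus a `targets` tibble naming the reduced labels.
#' @examples
#' m <- crag_merge_map(tissue_schema())
#' m$mapping[1:3] # the three epithelial classes all map to "gland"
#' @export
crag_merge_map <- function(schema = tissue_schema()) {
  check_default_schema(schema)
  mapping <- rep(3L, 14L)        # non-gland
  mapping[1:3] <- 0L             # 0-based classes 0,1,2 -> gland
  new_merge_map(mapping,
                tibble(index = c(0L, 3L), name = c("gland", "non-gland")),
                "crag")
}

#' @rdname crag_merge_map
#' @export
glas_merge_map <- function(schema = tissue_schema()) {
  check_default_schema(schema)
  mapping <- rep(3L, 14L)        # non-gland
  mapping[1:2] <- 0L             # normal glands + low-grade dysplasia
  mapping[3] <- 2L               # high-grade dysplasia/tumor
  new_merge_map(mapping,
                tibble(index = c(0L, 2L, 3L),
                       name = c("benign epithelium", "malignant epithelium",
                                "non-gland")),
                "glas")
}

#' Apply a class-merge map to an integer label mask
#'
#' Ignore-labelled pixels (>= 14) pass through unchanged. Applying a map to
#' an already merged mask is the identity on the reduced label set, so the
#' operation is idempotent.
#'
#' @param mask Integer matrix (or vector) of class labels.
#' @param map A `class_merge_map`.
#' @param ignore_index Label left untouched (default 255).
#' @return Mask of the same shape over the reduced label set.
#' @export
apply_merge_map <- function(mask, map, ignore_index = 255L) {
  stopifnot(inherits(map, "class_merge_map"))
  out <- mask
  src <- mask >= 0L & mask <= 13L
  out[src] <- map$mapping[mask[src] + 1L]
  # already-reduced labels (< number of targets) are fixed points by
  # construction since the map restricted to 0..(k-1) is the identity there
  out
}

#' Serialize / load a tissue schema as YAML
#'
#' @param schema A `tissue_schema`.
#' @param path File path.
#' @return `read_schema_yaml` returns a `tissue_schema`;
#'   `write_schema_yaml` returns `path` invisibly.
#' @export
write_schema_yaml <- function(schema, path) {
  stopifnot(inherits(schema, "tissue_schema"))
  yaml::write_yaml(
    list(
      ignore_index = schema$ignore_index,
      classes = purrr::pmap(schema$classes, function(index, name, color) {
        list(index = index, name = name, color = color)
      })
    ),
    path
  )
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cls <- purrr::map_dfr(raw$classes, ~ tibble(
    index = as.integer(.x$index), name = .x$name, color = .x$color
  ))
  cls <- dplyr::arrange(cls, .data$index)
  if (!identical(cls$index, 0:(nrow(cls) - 1L))) {
    abort("schema YAML has non-contiguous class indices")
  }
  structure(
    list(classes = cls, ignore_index = as.integer(raw$ignore_index)),
    class = "tissue_schema"
  )
}

#' Stable hash of a schema (class order + ignore label)
#'
#' Used to tag artifacts (label maps, checkpoints) so downstream steps can
#' detect schema mismatches without carrying the full schema around.
#'
#' @param schema A `tissue_schema`.
#' @return A short character hash.
#' @export
schema_hash <- function(schema) {
  key <- paste(c(schema$classes$name, schema$ignore_index), collapse = "|")
  # small FNV-1a style rolling hash; stable across sessions
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
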