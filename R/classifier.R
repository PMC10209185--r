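#' A slide-level case: tissue fragments plus an optional risk label
#'
#' A whole-slide image can contain several sections (fragments) of one
#' biopsy; the case bundles their segmentation maps under one slide
#' identifier. All fragments must share pixel spacing.
#'
#' @param slide_id Character identifier.
#' @param fragments Non-empty list of [segmentation_map()].
#' @param label Optional risk label (training only).
#' @return A `slide_case` object.
#' @export
slide_case <- function(slide_id, fragments, label = NULL) {
  if (length(fragments) < 1) abort("a case needs at least one fragment")
  sp <- vapply(fragments, function(f) f$spacing_um, numeric(1))
  if (max(sp) - min(sp) > 1e-9) abort("fragments must share pixel spacing")
  if (!is.null(label)) label <- as.character(risk_factor(label))
  structure(list(slide_id = as.character(slide_id), fragments = fragments,
                 label = label),
            class = "slide_case")
}

#' @export
print.slide_case <- function(x, ...) {
  cat(sprintf("<slide_case> %s: %d fragment(s)%s\n", x$slide_id,
              length(x$fragments),
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Split a slide-level label map into tissue fragments
#'
#' Connected components of non-background pixels become fragments, each
#' returned as a cropped [segmentation_map()] with pixels of other
#' components reset to background. Components below the minimum tissue
#' area are discarded as debris.
#'
#' @param map A slide-level [segmentation_map()].
#' @param background_index Background class (default 13).
#' @param min_area_um2 Minimum fragment area (default 1e4 um^2).
#' @param connectivity 4 (default) or 8.
#' @return List of fragment maps (possibly empty, with a warning).
#' @export
find_fragments <- function(map, background_index = 13L, min_area_um2 = 1e4,
                           connectivity = 4L) {
  stopifnot(inherits(map, "segmentation_map"))
  comp <- label_components(map$labels != background_index, connectivity)
  k <- max(comp)
  px_area <- map$spacing_um^2
  out <- list()
  for (i in seq_len(k)) {
    sel <- comp == i
    if (sum(sel) * px_area < min_area_um2) next
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    sub <- map$labels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    subsel <- sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    sub[!subsel] <- as.integer(background_index)
    out[[length(out) + 1L]] <- segmentation_map(sub, map$spacing_um)
  }
  if (length(out) == 0) warn("no tissue fragments above the minimum area")
  out
}

#' Tumor cluster areas within a fragment
#'
#' Connected components of the high-grade dysplasia/tumor class, with
#' cluster area in physical units (`pixels * spacing_um^2`). Clusters
#' smaller than `min_area_um2` (default 30 um^2) are removed: the
#' segmentation model occasionally emits tiny spurious tumor specks, and
#' the filter corrects these before cluster statistics are computed. The
#' filter applies to cluster features only; the label map and class
#' histogram are left untouched.
#'
#' @param fragment A fragment [segmentation_map()].
#' @param min_area_um2 Exclusion threshold (clusters with area strictly
#'   below it are dropped).
#' @param connectivity 4 (default) or 8.
#' @param tumor_index Class index of high-grade dysplasia/tumor (2).
#' @return Numeric vector of surviving cluster areas (um^2), descending.
#' @export
tumor_clusters <- function(fragment, min_area_um2 = 30, connectivity = 4L,
                           tumor_index = 2L) {
  stopifnot(inherits(fragment, "segmentation_map"))
  comp <- label_components(fragment$labels == tumor_index, connectivity)
  if (max(comp) == 0) return(numeric(0))
  areas <- tabulate(comp[comp > 0]) * fragment$spacing_um^2
  sort(areas[areas >= min_area_um2], decreasing = TRUE)
}

feature_names <- function(schema = tissue_schema()) {
  c(sprintf("hist_%02d", schema$classes$index),
    "n_tumor_clusters", "mean_cluster_area", "min_cluster_area",
    "max_cluster_area")
}

#' Extract the 18 slide-classification features of a fragment
#'
#' The feature set: (a) the normalized 14-bin histogram of tissue classes
#' over the fragment's tissue pixels (background excluded, so the
#' background bin is zero and the histogram is invariant to padding), and
#' (b) four tumor-cluster statistics after the 30 um^2 filter - cluster
#' count and mean/min/max cluster area in um^2 (all zero when no cluster
#' survives).
#'
#' @param fragment A fragment [segmentation_map()].
#' @param schema A [tissue_schema()].
#' @param min_area_um2,connectivity Passed to [tumor_clusters()].
#' @return A one-row tibble of 18 features.
#' @export
extract_features <- function(fragment, schema = tissue_schema(),
                             min_area_um2 = 30, connectivity = 4L) {
  stopifnot(inherits(fragment, "segmentation_map"))
  labs <- fragment$labels
  tissue <- labs[labs != 13L]
  if (length(tissue) == 0) abort("fragment contains no tissue pixels")
  hist <- tabulate(tissue + 1L, nbins = 14L)
  hist <- hist / sum(hist)
  cl <- tumor_clusters(fragment, min_area_um2, connectivity)
  vals <- c(hist, length(cl),
            if (length(cl) > 0) c(mean(cl), min(cl), max(cl)) else c(0, 0, 0))
  out <- as_tibble(as.list(setNames(vals, feature_names(schema))))
  out
}

case_features <- function(case, schema = tissue_schema()) {
  purrr::imap_dfr(case$fragments, function(f, i) {
    dplyr::bind_cols(
      tibble(slide_id = case$slide_id, fragment = i,
             label = case$label %||% NA_character_),
      extract_features(f, schema)
    )
  })
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < 2) {
      warn(sprintf("class '%s' has < 2 cases: assigned to a random fold", cl))
      fold[ix] <- sample.int(k, length(ix), replace = TRUE)
      next
    }
    fold[ix] <- (sample(seq_along(ix)) %% k) + 1L
  }
  fold
}

scale_fit <- function(x) {
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = center, scale = scl)
}

scale_apply <- function(x, sc) {
  as.data.frame(sweep(sweep(as.matrix(x), 2, sc$center), 2, sc$scale, "/"))
}

fit_one_forest <- function(feat_train, n_trees, seed) {
  sc <- scale_fit(feat_train[feature_names()])
  x <- scale_apply(feat_train[feature_names()], sc)
  y <- risk_factor(feat_train$label)
  forest <- ranger::ranger(
    x = x, y = factor(as.character(y), levels = risk_levels()),
    num.trees = n_trees, probability = TRUE, seed = seed,
    num.threads = 1
  )
  structure(list(forest = forest, scaling = sc), class = "biopsy_forest")
}

predict_fragments <- function(model, feat) {
  x <- scale_apply(feat[feature_names()], model$scaling)
  raw <- predict(model$forest, data = x, num.threads = 1)$predictions
  # a training split may lack a class; expand to the full label set
  probs <- matrix(0, nrow(raw), length(risk_levels()),
                  dimnames = list(NULL, risk_levels()))
  probs[, colnames(raw)] <- raw
  pred <- risk_levels()[apply(probs, 1, which.max)]
  dplyr::bind_cols(
    feat[c("slide_id", "fragment", "label")],
    as_tibble(as.data.frame(probs)),
    tibble(fragment_pred = pred)
  )
}

worst_grade_aggregate <- function(frag_pred) {
  frag_pred |>
    dplyr::mutate(rank = as.integer(risk_factor(.data$fragment_pred))) |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::slice_max(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"rank", -"fragment") |>
    dplyr::rename(predicted = "fragment_pred")
}

#' Fit the biopsy risk classifier with cross-validation
#'
#' Trains a 1000-tree random forest on per-fragment features in a
#' stratified five-fold cross-validation over slides. Per fold, feature
#' normalization (zero mean, unit variance) is learned on the four
#' training folds only and applied to the held-out fold; fragments carry
#' their slide's label during training (weak labels), and held-out slides
#' are labelled by their worst-graded fragment. A final model trained on
#' all cases is included for deployment.
#'
#' @param cases List of labelled [slide_case()] objects.
#' @param n_trees Trees per forest (default 1000).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed controlling fold assignment and forests.
#' @param schema A [tissue_schema()].
#' @return A `biopsy_forest_cv` object: `slide_predictions` (out-of-fold,
#'   one row per slide with class probabilities of the worst fragment),
#'   `fragment_predictions`, `fold_assignment`, per-fold `models`, and
#'   `final_model`.
#' @export
fit_forest <- function(cases, n_trees = 1000L, folds = 5L, seed = 1L,
                       schema = tissue_schema()) {
  if (length(cases) < folds) abort("need at least as many cases as folds")
  labels <- vapply(cases, function(c) c$label %||% NA_character_, character(1))
  if (any(is.na(labels))) abort("all cases must carry a risk label")
  feat <- purrr::map_dfr(cases, case_features, schema = schema)
  slide_ids <- vapply(cases, function(c) c$slide_id, character(1))
  fold <- stratified_folds(labels, folds, seed)
  assignment <- tibble(slide_id = slide_ids, label = labels, fold = fold)
  frag_pred <- list()
  models <- vector("list", folds)
  for (f in seq_len(folds)) {
    train_ids <- slide_ids[fold != f]
    test_ids <- slide_ids[fold == f]
    models[[f]] <- fit_one_forest(
      feat[feat$slide_id %in% train_ids, ], n_trees, seed + f)
    pr <- predict_fragments(models[[f]], feat[feat$slide_id %in% test_ids, ])
    pr$fold <- f
    frag_pred[[f]] <- pr
  }
  frag_pred <- dplyr::bind_rows(frag_pred)
  slide_pred <- worst_grade_aggregate(frag_pred) |>
    dplyr::left_join(assignment[c("slide_id", "fold")], by = "slide_id",
                     suffix = c("", ".y")) |>
    dplyr::select(-dplyr::ends_with(".y"))
  final <- fit_one_forest(feat, n_trees, seed)
  structure(
    list(slide_predictions = slide_pred, fragment_predictions = frag_pred,
         fold_assignment = assignment, models = models, final_model = final,
         n_trees = n_trees, folds = folds, seed = seed),
    class = "biopsy_forest_cv"
  )
}

#' @export
print.biopsy_forest_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<biopsy_forest_cv> %d slides, %d folds, %d trees | out-of-fold QWK %.3f\n",
    nrow(x$slide_predictions), x$folds, x$n_trees, g$kappa))
  invisible(x)
}

#' @describeIn fit_forest Out-of-fold slide predictions as a tibble.
#' @method tidy biopsy_forest_cv
#' @param x A `biopsy_forest_cv`.
#' @param ... Unused.
#' @export
tidy.biopsy_forest_cv <- function(x, ...) x$slide_predictions

#' @describeIn fit_forest One-row summary: out-of-fold quadratic weighted
#'   kappa, accuracy, and one-vs-all AUC per class.
#' @method glance biopsy_forest_cv
#' @export
glance.biopsy_forest_cv <- function(x, ...) {
  sp <- x$slide_predictions
  cm <- confusion_matrix(sp$label, sp$predicted)
  roc <- one_vs_all_roc(sp[risk_levels()], sp$label, folds = sp$fold)
  out <- tibble(
    n_slides = nrow(sp), kappa = quadratic_weighted_kappa(cm),
    accuracy = mean(sp$label == sp$predicted)
  )
  for (i in seq_len(nrow(roc))) {
    out[[paste0("auc_", roc$class[i])]] <- roc$auc[i]
  }
  out
}

#' Classify one slide with a fitted forest
#'
#' Each fragment is classified independently; the slide label is the
#' worst (highest-risk) fragment label, and the slide probabilities are
#' those of that fragment.
#'
#' @param model A `biopsy_forest` (e.g. `fit$final_model`) or a
#'   `biopsy_forest_cv` (its final model is used).
#' @param case A [slide_case()].
#' @param schema A [tissue_schema()].
#' @return A one-row tibble: `slide_id`, `predicted`, class probabilities.
#' @export
classify_slide <- function(model, case, schema = tissue_schema()) {
  if (inherits(model, "biopsy_forest_cv")) model <- model$final_model
  stopifnot(inherits(model, "biopsy_forest"), inherits(case, "slide_case"))
  feat <- case_features(case, schema)
  pr <- predict_fragments(model, feat)
  worst_grade_aggregate(pr)
}
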