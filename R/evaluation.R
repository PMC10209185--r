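#' Per-class and mean Dice score of a segmentation
#'
#' For each class c, `dice = 2 |P_c intersect R_c| / (|P_c| + |R_c|)`.
#' Reference pixels carrying the ignore label are excluded everywhere.
#' Classes absent from both prediction and reference are marked absent; the
#' mean is computed either excluding them (default) or counting them as
#' zero (`absent = "zero"`, the convention used when plotting per-center
#' scores where a missing tissue type scores zero).
#'
#' @param pred A [segmentation_map()] or integer label matrix.
#' @param ref Integer reference mask (may contain the ignore label).
#' @param schema A [tissue_schema()].
#' @param absent Absent-class policy for the mean: `"exclude"` or `"zero"`.
#' @return A `dice_report` tibble: class index, name, pixel counts, `dice`,
#'   `present`; the mean is in `attr(, "mean")` and via [glance()].
#' @export
dice_per_class <- function(pred, ref, schema = tissue_schema(),
                           absent = c("exclude", "zero")) {
  absent <- match.arg(absent)
  p <- if (inherits(pred, "segmentation_map")) pred$labels else as.matrix(pred)
  r <- as.matrix(ref)
  if (!all(dim(p) == dim(r))) {
    abort(sprintf("shape mismatch: pred %s vs ref %s",
                  paste(dim(p), collapse = "x"),
                  paste(dim(r), collapse = "x")))
  }
  valid <- r != schema$ignore_index
  pv <- p[valid]
  rv <- r[valid]
  out <- purrr::map_dfr(schema$classes$index, function(c) {
    np <- sum(pv == c)
    nr <- sum(rv == c)
    inter <- sum(pv == c & rv == c)
    tibble(
      index = c, name = schema$classes$name[c + 1L],
      n_pred = np, n_ref = nr,
      present = (np + nr) > 0,
      dice = if (np + nr > 0) 2 * inter / (np + nr) else NA_real_
    )
  })
  mean_dice <- if (absent == "exclude") {
    mean(out$dice[out$present])
  } else {
    mean(ifelse(out$present, out$dice, 0))
  }
  structure(out, class = c("dice_report", class(out)),
            mean = mean_dice, absent = absent)
}

#' @describeIn dice_per_class One-row summary (mean Dice, classes present).
#' @method glance dice_report
#' @param x A `dice_report`.
#' @param ... Unused.
#' @export
glance.dice_report <- function(x, ...) {
  tibble(mean_dice = attr(x, "mean"), n_present = sum(x$present),
         absent_policy = attr(x, "absent"))
}

#' Relabel gland lumina as background by brightness
#'
#' Gland-segmentation benchmarks include the (near-white) lumen in the
#' gland object, while this package's schema segments lumina as background.
#' For comparison, reference pixels whose mean RGB value strictly exceeds
#' the threshold are relabelled to background.
#'
#' @param image RGB array aligned with `mask`, in `[0, 1]` or 0-255.
#' @param mask Integer reference mask.
#' @param threshold Mean-RGB threshold on the 0-255 scale (default 240,
#'   strict inequality).
#' @param background_index Label written at lumen pixels (default 13).
#' @return The relabelled mask.
#' @export
relabel_lumen <- function(image, mask, threshold = 240,
                          background_index = 13L) {
  stopifnot(length(dim(image)) == 3L)
  if (!all(dim(image)[1:2] == dim(mask))) abort("image and mask misaligned")
  scale <- if (max(image) <= 1 + 1e-9) 255 else 1
  mean_rgb <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3 * scale
  out <- as.matrix(mask)
  out[mean_rgb > threshold] <- as.integer(background_index)
  out
}

#' Benchmark-style F1 after class merging
#'
#' Applies a [class_merge_map][crag_merge_map] to both prediction and
#' reference, optionally relabels bright lumina in the reference, and
#' returns the pixel-level F1 (identical to Dice at pixel level) averaged
#' over the merged foreground classes, background excluded.
#'
#' @param pred A [segmentation_map()] or label matrix.
#' @param ref Reference mask (same label space as `pred` before merging).
#' @param merge A `class_merge_map`.
#' @param image Reference RGB image; required when `with_lumen = FALSE`.
#' @param with_lumen If `FALSE`, bright lumen pixels in the reference are
#'   relabelled to background before scoring.
#' @param ignore_index Ignore label in `ref`.
#' @return Scalar F1.
#' @export
merged_f1 <- function(pred, ref, merge, image = NULL, with_lumen = TRUE,
                      ignore_index = 255L) {
  stopifnot(inherits(merge, "class_merge_map"))
  p <- if (inherits(pred, "segmentation_map")) pred$labels else as.matrix(pred)
  r <- as.matrix(ref)
  if (!with_lumen) {
    if (is.null(image)) abort("lumen removal needs the reference image")
    r <- relabel_lumen(image, r)
  }
  pm <- apply_merge_map(p, merge, ignore_index)
  rm_ <- apply_merge_map(r, merge, ignore_index)
  valid <- rm_ != ignore_index
  pv <- pm[valid]
  rv <- rm_[valid]
  fg <- merge$targets$index[merge$targets$name != "non-gland"]
  f1 <- vapply(fg, function(c) {
    denom <- sum(pv == c) + sum(rv == c)
    if (denom == 0) return(NA_real_)
    2 * sum(pv == c & rv == c) / denom
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

#' Paired Wilcoxon signed-rank comparison of two models' scores
#'
#' Two-sided signed-rank test on paired per-tile (or per-class) scores.
#' The exact null distribution is used for n <= 25 informative pairs with
#' no ties; larger samples (or ties) use the normal approximation with tie
#' correction. If every difference is zero the comparison is degenerate and
#' reported as p = 1.
#'
#' @param scores_a,scores_b Equal-length paired score vectors.
#' @return A tibble with `statistic`, `p_value`, `n_effective`.
#' @export
wilcoxon_compare <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    abort("paired score vectors must have equal length")
  }
  d <- scores_a - scores_b
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble(statistic = NA_real_, p_value = 1, n_effective = 0L))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, paired = TRUE, exact = exact,
                       correct = !exact)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_effective = length(nz))
}

#' Confusion matrix of slide-level predictions
#'
#' @param reference,predicted Risk labels (characters or factors over
#'   [risk_levels()]).
#' @return A K x K integer matrix, rows = reference, cols = predicted.
#' @export
confusion_matrix <- function(reference, predicted) {
  r <- risk_factor(reference)
  p <- risk_factor(predicted)
  table(reference = r, predicted = p)
}

#' Quadratic weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement with squared-distance penalties:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `w_ij = (i - j)^2 / (K -
#' 1)^2`, `O` the observed confusion matrix and `E` the outer product of
#' its marginals (scaled to the same total). Misclassifications between
#' distant risk categories are penalized quadratically more than adjacent
#' confusions. Perfect agreement gives 1; marginal-product (chance)
#' agreement gives 0.
#'
#' @param cm Square confusion matrix of counts, rows = reference.
#' @return Scalar kappa in `(-Inf, 1]`.
#' @export
quadratic_weighted_kappa <- function(cm) {
  cm <- as.matrix(unclass(cm))
  K <- nrow(cm)
  if (K < 2 || ncol(cm) != K) abort("confusion matrix must be square, K >= 2")
  total <- sum(cm)
  if (total <= 0) abort("empty confusion matrix")
  w <- outer(seq_len(K), seq_len(K), function(i, j) (i - j)^2) / (K - 1)^2
  E <- outer(rowSums(cm), colSums(cm)) / total
  denom <- sum(w * E)
  if (denom == 0) abort("degenerate marginals: expected agreement undefined")
  1 - sum(w * cm) / denom
}

#' One-vs-all ROC analysis of slide class probabilities
#'
#' For each risk class, computes the AUC of that class's predicted
#' probability against binary class membership. With fold identifiers the
#' per-fold AUCs are summarized as mean and standard deviation, mirroring
#' cross-validated reporting. Classes without both a positive and a
#' negative example have undefined AUC and are reported as `NA`.
#'
#' @param scores Data frame of per-slide class probabilities with one
#'   column per risk class (named as [risk_levels()]).
#' @param labels True risk labels.
#' @param folds Optional fold identifier per slide.
#' @return A tibble: class, auc (pooled), and with folds `auc_mean`,
#'   `auc_sd`.
#' @export
one_vs_all_roc <- function(scores, labels, folds = NULL) {
  labels <- risk_factor(labels)
  auc1 <- function(resp, prob) {
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(
      response = resp, predictor = prob, levels = c(FALSE, TRUE),
      direction = "<", quiet = TRUE)))
  }
  purrr::map_dfr(risk_levels(), function(cl) {
    if (!cl %in% names(scores)) {
      abort(sprintf("scores lack a probability column for class '%s'", cl))
    }
    resp <- labels == cl
    prob <- scores[[cl]]
    row <- tibble(class = cl, auc = auc1(resp, prob))
    if (!is.null(folds)) {
      per <- vapply(split(seq_along(prob), folds),
                    function(ix) auc1(resp[ix], prob[ix]), numeric(1))
      row$auc_mean <- mean(per, na.rm = TRUE)
      row$auc_sd <- sd(per, na.rm = TRUE)
    }
    row
  })
}
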