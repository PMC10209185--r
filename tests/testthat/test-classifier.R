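make_map <- function(labels, spacing = 1) segmentation_map(labels, spacing)

test_that("fragment detection separates blobs and discards debris", {
  m <- matrix(13L, 200, 200)
  m[10:80, 10:80] <- 0L                      # ~5000 px fragment
  m[120:190, 120:190] <- 5L                  # second fragment
  m[100, 100] <- 2L                          # 1 px debris
  frags <- find_fragments(make_map(m), min_area_um2 = 1e3)
  expect_length(frags, 2)
  expect_identical(dim(frags[[1]]$labels), c(71L, 71L))
  # all-background map: empty with a warning
  expect_warning(f0 <- find_fragments(make_map(matrix(13L, 100, 100))),
                 "no tissue")
  expect_length(f0, 0)
  # a 50 px blob at 1 um/px is below a 1e4 um^2 threshold
  m2 <- matrix(13L, 100, 100)
  m2[1:10, 1:5] <- 0L
  expect_warning(f2 <- find_fragments(make_map(m2), min_area_um2 = 1e4))
  expect_length(f2, 0)
})

test_that("tumor cluster filter applies the 30 um^2 threshold in physical units", {
  m <- matrix(13L, 100, 100)
  m[1:5, 1:5] <- 2L                          # 25 px cluster
  m[50:55, 50:55] <- 2L                      # 36 px cluster
  frag <- make_map(m)
  areas <- tumor_clusters(frag, min_area_um2 = 30)
  expect_identical(areas, 36)                # 25 um^2 removed, 36 kept
  # at 2 um/px the 25 px cluster is 100 um^2 and survives
  areas2 <- tumor_clusters(make_map(m, spacing = 2), min_area_um2 = 30)
  expect_identical(sort(areas2), c(100, 144))
})

test_that("diagonally touching clusters stay separate under 4-connectivity", {
  m <- matrix(13L, 64, 64)
  m[1:7, 1:7] <- 2L
  m[8:14, 8:14] <- 2L                        # touches only at the corner
  expect_length(tumor_clusters(make_map(m), min_area_um2 = 30,
                               connectivity = 4), 2)
  expect_length(tumor_clusters(make_map(m), min_area_um2 = 30,
                               connectivity = 8), 1)
})

test_that("fragment features follow the documented semantics", {
  # pure lamina propria: one-hot histogram, zero cluster stats
  m <- matrix(5L, 64, 64)
  f <- extract_features(make_map(m))
  expect_equal(f$hist_05, 1)
  expect_equal(sum(as.numeric(f[1, sprintf("hist_%02d", 0:13)])), 1)
  expect_equal(f$n_tumor_clusters, 0)
  expect_equal(f$mean_cluster_area + f$min_cluster_area + f$max_cluster_area, 0)
  # a single 100 um^2 cluster: n = 1, mean = min = max = 100
  m2 <- matrix(5L, 64, 64)
  m2[1:10, 1:10] <- 2L
  f2 <- extract_features(make_map(m2))
  expect_equal(f2$n_tumor_clusters, 1)
  expect_equal(f2$mean_cluster_area, 100)
  expect_equal(f2$min_cluster_area, 100)
  expect_equal(f2$max_cluster_area, 100)
  # sub-threshold clusters still count in the histogram
  m3 <- matrix(5L, 64, 64)
  m3[1:2, 1:2] <- 2L                         # 4 px < 30 um^2
  f3 <- extract_features(make_map(m3))
  expect_equal(f3$n_tumor_clusters, 0)
  expect_equal(f3$hist_02, 4 / (64 * 64))
  # translation and padding invariance
  base <- matrix(13L, 64, 64)
  base[5:20, 5:20] <- 0L
  shifted <- matrix(13L, 96, 96)
  shifted[40:55, 60:75] <- 0L
  expect_equal(extract_features(make_map(base)),
               extract_features(make_map(shifted)))
})

test_that("worst-grade aggregation takes the highest-risk fragment", {
  cohort <- generate_cohort(
    cohort_spec(n_slides = setNames(c(6, 6, 6, 6), risk_levels()),
                canvas_px = 64), seed = 5)
  fit <- fit_forest(cohort, n_trees = 100, folds = 3, seed = 2)
  sp <- fit$slide_predictions
  fp <- fit$fragment_predictions
  for (sid in sp$slide_id) {
    worst <- max(risk_factor(fp$fragment_pred[fp$slide_id == sid]))
    expect_identical(as.character(worst), sp$predicted[sp$slide_id == sid])
  }
  # classify_slide mirrors the rule with the final model
  cs <- cohort[[1]]
  out <- classify_slide(fit, cs)
  frag_direct <- crcseg:::predict_fragments(
    fit$final_model, crcseg:::case_features(cs))
  expect_identical(out$predicted,
                   as.character(max(risk_factor(frag_direct$fragment_pred))))
})

test_that("cross-validation partitions slides and isolates normalization", {
  cohort <- generate_cohort(
    cohort_spec(n_slides = setNames(c(5, 5, 10, 10), risk_levels()),
                canvas_px = 64), seed = 7)
  fit <- fit_forest(cohort, n_trees = 50, folds = 5, seed = 3)
  fa <- fit$fold_assignment
  # every case in exactly one test fold
  expect_identical(sort(fit$slide_predictions$slide_id), sort(fa$slide_id))
  expect_identical(anyDuplicated(fit$slide_predictions$slide_id), 0L)
  # normalization parameters learned per training split differ across folds
  centers <- vapply(fit$models, function(m) m$scaling$center[["hist_02"]],
                    numeric(1))
  expect_gt(length(unique(centers)), 1)
  # determinism end to end
  fit2 <- fit_forest(cohort, n_trees = 50, folds = 5, seed = 3)
  expect_equal(fit$slide_predictions, fit2$slide_predictions)
})

test_that("degenerate inputs are handled", {
  cohort <- generate_cohort(
    cohort_spec(n_slides = setNames(c(1, 4, 4, 4), risk_levels()),
                canvas_px = 64), seed = 8)
  ws <- testthat::capture_warnings(
    fit <- fit_forest(cohort, n_trees = 30, folds = 4, seed = 1))
  expect_true(any(grepl("random fold", ws)))
  expect_s3_class(fit, "biopsy_forest_cv")
  unlabeled <- slide_case("x", cohort[[1]]$fragments)
  expect_error(fit_forest(c(cohort[2:13], list(unlabeled)), folds = 4),
               "risk label")
})
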