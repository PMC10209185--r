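test_that("per-class Dice matches hand-counted overlaps", {
  ref <- matrix(13L, 20, 20)
  ref[1:10, 1:10] <- 0L
  pred <- ref
  r <- dice_per_class(pred, ref)
  expect_true(all(r$dice[r$present] == 1))
  expect_equal(attr(r, "mean"), 1)
  # half overlap: |P| = |R| = 100, intersection 50
  pred2 <- matrix(13L, 20, 20)
  pred2[1:10, 6:15] <- 0L
  r2 <- dice_per_class(pred2, ref)
  expect_equal(r2$dice[r2$index == 0], 0.5)
  # disjoint equal-size regions score zero
  pred3 <- matrix(13L, 20, 20)
  pred3[11:20, 11:20] <- 0L
  r3 <- dice_per_class(pred3, ref)
  expect_equal(r3$dice[r3$index == 0], 0)
  expect_error(dice_per_class(pred[1:10, ], ref), "mismatch")
})

test_that("Dice is symmetric and ignore pixels are excluded", {
  set.seed(8)
  a <- matrix(sample(0:3, 400, replace = TRUE), 20)
  b <- matrix(sample(0:3, 400, replace = TRUE), 20)
  ra <- dice_per_class(a, b)
  rb <- dice_per_class(b, a)
  expect_equal(ra$dice, rb$dice)
  b2 <- b
  b2[1:5, ] <- 255L
  r <- dice_per_class(a, b2)
  r_manual <- dice_per_class(a[6:20, ], b[6:20, ])
  expect_equal(r$dice, r_manual$dice)
})

test_that("absent-class policy controls the mean", {
  ref <- matrix(0L, 10, 10)
  pred <- ref
  r_ex <- dice_per_class(pred, ref, absent = "exclude")
  r_zf <- dice_per_class(pred, ref, absent = "zero")
  expect_equal(attr(r_ex, "mean"), 1)
  expect_equal(attr(r_zf, "mean"), 1 / 14)   # 13 absent classes count as zero
  expect_identical(sum(r_ex$present), 1L)
})

test_that("lumen relabeling uses a strict mean-RGB threshold", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(255, 255, 255) / 255     # mean 255 > 240 -> background
  img[1, 2, ] <- c(240, 240, 240) / 255     # mean exactly 240 -> unchanged
  img[2, 1, ] <- c(250, 240, 235) / 255     # mean 241.67 -> background
  mask <- matrix(0L, 2, 2)
  out <- relabel_lumen(img, mask, threshold = 240)
  expect_identical(out, matrix(c(13L, 0L, 13L, 0L), 2, byrow = TRUE))
  # all-dark image unchanged
  dark <- array(0.2, c(2, 2, 3))
  expect_identical(relabel_lumen(dark, mask), mask)
})

test_that("merged F1 matches hand-computed overlap after merging", {
  m <- crag_merge_map()
  # |P| = |R| = 200 merged gland pixels with 150 shared
  ref <- matrix(13L, 20, 20)
  ref[1:10, 1:20] <- 0L                      # 200 gland px
  pred <- matrix(13L, 20, 20)
  pred[1:10, 1:15] <- 1L                     # 150 shared (as low-grade)
  pred[11:15, 1:10] <- 2L                    # 50 extra (as tumor)
  expect_equal(merged_f1(pred, ref, m), 2 * 150 / 400)
  expect_equal(merged_f1(ref, ref, m), 1)
  # lumen removal shrinks |R| by the white pixels
  img <- array(0.3, c(20, 20, 3))
  img[1:2, 1:10, ] <- 1                      # 20 white px inside the gland
  f1_with <- merged_f1(pred, ref, m, image = img, with_lumen = TRUE)
  f1_wo <- merged_f1(pred, ref, m, image = img, with_lumen = FALSE)
  inter_wo <- sum(pred[1:10, 1:15] == 1) - sum(pred[1:2, 1:10] == 1)
  expect_equal(f1_with, 0.75)
  expect_equal(f1_wo, 2 * inter_wo / (200 + 180))
})

test_that("identity merge with no lumen handling reduces to foreground Dice", {
  set.seed(14)
  pred <- matrix(sample(c(0L, 1L, 2L, 13L), 400, replace = TRUE), 20)
  ref <- matrix(sample(c(0L, 1L, 2L, 13L), 400, replace = TRUE), 20)
  m <- glas_merge_map()
  f1 <- merged_f1(pred, ref, m)
  # recompute from scratch on merged masks
  mp <- apply_merge_map(pred, m)
  mr <- apply_merge_map(ref, m)
  fg <- m$targets$index[m$targets$name != "non-gland"]
  direct <- mean(vapply(fg, function(c) {
    2 * sum(mp == c & mr == c) / (sum(mp == c) + sum(mr == c))
  }, numeric(1)))
  expect_equal(f1, direct)
})

test_that("Wilcoxon comparison behaves across degenerate and shifted inputs", {
  a <- runif(20)
  r_same <- wilcoxon_compare(a, a)
  expect_equal(r_same$p_value, 1)
  r_shift <- wilcoxon_compare(a, a + 0.3)
  expect_lt(r_shift$p_value, 0.001)
  expect_equal(r_shift$statistic, 0)
  # pair order does not matter
  o <- sample(20)
  r_perm <- wilcoxon_compare(a[o], (a + 0.3)[o])
  expect_equal(r_perm$p_value, r_shift$p_value)
  # agreement with the reference implementation on clean data
  set.seed(5)
  x <- rnorm(15)
  y <- x + rnorm(15, 0.2)
  ours <- wilcoxon_compare(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value)
  expect_error(wilcoxon_compare(1:3, 1:4), "equal length")
})

test_that("quadratic weighted kappa matches its definition", {
  expect_equal(quadratic_weighted_kappa(diag(c(5, 8, 2, 10))), 1)
  # chance-level agreement: matrix equal to outer product of marginals
  p <- c(0.1, 0.2, 0.3, 0.4)
  q <- c(0.25, 0.25, 0.3, 0.2)
  cm <- outer(p, q) * 400
  expect_equal(quadratic_weighted_kappa(cm), 0, tolerance = 1e-12)
  # independent double-loop oracle
  cm2 <- matrix(c(9, 1, 0, 10), 2, byrow = TRUE)
  K <- 2
  obs <- 0; exp_ <- 0
  tot <- sum(cm2)
  for (i in 1:K) for (j in 1:K) {
    w <- (i - j)^2 / (K - 1)^2
    obs <- obs + w * cm2[i, j]
    exp_ <- exp_ + w * sum(cm2[i, ]) * sum(cm2[, j]) / tot
  }
  expect_equal(quadratic_weighted_kappa(cm2), 1 - obs / exp_,
               tolerance = 1e-10)
  # invariance to scaling the matrix
  expect_equal(quadratic_weighted_kappa(cm2 * 7),
               quadratic_weighted_kappa(cm2), tolerance = 1e-12)
  expect_error(quadratic_weighted_kappa(matrix(1, 2, 3)), "square")
})

test_that("one-vs-all ROC has the expected limits and symmetries", {
  labels <- rep(risk_levels(), each = 25)
  # perfectly separating scores
  scores <- as.data.frame(matrix(0.01, 100, 4))
  names(scores) <- risk_levels()
  for (cl in risk_levels()) scores[labels == cl, cl] <- 0.97
  r <- one_vs_all_roc(scores, labels)
  expect_equal(r$auc, rep(1, 4))
  # label-independent scores: AUC near 0.5
  set.seed(10)
  n <- 500
  labs2 <- sample(risk_levels(), n, replace = TRUE)
  sc2 <- as.data.frame(matrix(runif(n * 4), n, 4))
  names(sc2) <- risk_levels()
  r2 <- one_vs_all_roc(sc2, labs2)
  expect_true(all(abs(r2$auc - 0.5) < 0.05))
  # reversing a score flips its AUC
  sc3 <- sc2
  sc3$high_risk <- -sc2$high_risk
  r3 <- one_vs_all_roc(sc3, labs2)
  expect_equal(r3$auc[4], 1 - r2$auc[4], tolerance = 1e-12)
  # single-class labels: undefined AUC reported as NA
  r4 <- one_vs_all_roc(sc2[1:5, ], rep("other", 5))
  expect_true(is.na(r4$auc[r4$class == "high_risk"]))
})
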