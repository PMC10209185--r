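test_that("cross-entropy matches direct per-pixel arithmetic", {
  # perfect prediction
  p <- matrix(c(1, 0, 0), 1)
  expect_equal(loss_cross_entropy(pixel_batch(p, targets = 0L)), 0)
  # uniform over 14 classes
  expect_equal(
    loss_cross_entropy(pixel_batch(matrix(1 / 14, 1, 14), targets = 5L)),
    log(14), tolerance = 1e-12)
  # seeded 3-pixel batch vs an explicit loop
  b <- random_prob_batch(3, 3, seed = 21)
  manual <- mean(vapply(1:3, function(i) {
    -log(b$probabilities[i, b$targets[i] + 1L])
  }, numeric(1)))
  expect_equal(loss_cross_entropy(b), manual, tolerance = 1e-12)
})

test_that("focal loss reduces to cross-entropy at gamma 0, alpha 1", {
  for (seed in 1:5) {
    b <- random_prob_batch(100, 14, seed = seed)
    expect_equal(loss_focal(b, alpha = 1, gamma = 0), loss_cross_entropy(b),
                 tolerance = 1e-9)
  }
})

test_that("focal loss matches its closed form on a single pixel", {
  p <- matrix(c(0.9, 0.06, 0.04), 1)
  expect_equal(loss_focal(pixel_batch(p, targets = 0L), 0.25, 2),
               0.25 * 0.1^2 * -log(0.9), tolerance = 1e-12)
  expect_equal(loss_focal(pixel_batch(matrix(c(1, 0, 0), 1), targets = 0L),
                          0.7, 3), 0)
})

test_that("tempered log/exp match closed forms and invert each other", {
  expect_equal(tempered_log(1, 0.3), 0)
  expect_equal(tempered_log(exp(1), 1), 1)
  expect_equal(tempered_log(4, 0.5), 2)
  expect_equal(tempered_exp(0, 1.7), 1)
  expect_equal(tempered_exp(-10, 2), 1 / 11, tolerance = 1e-12)
  expect_equal(tempered_exp(tempered_log(0.3, 0.7), 0.7), 0.3,
               tolerance = 1e-12)
  expect_error(tempered_log(-1, 0.5), "x > 0")
})

test_that("tempered softmax is a valid distribution and matches bisection", {
  # limit case: standard softmax
  set.seed(4)
  a <- matrix(rnorm(20 * 6), 20)
  std <- exp(a - apply(a, 1, max))
  std <- std / rowSums(std)
  expect_equal(tempered_softmax(a, 1), std, tolerance = 1e-8)
  # symmetry: equal activations -> uniform
  expect_equal(tempered_softmax(rep(2.5, 5), 1.8), rep(0.2, 5),
               tolerance = 1e-8)
  # oracle bisection on one vector
  v <- c(2, 1, 0.5)
  expect_equal(tempered_softmax(v, 1.5, tol = 1e-12, max_iter = 200),
               oracle_tempered_softmax(v, 1.5), tolerance = 1e-8)
  # validity over temperatures
  for (t2 in c(1, 1.2, 2, 4)) {
    p <- tempered_softmax(a, t2)
    expect_true(all(p >= 0))
    expect_true(max(abs(rowSums(p) - 1)) <= 1e-8)
    # order preservation
    expect_identical(apply(p, 1, which.max), apply(a, 1, which.max))
  }
})

test_that("bi-tempered loss recovers the logistic loss at t1 = t2 = 1", {
  for (seed in 1:5) {
    b <- random_act_batch(100, 14, seed = seed)
    p <- exp(b$activations - apply(b$activations, 1, max))
    p <- p / rowSums(p)
    ce <- loss_cross_entropy(pixel_batch(p, targets = b$targets))
    expect_equal(loss_bi_tempered(b, t1 = 1, t2 = 1), ce, tolerance = 1e-6)
  }
})

test_that("bi-tempered loss vanishes on confident correct predictions", {
  a <- matrix(c(50, 0, -1), 1)
  b <- pixel_batch(activations = a, targets = 0L)
  expect_lt(loss_bi_tempered(b, 0.8, 1.2), 1e-4)
})

test_that("bi-tempered single pixel matches a from-scratch evaluation", {
  a <- c(1, 0, -1)
  t1 <- 0.8; t2 <- 1.2
  y <- oracle_tempered_softmax(a, t2)
  tlog <- function(x) (x^(1 - t1) - 1) / (1 - t1)
  manual <- (tlog(1) - tlog(y[1])) - (1 - y[1]^(2 - t1)) / (2 - t1) +
    sum(y[2:3]^(2 - t1)) / (2 - t1)
  b <- pixel_batch(activations = matrix(a, 1), targets = 0L)
  expect_equal(loss_bi_tempered(b, t1, t2, tol = 1e-12, max_iter = 200),
               manual, tolerance = 1e-8)
})

test_that("Lovasz gradient matches prefix Jaccard differences", {
  expect_equal(lovasz_gradient(1), 1)
  expect_equal(lovasz_gradient(c(1, 0)), c(1, 0))
  expect_error(lovasz_gradient(c(1, 2)), "binary")
  set.seed(9)
  for (i in 1:20) {
    gt <- sample(0:1, 12, replace = TRUE)
    g <- lovasz_gradient(gt)
    # explicit prefix-set oracle: J(S) from set sizes, no cumsum shortcuts
    G <- which(gt == 1)
    J <- function(k) {
      if (k == 0) return(0)                  # J_0 = 0 by convention
      S <- seq_len(k)
      1 - (length(G) - length(intersect(S, G))) / length(union(S, G))
    }
    oracle <- vapply(seq_along(gt), function(k) J(k) - J(k - 1), numeric(1))
    expect_equal(g, oracle, tolerance = 1e-12)
  }
})

test_that("Lovasz-softmax equals the independent extension oracle", {
  expect_equal(
    loss_lovasz_softmax(pixel_batch(diag(3)[c(1, 2, 3), ],
                                    targets = 0:2)), 0)
  for (seed in 1:200) {
    set.seed(seed)
    n <- sample(2:8, 1)
    C <- sample(2:3, 1)
    p <- matrix(runif(n * C), n)
    p <- p / rowSums(p)
    targets <- sample(0:(C - 1L), n, replace = TRUE)
    b <- pixel_batch(p, targets = targets)
    expect_equal(loss_lovasz_softmax(b), oracle_lovasz_softmax(p, targets),
                 tolerance = 1e-8)
  }
})

test_that("Lovasz-softmax on hard predictions equals mean(1 - IoU)", {
  set.seed(31)
  for (i in 1:20) {
    n <- 30
    C <- 3
    pred <- sample(0:(C - 1L), n, replace = TRUE)
    targets <- sample(0:(C - 1L), n, replace = TRUE)
    p <- matrix(0, n, C)
    p[cbind(1:n, pred + 1L)] <- 1
    b <- pixel_batch(p, targets = targets)
    iou_loss <- vapply(0:(C - 1L), function(c) {
      P <- pred == c
      G <- targets == c
      u <- sum(P | G)
      if (u == 0) 0 else 1 - sum(P & G) / u
    }, numeric(1))
    expect_equal(loss_lovasz_softmax(b), mean(iou_loss), tolerance = 1e-10)
  }
})

test_that("all losses are non-negative and zero on exact predictions", {
  C <- 5
  targets <- c(0L, 2L, 4L)
  p <- matrix(0, 3, C)
  p[cbind(1:3, targets + 1L)] <- 1
  a <- matrix(-60, 3, C)
  a[cbind(1:3, targets + 1L)] <- 60
  bp <- pixel_batch(p, targets = targets)
  ba <- pixel_batch(activations = a, targets = targets)
  expect_equal(loss_cross_entropy(bp), 0, tolerance = 1e-10)
  expect_equal(loss_focal(bp), 0, tolerance = 1e-10)
  expect_lt(loss_bi_tempered(ba), 1e-4)
  expect_equal(loss_lovasz_softmax(bp), 0, tolerance = 1e-10)
  for (seed in 1:3) {
    b <- random_prob_batch(50, C, seed)
    expect_gte(loss_cross_entropy(b), 0)
    expect_gte(loss_focal(b), 0)
    expect_gte(loss_lovasz_softmax(b), 0)
    expect_lte(loss_lovasz_softmax(b), 1)
  }
})

test_that("ignored pixels contribute exactly zero to every loss", {
  set.seed(17)
  C <- 6
  p <- matrix(runif(8 * C), 8)
  p <- p / rowSums(p)
  a <- matrix(rnorm(8 * C), 8)
  targets <- sample(0:(C - 1L), 8, replace = TRUE)
  base_p <- pixel_batch(p[1:5, ], targets = targets[1:5])
  base_a <- pixel_batch(activations = a[1:5, ], targets = targets[1:5])
  t2 <- targets
  t2[6:8] <- 255L
  aug_p <- pixel_batch(p, targets = t2)
  aug_a <- pixel_batch(activations = a, targets = t2)
  expect_equal(loss_cross_entropy(aug_p), loss_cross_entropy(base_p))
  expect_equal(loss_focal(aug_p), loss_focal(base_p))
  expect_equal(loss_bi_tempered(aug_a), loss_bi_tempered(base_a))
  expect_equal(loss_lovasz_softmax(aug_p), loss_lovasz_softmax(base_p))
  expect_error(
    loss_cross_entropy(pixel_batch(p, targets = rep(255L, 8))), "empty")
})

test_that("loss configuration validates hyperparameters", {
  expect_error(loss_config("focal", gamma = -1), "gamma")
  expect_error(loss_config("bi_tempered", t1 = 1.2), "t1")
  expect_error(loss_config("bi_tempered", t2 = 0.5), "t2")
  cfg <- loss_config("focal")
  expect_identical(cfg$alpha, 0.25)
  expect_identical(cfg$gamma, 2)
})
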