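test_that("filters double per level and construction is seed-deterministic", {
  spec <- unet_spec(base_filters = 32L, depth = 4L)
  m <- unet_build(spec, seed = 2)
  td <- tidy(m)
  enc_filters <- td$out_channels[match(
    c("enc1_c1", "enc2_c1", "enc3_c1", "enc4_c1", "bott_c1"), td$unit)]
  expect_equal(enc_filters, c(32, 64, 128, 256, 512))
  expect_equal(td$out_channels[td$unit == "head"], 14)
  m2 <- unet_build(spec, seed = 2)
  expect_identical(m$params, m2$params)
  m3 <- unet_build(spec, seed = 3)
  expect_false(identical(m$params, m3$params))
})

test_that("parameter count of the full-size network is stable", {
  # regression value computed once from the frozen layout
  m <- unet_build(unet_spec(3L, 14L, 32L, 4L), seed = 1)
  expect_equal(unet_n_params(m), 10727256)
  expect_equal(unet_n_params(unet_build(unet_spec(3L, 14L, 2L, 1L), 1)),
               842)
})

test_that("forward pass produces aligned, normalized likelihood maps", {
  m <- unet_build(unet_spec(base_filters = 4L, depth = 2L), seed = 5)
  x <- array(runif(32 * 48 * 3), c(32, 48, 3))
  fw <- unet_forward(m, x)
  expect_identical(dim(fw$probabilities), c(32L, 48L, 14L))
  sums <- apply(fw$probabilities, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # constant-zero image: finite, normalized
  fw0 <- unet_forward(m, array(0, c(32, 32, 3)))
  expect_true(all(is.finite(fw0$probabilities)))
  # batched input keeps the batch dimension
  xb <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  expect_identical(dim(unet_forward(m, xb)$probabilities), c(32L, 32L, 14L, 3L))
})

test_that("invalid input geometry is rejected", {
  m <- unet_build(unet_spec(base_filters = 2L, depth = 3L), seed = 1)
  expect_error(unet_forward(m, array(0, c(20, 20, 3))), "divisible")
  expect_error(unet_forward(m, array(0, c(32, 32, 4))), "channels")
})

test_that("permuting the head weights permutes the likelihood channels", {
  m <- unet_build(unet_spec(base_filters = 2L, depth = 1L), seed = 8)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  base <- unet_forward(m, x)$probabilities
  perm <- c(14, 1:13)
  m$params[["head.W"]] <- m$params[["head.W"]][perm, ]
  m$params[["head.b"]] <- m$params[["head.b"]][perm]
  permuted <- unet_forward(m, x)$probabilities
  expect_equal(permuted, base[, , perm], tolerance = 1e-12)
})

test_that("gradient flows to every parameter", {
  set.seed(12)
  m <- unet_build(unet_spec(base_filters = 2L, depth = 2L), seed = 12)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  targets <- sample(0:13, 16 * 16 * 2, replace = TRUE)
  lf <- crcseg:::make_loss(loss_config("cross_entropy"))
  fw <- unet_forward(m, x, training = TRUE)
  r <- lf(t(fw$act_matrix), targets)
  grads <- crcseg:::unet_backward(m, fw$cache, t(r$gradient))
  expect_setequal(names(grads), names(m$params))
  norms <- vapply(grads, function(g) sqrt(sum(g^2)), numeric(1))
  expect_true(all(norms > 0))
})

test_that("whole-network analytic gradients match central differences", {
  set.seed(13)
  m <- unet_build(unet_spec(n_classes = 4L, base_filters = 2L, depth = 2L),
                  seed = 13)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  targets <- sample(0:3, 64, replace = TRUE)
  lf <- crcseg:::make_loss(loss_config("cross_entropy"))
  fw <- unet_forward(m, x, training = TRUE)
  r <- lf(t(fw$act_matrix), targets)
  grads <- crcseg:::unet_backward(m, fw$cache, t(r$gradient))
  loss_of <- function(model) {
    f <- unet_forward(model, x, training = TRUE)
    lf(t(f$act_matrix), targets)$value
  }
  h <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + h
      mm <- m; mm$params[[nm]][i] <- p[i] - h
      num <- (loss_of(mp) - loss_of(mm)) / (2 * h)
      expect_lt(abs(grads[[nm]][i] - num) / max(abs(num), 1e-6), 1e-3)
    }
  }
})
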