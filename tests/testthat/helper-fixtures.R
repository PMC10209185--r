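# Shared fixtures, built in code at test time.

# seeded random probability batch on the simplex
random_prob_batch <- function(n, C, seed, ignore = integer(0),
                              ignore_index = 255L) {
  set.seed(seed)
  p <- matrix(runif(n * C) + 1e-3, n, C)
  p <- p / rowSums(p)
  targets <- sample(0:(C - 1L), n, replace = TRUE)
  targets[ignore] <- ignore_index
  pixel_batch(probabilities = p, targets = targets,
              ignore_index = ignore_index)
}

random_act_batch <- function(n, C, seed, ignore = integer(0),
                             ignore_index = 255L) {
  set.seed(seed)
  a <- matrix(rnorm(n * C), n, C)
  targets <- sample(0:(C - 1L), n, replace = TRUE)
  targets[ignore] <- ignore_index
  pixel_batch(activations = a, targets = targets, ignore_index = ignore_index)
}

# independent evaluation of the Lovasz extension for one class: Jaccard
# loss of explicit prefix sets, no cumsum shortcuts
oracle_lovasz_class <- function(errors, fg) {
  ord <- order(errors, decreasing = TRUE)
  e <- errors[ord]
  g <- fg[ord] == 1
  G <- which(g)
  # Jaccard loss as a function of the ERROR set S: with errors S, the
  # prediction hits |G| - |G n S| of G and adds |S \ G| false positives
  jacc_loss <- function(S) {
    denom <- length(G) + length(setdiff(S, G))
    if (denom == 0) return(0)
    1 - (length(G) - length(intersect(S, G))) / denom
  }
  total <- 0
  prev <- jacc_loss(integer(0))
  for (i in seq_along(e)) {
    cur <- jacc_loss(seq_len(i))
    total <- total + e[i] * (cur - prev)
    prev <- cur
  }
  total
}

oracle_lovasz_softmax <- function(p, targets, C = ncol(p)) {
  terms <- vapply(0:(C - 1L), function(c) {
    fg <- as.numeric(targets == c)
    oracle_lovasz_class(abs(fg - p[, c + 1L]), fg)
  }, numeric(1))
  mean(terms)
}

# bisection oracle for the tempered-softmax normalizer, independent of the
# package's vectorized implementation
oracle_tempered_softmax <- function(a, t2, tol = 1e-12) {
  texp <- function(x) pmax(1 + (1 - t2) * x, 0)^(1 / (1 - t2))
  lo <- max(a)
  hi <- lo + 1
  while (sum(texp(a - hi)) > 1) hi <- hi + (hi - lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(texp(a - mid)) - 1 > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  texp(a - (lo + hi) / 2)
}

# one small trained segmentation model, built once per test run
.fixture_env <- new.env()

fixture_trained <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- segmentation_benchmark(
      loss = loss_config("cross_entropy"), seed = 101L,
      n_train = 60L, n_val = 6L, n_test = 8L,
      epochs = 6L, iters_per_epoch = 25L
    )
  }
  .fixture_env$fit
}

flat_tile <- function(class_index, side = 64L, texture = texture_model()) {
  mask <- matrix(as.integer(class_index), side, side)
  set.seed(7)
  img <- render_texture(mask, texture)
  labeled_tile(img, mask, 1.0)
}
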