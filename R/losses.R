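#' Bundle per-pixel predictions and targets for loss evaluation
#'
#' A pixel batch is the tabular unit the four training objectives operate
#' on: one row per pixel, one column per class. Cross-entropy, focal and
#' Lovasz-softmax losses consume the `probabilities` table (rows on the
#' simplex); the bi-tempered loss consumes raw `activations` because its
#' heavy-tailed softmax is part of the loss itself. Pixels labelled with
#' `ignore_index` are excluded from every loss and contribute exactly zero.
#'
#' @param probabilities Numeric matrix `[n_pixels x C]`, rows summing to 1.
#' @param activations Numeric matrix `[n_pixels x C]` of pre-softmax scores.
#' @param targets Integer vector of 0-based class indices, possibly
#'   `ignore_index`.
#' @param ignore_index Label marking unannotated pixels (default 255).
#' @return A `pixel_batch` object.
#' @export
pixel_batch <- function(probabilities = NULL, activations = NULL, targets,
                        ignore_index = 255L) {
  if (is.null(probabilities) && is.null(activations)) {
    abort("supply `probabilities` and/or `activations`")
  }
  n <- length(targets)
  C <- ncol(probabilities %||% activations)
  for (m in list(probabilities, activations)) {
    if (!is.null(m) && (nrow(m) != n || ncol(m) != C)) {
      abort("probabilities/activations must be [n_pixels x C] matching targets")
    }
  }
  targets <- as.integer(targets)
  valid <- targets != ignore_index
  if (any(targets[valid] < 0L | targets[valid] >= C)) {
    abort("targets must lie in 0..C-1 or equal ignore_index")
  }
  if (!is.null(probabilities)) {
    rs <- rowSums(probabilities[valid, , drop = FALSE])
    if (length(rs) > 0 && any(abs(rs - 1) > 1e-6)) {
      abort("probability rows must sum to 1 (tolerance 1e-6)")
    }
  }
  structure(
    list(probabilities = probabilities, activations = activations,
         targets = targets, valid = valid, n_classes = C,
         ignore_index = as.integer(ignore_index)),
    class = "pixel_batch"
  )
}

check_nonempty <- function(batch) {
  if (!inherits(batch, "pixel_batch")) abort("`batch` must be a pixel_batch")
  if (!any(batch$valid)) abort("empty batch: all pixels carry the ignore label")
  invisible(batch)
}

PROB_CLAMP <- 1e-12

#' Categorical cross-entropy over a pixel batch
#'
#' Mean over valid pixels of `-log p_target`, the multinomial logistic
#' objective. Probabilities are clamped at 1e-12 before the logarithm so a
#' zero-probability target yields a large finite value rather than `Inf`.
#'
#' @param batch A [pixel_batch()] carrying probabilities.
#' @param gradient If `TRUE`, also return the gradient with respect to the
#'   probability table (zero rows for ignored pixels).
#' @return Scalar loss, or `list(value, gradient)` when `gradient = TRUE`.
#' @export
loss_cross_entropy <- function(batch, gradient = FALSE) {
  check_nonempty(batch)
  p <- batch$probabilities
  if (is.null(p)) abort("cross-entropy needs probabilities")
  idx <- which(batch$valid)
  pt <- pmax(p[cbind(idx, batch$targets[idx] + 1L)], PROB_CLAMP)
  value <- mean(-log(pt))
  if (!gradient) return(value)
  g <- matrix(0, nrow(p), ncol(p))
  g[cbind(idx, batch$targets[idx] + 1L)] <- -1 / (pt * length(idx))
  list(value = value, gradient = g)
}

#' Focal loss over a pixel batch
#'
#' Cross-entropy with each pixel's contribution scaled by
#' `alpha * (1 - p_target)^gamma`, down-weighting easy, abundant pixels so
#' rare tissue compartments keep influence. With `gamma = 0, alpha = 1` the
#' focal loss reduces exactly to categorical cross-entropy.
#'
#' @inheritParams loss_cross_entropy
#' @param alpha Global weight (default 0.25, the value recommended by the
#'   loss's authors).
#' @param gamma Focusing exponent `>= 0` (default 2).
#' @export
loss_focal <- function(batch, alpha = 0.25, gamma = 2, gradient = FALSE) {
  check_nonempty(batch)
  if (gamma < 0) abort("gamma must be >= 0")
  p <- batch$probabilities
  if (is.null(p)) abort("focal loss needs probabilities")
  idx <- which(batch$valid)
  pt <- pmax(p[cbind(idx, batch$targets[idx] + 1L)], PROB_CLAMP)
  mod <- (1 - pt)^gamma
  value <- mean(-alpha * mod * log(pt))
  if (!gradient) return(value)
  dmod <- if (gamma == 0) 0 else gamma * (1 - pt)^(gamma - 1)
  dpt <- alpha * (dmod * log(pt) - mod / pt) / length(idx)
  g <- matrix(0, nrow(p), ncol(p))
  g[cbind(idx, batch$targets[idx] + 1L)] <- dpt
  list(value = value, gradient = g)
}

#' Tempered logarithm and exponential
#'
#' Heavy-tailed one-parameter generalizations of `log` and `exp`:
#' `log_t(x) = (x^(1-t) - 1) / (1 - t)` and
#' `exp_t(x) = max(1 + (1-t) x, 0)^(1/(1-t))`, recovering the natural
#' functions continuously at `t = 1`. They are inverses on their ranges.
#'
#' @param x Numeric vector (`x > 0` for `tempered_log`).
#' @param t Temperature.
#' @return Numeric vector.
#' @export
tempered_log <- function(x, t) {
  if (any(x <= 0)) abort("tempered_log requires x > 0")
  if (abs(t - 1) < 1e-12) return(log(x))
  (x^(1 - t) - 1) / (1 - t)
}

#' @rdname tempered_log
#' @export
tempered_exp <- function(x, t) {
  if (abs(t - 1) < 1e-12) return(exp(x))
  pmax(1 + (1 - t) * x, 0)^(1 / (1 - t))
}

softmax_rows <- function(a) {
  z <- exp(a - apply(a, 1, max))
  z / rowSums(z)
}

#' Tempered softmax: a heavy-tailed probability mapping
#'
#' Maps activations to probabilities via
#' `y_j = exp_t2(a_j - lambda(a))`, where the normalizer `lambda` is the
#' unique value making the row sum to one. For `t2 = 1` this is the ordinary
#' softmax; for `t2 > 1` the tails are polynomial rather than exponential,
#' which bounds the loss contribution of far-off-margin (noisy) pixels.
#' `lambda` is found by bisection on the monotone-decreasing residual
#' `sum(exp_t2(a - lambda)) - 1`, which converges unconditionally.
#'
#' @param activations Numeric vector of length C, or matrix `[n x C]` (one
#'   distribution per row).
#' @param t2 Tail temperature `>= 1`.
#' @param tol Residual tolerance for the normalizer (default 1e-9).
#' @param max_iter Bisection iteration cap.
#' @return Probability vector/matrix matching the input shape.
#' @export
tempered_softmax <- function(activations, t2, tol = 1e-9, max_iter = 100L) {
  vec <- is.null(dim(activations))
  a <- if (vec) matrix(activations, nrow = 1) else activations
  if (any(!is.finite(a))) abort("activations must be finite")
  if (t2 < 1) abort("t2 must be >= 1")
  if (abs(t2 - 1) < 1e-12) {
    p <- softmax_rows(a)
    return(if (vec) p[1, ] else p)
  }
  # bisection, vectorized over rows
  lo <- apply(a, 1, max)            # residual >= 0 here
  step <- rep(1, nrow(a))
  hi <- lo + step
  resid_at <- function(lam) rowSums(tempered_exp(a - lam, t2)) - 1
  for (k in seq_len(60)) {
    bad <- resid_at(hi) > 0
    if (!any(bad)) break
    step[bad] <- step[bad] * 2
    hi[bad] <- lo[bad] + step[bad]
  }
  lam <- (lo + hi) / 2
  for (k in seq_len(max_iter)) {
    r <- resid_at(lam)
    if (all(abs(r) <= tol)) break
    up <- r > 0
    lo[up] <- lam[up]
    hi[!up] <- lam[!up]
    lam <- (lo + hi) / 2
  }
  r <- resid_at(lam)
  if (any(abs(r) > tol)) {
    abort(sprintf(
      "tempered softmax normalizer did not converge: max residual %.3e",
      max(abs(r))))
  }
  p <- tempered_exp(a - lam, t2)
  if (vec) p[1, ] else p
}

#' Bi-tempered logistic loss over a pixel batch
#'
#' Robust generalization of cross-entropy with two temperatures: `t1 < 1`
#' bounds the loss (entropy tempering), `t2 > 1` fattens the softmax tails.
#' For a one-hot target t the per-pixel loss is
#' `-log_t1(y_t) - (1 - sum_i y_i^(2-t1)) / (2 - t1)`,
#' with `y` the tempered softmax of the activations. At `t1 = t2 = 1` the
#' ordinary softmax cross-entropy is recovered.
#'
#' @inheritParams loss_cross_entropy
#' @param t1 Entropy temperature in `(0, 1]` (default 0.8).
#' @param t2 Tail temperature `>= 1` (default 1.2).
#' @param tol,max_iter Normalizer controls, see [tempered_softmax()].
#' @return Scalar loss, or `list(value, gradient)` with the gradient taken
#'   with respect to the activations.
#' @export
loss_bi_tempered <- function(batch, t1 = 0.8, t2 = 1.2, tol = 1e-9,
                             max_iter = 100L, gradient = FALSE) {
  check_nonempty(batch)
  if (t1 <= 0 || t1 > 1) abort("t1 must lie in (0, 1]")
  a <- batch$activations
  if (is.null(a)) abort("bi-tempered loss consumes activations")
  idx <- which(batch$valid)
  av <- a[idx, , drop = FALSE]
  y <- tempered_softmax(av, t2, tol, max_iter)
  tcols <- cbind(seq_along(idx), batch$targets[idx] + 1L)
  yt <- pmax(y[tcols], PROB_CLAMP)
  per <- -tempered_log(yt, t1) -
    (1 - rowSums(pmax(y, 0)^(2 - t1))) / (2 - t1)
  value <- mean(per)
  if (!gradient) return(value)
  yc <- pmax(y, PROB_CLAMP)
  dLdy <- yc^(1 - t1)                      # from + y^(2-t1)/(2-t1) term
  dLdy[tcols] <- dLdy[tcols] - yc[tcols]^(-t1)  # from -log_t1(y_t)
  w <- yc^t2                               # d exp_t2(u)/du = exp_t2(u)^t2
  gv <- dLdy * w
  lam_grad <- w / rowSums(w)
  gv <- gv - rowSums(gv) * lam_grad
  g <- matrix(0, nrow(a), ncol(a))
  g[idx, ] <- gv / length(idx)
  list(value = value, gradient = g)
}

#' Lovasz gradient of the Jaccard loss
#'
#' Given ground-truth membership of pixels sorted by decreasing prediction
#' error, returns the vector of first differences of the Jaccard loss of
#' successive prefixes. This is the gradient of the Lovasz extension of the
#' Jaccard set-loss; its dot product with the sorted error vector is the
#' extension's value.
#'
#' @param sorted_gt Binary (0/1) vector, sorted by descending error.
#' @return Numeric weight vector of the same length; sums to the Jaccard
#'   loss of the full prefix.
#' @export
lovasz_gradient <- function(sorted_gt) {
  if (length(sorted_gt) < 1) abort("need at least one pixel")
  if (!all(sorted_gt %in% c(0, 1))) abort("sorted_gt must be binary")
  gts <- sum(sorted_gt)
  inter <- gts - cumsum(sorted_gt)
  union <- gts + cumsum(1 - sorted_gt)
  jacc <- 1 - inter / union
  diff(c(0, jacc))
}

#' Lovasz-softmax loss over a pixel batch
#'
#' Differentiable surrogate of `1 - mean IoU`. Per class c, pixel errors
#' `|1[y = c] - p_c|` are sorted in decreasing order and weighted by the
#' [lovasz_gradient()] of the ground truth in that order; the loss is the
#' mean over classes of the weighted error sums. On hard 0/1 predictions the
#' per-class term equals `1 - IoU` exactly. By default all C classes are
#' averaged; `classes = "present"` restricts to classes occurring in the
#' targets.
#'
#' @inheritParams loss_cross_entropy
#' @param classes `"all"` (default) or `"present"`.
#' @return Scalar in `[0, 1]`, or `list(value, gradient)` with the gradient
#'   with respect to the probability table.
#' @export
loss_lovasz_softmax <- function(batch, classes = c("all", "present"),
                                gradient = FALSE) {
  check_nonempty(batch)
  classes <- match.arg(classes)
  p <- batch$probabilities
  if (is.null(p)) abort("Lovasz-softmax needs probabilities")
  idx <- which(batch$valid)
  pv <- p[idx, , drop = FALSE]
  tv <- batch$targets[idx]
  C <- batch$n_classes
  cls <- if (classes == "present") sort(unique(tv)) else 0:(C - 1L)
  g <- if (gradient) matrix(0, nrow(p), ncol(p)) else NULL
  total <- 0
  for (c in cls) {
    fg <- as.numeric(tv == c)
    err <- abs(fg - pv[, c + 1L])
    ord <- order(err, decreasing = TRUE)   # radix sort: stable in pixel index
    lg <- lovasz_gradient(fg[ord])
    total <- total + sum(err[ord] * lg)
    if (gradient) {
      gvec <- numeric(length(err))
      gvec[ord] <- lg
      g[idx, c + 1L] <- ifelse(fg == 1, -1, 1) * gvec / length(cls)
    }
  }
  value <- total / length(cls)
  if (!gradient) return(value)
  list(value = value, gradient = g)
}

#' Configuration of a training objective
#'
#' Bundles the choice of loss and its hyperparameters so a training run is
#' fully described by serializable values. `cross_entropy` ignores all
#' hyperparameters. Defaults for the focal (`alpha = 0.25, gamma = 2`) and
#' bi-tempered (`t1 = 0.8, t2 = 1.2`) losses follow the recommendations of
#' their original authors and are deliberately configuration-exposed.
#'
#' @param kind One of `"cross_entropy"`, `"focal"`, `"bi_tempered"`,
#'   `"lovasz_softmax"`.
#' @param alpha,gamma Focal-loss weight and focusing exponent.
#' @param t1,t2 Bi-tempered temperatures (`t1` in `(0,1]`, `t2 >= 1`).
#' @param lambda_tol,lambda_max_iter Tempered-softmax normalizer controls.
#' @return A `loss_config` object.
#' @export
loss_config <- function(kind = c("cross_entropy", "focal", "bi_tempered",
                                 "lovasz_softmax"),
                        alpha = 0.25, gamma = 2, t1 = 0.8, t2 = 1.2,
                        lambda_tol = 1e-9, lambda_max_iter = 100L) {
  kind <- match.arg(kind)
  if (gamma < 0) abort("gamma must be >= 0")
  if (t1 <= 0 || t1 > 1) abort("t1 must lie in (0, 1]")
  if (t2 < 1) abort("t2 must be >= 1")
  if (lambda_tol <= 0) abort("lambda_tol must be positive")
  structure(
    list(kind = kind, alpha = alpha, gamma = gamma, t1 = t1, t2 = t2,
         lambda_tol = lambda_tol, lambda_max_iter = as.integer(lambda_max_iter)),
    class = "loss_config"
  )
}

#' @export
print.loss_config <- function(x, ...) {
  hp <- switch(x$kind,
    focal = sprintf(" (alpha=%g, gamma=%g)", x$alpha, x$gamma),
    bi_tempered = sprintf(" (t1=%g, t2=%g)", x$t1, x$t2),
    "")
  cat("<loss_config> ", x$kind, hp, "\n", sep = "")
  invisible(x)
}

# Returns f(activations [n x C], targets) -> list(value, gradient w.r.t.
# activations). For probability-space losses the softmax Jacobian is chained
# in here; the bi-tempered loss differentiates through its own normalizer.
make_loss <- function(config, ignore_index = 255L) {
  stopifnot(inherits(config, "loss_config"))
  chain_softmax <- function(p, gp) p * (gp - rowSums(gp * p))
  switch(config$kind,
    cross_entropy = function(act, targets) {
      p <- softmax_rows(act)
      b <- pixel_batch(probabilities = p, targets = targets,
                       ignore_index = ignore_index)
      r <- loss_cross_entropy(b, gradient = TRUE)
      list(value = r$value, gradient = chain_softmax(p, r$gradient))
    },
    focal = function(act, targets) {
      p <- softmax_rows(act)
      b <- pixel_batch(probabilities = p, targets = targets,
                       ignore_index = ignore_index)
      r <- loss_focal(b, alpha = config$alpha, gamma = config$gamma,
                      gradient = TRUE)
      list(value = r$value, gradient = chain_softmax(p, r$gradient))
    },
    bi_tempered = function(act, targets) {
      b <- pixel_batch(activations = act, targets = targets,
                       ignore_index = ignore_index)
      loss_bi_tempered(b, t1 = config$t1, t2 = config$t2,
                       tol = config$lambda_tol,
                       max_iter = config$lambda_max_iter, gradient = TRUE)
    },
    lovasz_softmax = function(act, targets) {
      p <- softmax_rows(act)
      b <- pixel_batch(probabilities = p, targets = targets,
                       ignore_index = ignore_index)
      r <- loss_lovasz_softmax(b, gradient = TRUE)
      list(value = r$value, gradient = chain_softmax(p, r$gradient))
    }
  )
}
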