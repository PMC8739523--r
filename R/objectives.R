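# Compound segmentation objective: soft Dice + pixel-wise cross-entropy.
# Core routines return both the value and the gradient with respect to the
# probability map so that training can reuse them on the autodiff tape;
# the exported functions expose the values only.

CE_CLAMP <- 1e-12

#' One-hot encode a label mask
#'
#' @param mask integer matrix (`H x W`) or array (`H x W x N`) of class
#'   labels in `0 .. num_classes - 1`.
#' @param num_classes number of classes.
#' @return Array `H x W x N x num_classes` of 0/1 indicator values.
#' @export
one_hot <- function(mask, num_classes) {
  mask <- as_feature_array(mask)[, , , 1, drop = FALSE]
  d <- dim(mask)
  if (any(mask < 0 | mask > num_classes - 1L)) {
    stop("labels outside 0..", num_classes - 1L)
  }
  out <- array(0, c(d[1], d[2], d[3], num_classes))
  for (cc in 0:(num_classes - 1L)) {
    out[, , , cc + 1L] <- as.numeric(mask[, , , 1] == cc)
  }
  out
}

check_loss_extents <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) {
    stop("prediction and target extents differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
  }
}

# binary <=> single-channel map under the Bernoulli two-term form
ce_core <- function(pred, target) {
  d <- dim(pred)
  npix <- prod(d[1:3])
  if (d[4] == 1L) {
    p <- pmin(pmax(pred, CE_CLAMP), 1 - CE_CLAMP)
    value <- -sum(target * log(p) + (1 - target) * log(1 - p)) / npix
    grad <- -(target / p - (1 - target) / (1 - p)) / npix
  } else {
    p <- pmax(pred, CE_CLAMP)
    value <- -sum(target * log(p)) / npix
    grad <- -(target / p) / npix
  }
  list(value = value, grad = grad)
}

dice_core <- function(pred, target, smooth = 1e-5, include_background = TRUE) {
  d <- dim(pred)
  k <- d[4]
  classes <- if (k == 1L || include_background) seq_len(k) else 2:k
  nk <- length(classes)
  grad <- array(0, d)
  total <- 0
  for (cc in classes) {
    p <- pred[, , , cc]
    y <- target[, , , cc]
    inter <- sum(p * y)
    denom <- sum(y) + sum(p) + smooth
    dice_c <- (2 * inter + smooth) / denom
    total <- total + dice_c
    # d/dp of -(1/nk) * (2*inter + smooth)/denom
    grad[, , , cc] <- -(2 * y * denom - (2 * inter + smooth)) / (nk * denom^2)
  }
  list(value = 1 - total / nk, grad = grad)
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over all pixels (and batch) of \eqn{-\sum_c Y_c \log Y'_c}; for a
#' single-channel map the two-term Bernoulli form is used.  Probabilities
#' are clamped at 1e-12 before the logarithm.
#'
#' @param pred probability array `H x W x N x C` (per-pixel class
#'   probabilities, e.g. from [forward()]).
#' @param target one-hot array of the same extents (see [one_hot()]).
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, target) {
  pred <- as_feature_array(pred); target <- as_feature_array(target)
  check_loss_extents(pred, target)
  ce_core(pred, target)$value
}

#' Soft Dice loss
#'
#' \deqn{L_{Dice} = 1 - \frac{1}{k}\sum_{c=0}^{k-1}
#'   \frac{2\sum Y_c Y'_c + \xi}{\sum Y_c + \sum Y'_c + \xi}}
#' with sums over every pixel of the batch and a small smoothing constant
#' \eqn{\xi} guarding the divisor.  The class average includes the
#' background class by default (the printed summation bounds run from
#' class 0); set `include_background = FALSE` to average foreground classes
#' only.  Computed on soft probabilities, so it is differentiable.
#'
#' @inheritParams cross_entropy_loss
#' @param smooth the smoothing constant \eqn{\xi} (default 1e-5).
#' @param include_background include class 0 in the class average.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1e-5, include_background = TRUE) {
  stopifnot(smooth > 0)
  pred <- as_feature_array(pred); target <- as_feature_array(target)
  check_loss_extents(pred, target)
  dice_core(pred, target, smooth, include_background)$value
}

#' Compound training loss: Dice + cross-entropy
#'
#' @inheritParams dice_loss
#' @return `dice_loss(pred, target) + cross_entropy_loss(pred, target)`.
#' @export
total_loss <- function(pred, target, smooth = 1e-5, include_background = TRUE) {
  dice_loss(pred, target, smooth, include_background) +
    cross_entropy_loss(pred, target)
}

# tape op: attaches the compound loss to a probability node; returns the
# scalar loss node plus the component values for logging
op_total_loss <- function(prob_node, target, smooth = 1e-5,
                          include_background = TRUE) {
  pred <- prob_node$val
  check_loss_extents(pred, target)
  ce <- ce_core(pred, target)
  di <- dice_core(pred, target, smooth, include_background)
  nd <- tape_node(prob_node$tape, ce$value + di$value, function(g) {
    node_accum(prob_node, g * (ce$grad + di$grad))
  })
  list(node = nd, ce = ce$value, dice = di$value)
}
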