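#' Pixel-wise cross-entropy loss
#'
#' `-(1/N) * sum_i sum_c I[i,c] * log(B[i,c])` with `N` the pixel count,
#' `I` the one-hot ground-truth indicator and `B` the predicted
#' probability.  The log is clamped below at `clamp` for a numerical
#' floor.
#'
#' @param gt 2D integer label matrix with classes in `0..C-1`.
#' @param pred `(H, W, C)` probability array (channels sum to 1).
#' @param clamp lower clamp applied inside the log.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(gt, pred, clamp = 1e-12) {
  C <- dim(pred)[3]
  check_gt_pred(gt, pred)
  g <- one_hot(gt, C)
  -sum(g * log(pmax(pred, clamp))) / (nrow(gt) * ncol(gt))
}

#' Soft dice loss
#'
#' `1 - mean_c Dice_c`, where per-class dice uses the overlap formula
#' `2|A n B| / (|A| + |B|)` with probabilities in place of binary
#' membership and a smoothing epsilon in numerator and denominator.
#' Averaged with equal weight over all classes (background included) by
#' default; `weights` reweights classes.
#'
#' @param gt 2D integer label matrix.
#' @param pred `(H, W, C)` probability array.
#' @param eps smoothing epsilon.
#' @param weights optional length-C nonnegative class weights (normalized
#'   internally).
#' @return scalar in \[0, 1\] (up to epsilon effects), with attribute
#'   `per_class` holding the per-class dice loss `1 - Dice_c`.
#' @export
dice_loss <- function(gt, pred, eps = 1e-6, weights = NULL) {
  C <- dim(pred)[3]
  check_gt_pred(gt, pred)
  g <- one_hot(gt, C)
  num <- den <- numeric(C)
  for (c in seq_len(C)) {
    num[c] <- 2 * sum(pred[, , c] * g[, , c]) + eps
    den[c] <- sum(pred[, , c]) + sum(g[, , c]) + eps
  }
  per_class <- 1 - num / den
  if (is.null(weights)) weights <- rep(1, C)
  stopifnot(length(weights) == C, all(weights >= 0), sum(weights) > 0)
  structure(sum(per_class * weights) / sum(weights), per_class = per_class)
}

#' Hybrid segmentation loss
#'
#' The linear sum of cross-entropy and soft dice loss on one mask.
#'
#' @inheritParams dice_loss
#' @return scalar with attributes `ce` and `dice`.
#' @export
hybrid_loss <- function(gt, pred, eps = 1e-6, weights = NULL) {
  ce <- cross_entropy(gt, pred)
  dc <- dice_loss(gt, pred, eps = eps, weights = weights)
  structure(ce + as.numeric(dc), ce = ce, dice = as.numeric(dc))
}

#' Deep-supervision total loss
#'
#' Unweighted sum of the hybrid loss over the supervised masks (main,
#' auxiliary 1, auxiliary 2, refined).  NULL masks (disabled by ablation
#' flags) are skipped.
#'
#' @param gt 2D integer label matrix.
#' @param mask_main,mask_aux1,mask_aux2,mask_refined `(H, W, C)`
#'   probability arrays or NULL.
#' @param weights optional per-class weights passed to [dice_loss()].
#' @return scalar with attribute `breakdown`, a data.frame of per-mask
#'   CE/dice/hybrid terms.
#' @export
total_loss <- function(gt, mask_main, mask_aux1 = NULL, mask_aux2 = NULL,
                       mask_refined = NULL, weights = NULL) {
  masks <- list(main = mask_main, aux1 = mask_aux1, aux2 = mask_aux2,
                refined = mask_refined)
  masks <- masks[!vapply(masks, is.null, TRUE)]
  terms <- lapply(masks, function(m) hybrid_loss(gt, m, weights = weights))
  breakdown <- data.frame(
    mask = names(terms),
    ce = vapply(terms, function(t) attr(t, "ce"), 0),
    dice = vapply(terms, function(t) attr(t, "dice"), 0),
    hybrid = vapply(terms, as.numeric, 0),
    row.names = NULL)
  structure(sum(breakdown$hybrid), breakdown = breakdown)
}

check_gt_pred <- function(gt, pred) {
  stopifnot(length(dim(pred)) == 3,
            all(dim(pred)[1:2] == dim(gt)),
            all(gt >= 0), all(gt < dim(pred)[3]))
  invisible(TRUE)
}

# Gradient of the hybrid loss with respect to the probability mask.
# d(CE)/dp = -g / (N * max(p, clamp)) on the true-class channel;
# d(Dice_c)/dp_c = (2 g den_c - num_c) / den_c^2 per pixel, scaled by the
# class weight.
hybrid_loss_grad_probs <- function(gt, pred, eps = 1e-6, clamp = 1e-12,
                                   weights = NULL) {
  hybrid_loss_with_grad(gt, pred, eps, clamp, weights)$grad
}

# Loss value (with CE/dice breakdown) and gradient in one pass, shared
# by the training step.
hybrid_loss_with_grad <- function(gt, pred, eps = 1e-6, clamp = 1e-12,
                                  weights = NULL) {
  C <- dim(pred)[3]
  g <- one_hot(gt, C)
  npix <- nrow(gt) * ncol(gt)
  if (is.null(weights)) weights <- rep(1, C)
  wsum <- sum(weights)
  dp <- array(0, dim = dim(pred))
  ce <- 0
  dice <- 0
  for (c in seq_len(C)) {
    pc <- pred[, , c]; gc <- g[, , c]
    pclamp <- pmax(pc, clamp)
    num <- 2 * sum(pc * gc) + eps
    den <- sum(pc) + sum(gc) + eps
    ce <- ce - sum(gc * log(pclamp)) / npix
    dice <- dice + (weights[c] / wsum) * (1 - num / den)
    dp[, , c] <- -gc / (npix * pclamp) -
      (weights[c] / wsum) * (2 * gc * den - num) / den^2
  }
  list(ce = ce, dice = dice, loss = ce + dice, grad = dp)
}
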