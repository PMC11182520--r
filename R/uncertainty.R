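#' Binarize a probability mask
#'
#' One-hot of the per-pixel argmax over channels; ties are broken toward
#' the lower class index.
#'
#' @param mask `(H, W, C)` probability array.
#' @return `(H, W, C)` binary array, one-hot across channels per pixel.
#' @export
binarize_mask <- function(mask) {
  d <- dim(mask)
  m <- matrix(mask, d[1] * d[2], d[3])
  winner <- max.col(m, ties.method = "first")
  out <- matrix(0, d[1] * d[2], d[3])
  out[cbind(seq_along(winner), winner)] <- 1
  array(out, dim = d)
}

#' Union of decoder masks
#'
#' Per-class elementwise OR over any number of binary mask arrays: the
#' region at least one decoder assigns to a class (agreement plus
#' disagreement).
#'
#' @param ... binary `(H, W, C)` arrays of identical shape.
#' @return binary array of the same shape.
#' @export
mask_union <- function(...) {
  masks <- check_same_shape(...)
  Reduce(pmax, masks)
}

#' Intersection of decoder masks
#'
#' Per-class elementwise AND: the region every decoder assigns to a class
#' (agreement only).
#'
#' @inheritParams mask_union
#' @return binary array of the same shape.
#' @export
mask_intersection <- function(...) {
  masks <- check_same_shape(...)
  Reduce(pmin, masks)
}

#' Disagreement region
#'
#' Elementwise difference union minus intersection: 1 exactly where the
#' decoders do not vote unanimously for a class.
#'
#' @param mask_all union of the decoder masks.
#' @param mask_common intersection of the decoder masks.
#' @return binary array of the same shape.
#' @export
disagreement <- function(mask_all, mask_common) {
  stopifnot(all(dim(mask_all) == dim(mask_common)))
  if (any(mask_common > mask_all)) {
    stop("mask_common exceeds mask_all; inputs are not a union/intersection pair")
  }
  mask_all - mask_common
}

#' Uncertainty map
#'
#' The disagreement indicator weighted elementwise by the main decoder's
#' softmax probabilities, localizing how confident the main decoder is
#' inside the contested region.  Zero wherever the decoders agree.
#'
#' @param dis binary disagreement array.
#' @param mask_main `(H, W, C)` probability array of the main decoder.
#' @return `(H, W, C)` real array in \[0, 1\].
#' @export
uncertainty_map <- function(dis, mask_main) {
  stopifnot(all(dim(dis) == dim(mask_main)))
  dis * mask_main
}

#' Full uncertainty pipeline from decoder probability masks
#'
#' Binarizes each decoder's probability mask by argmax, applies the
#' Boolean union/intersection/difference algebra per class, then weights
#' the disagreement by the main decoder's continuous probabilities.
#'
#' @param mask_main main decoder probability mask `(H, W, C)`.
#' @param ... auxiliary decoder probability masks (at least one).
#' @return list with `disagreement` and `uncertainty` arrays.
#' @export
compute_uncertainty <- function(mask_main, ...) {
  aux <- list(...)
  stopifnot(length(aux) >= 1)
  bins <- lapply(c(list(mask_main), aux), binarize_mask)
  all_m <- do.call(mask_union, bins)
  common <- do.call(mask_intersection, bins)
  dis <- disagreement(all_m, common)
  list(disagreement = dis, uncertainty = uncertainty_map(dis, mask_main))
}

check_same_shape <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 2)
  d <- dim(masks[[1]])
  for (m in masks[-1]) {
    if (!all(dim(m) == d)) stop("mask shape mismatch")
  }
  masks
}

#' Fraction of uncertainty mass near the predicted boundary
#'
#' Diagnostic used to check that uncertainty concentrates where it
#' should: computes the fraction of total uncertainty-map mass lying
#' within `radius` pixels (Euclidean) of the predicted class boundary
#' (pixels whose label differs from a 4-neighbour).
#'
#' @param unc `(H, W, C)` uncertainty array.
#' @param labels 2D predicted label matrix.
#' @param radius distance in pixels.
#' @return scalar in \[0, 1\]; NA when the uncertainty map is all zero.
#' @export
uncertainty_boundary_fraction <- function(unc, labels, radius = 3) {
  H <- nrow(labels); W <- ncol(labels)
  diff_any <- matrix(FALSE, H, W)
  diff_any[-H, ] <- diff_any[-H, ] | labels[-H, ] != labels[-1, ]
  diff_any[-1, ] <- diff_any[-1, ] | labels[-1, ] != labels[-H, ]
  diff_any[, -W] <- diff_any[, -W] | labels[, -W] != labels[, -1]
  diff_any[, -1] <- diff_any[, -1] | labels[, -1] != labels[, -W]
  total <- sum(unc)
  if (total == 0) return(NA_real_)
  if (!any(diff_any)) return(0)
  bnd <- which(diff_any, arr.ind = TRUE)
  mass2d <- apply(unc, c(1, 2), sum)
  pts <- which(mass2d > 0, arr.ind = TRUE)
  near <- .cpp_near_boundary(pts[, 1], pts[, 2], bnd[, 1], bnd[, 2], radius)
  sum(mass2d[pts[near, , drop = FALSE]]) / total
}
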