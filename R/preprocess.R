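#' CT intensity window
#'
#' @param level window centre in HU.
#' @param width window width in HU (> 0).  The defaults (level 30,
#'   width 400) map the soft-tissue interval \[-170, 230\] HU onto
#'   \[0, 1\].
#' @return list of class `window_spec`.
#' @export
window_spec <- function(level = 30, width = 400) {
  stopifnot(width > 0)
  structure(list(level = level, width = width), class = "window_spec")
}

#' Apply an intensity window
#'
#' Affine map of `[level - width/2, level + width/2]` onto `[0, 1]`,
#' clamped outside: `out = clip((hu - (level - width/2)) / width, 0, 1)`.
#' Monotone non-decreasing in HU.
#'
#' @param volume array of HU intensities (any shape), finite.
#' @param spec a [window_spec()].
#' @return array of the same shape with values in \[0, 1\].
#' @export
apply_window <- function(volume, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), all(is.finite(volume)))
  pmin(pmax((volume - (spec$level - spec$width / 2)) / spec$width, 0), 1)
}

#' Crop a slice to the body region
#'
#' Finds the largest connected component of above-threshold pixels in a
#' windowed slice (the patient's body), takes its bounding box dilated by
#' a margin, and applies the identical box to the label slice.  Separate
#' small structures such as the scanner couch fall outside the box.  The
#' box is returned so predictions can be mapped back to the original
#' geometry.
#'
#' @param image 2D windowed slice in \[0, 1\].
#' @param labels 2D integer label slice of the same shape (optional).
#' @param threshold body threshold on the windowed intensity.
#' @param margin bounding-box dilation in pixels.
#' @return list with `image`, `labels`, `box` (`c(r0, r1, c0, c1)`, 1-based
#'   inclusive), `full_size` and `empty` (TRUE when no foreground was found
#'   and the slice was returned unchanged).
#' @export
crop_body <- function(image, labels = NULL, threshold = 0.05, margin = 5L) {
  stopifnot(is.matrix(image))
  if (!is.null(labels)) stopifnot(all(dim(labels) == dim(image)))
  H <- nrow(image); W <- ncol(image)
  mask <- image > threshold
  if (!any(mask)) {
    return(list(image = image, labels = labels,
                box = c(1L, H, 1L, W), full_size = c(H, W), empty = TRUE))
  }
  comp <- EBImage::bwlabel(matrix(as.numeric(mask), H, W))
  sizes <- tabulate(comp[comp > 0])
  largest <- which.max(sizes)
  keep <- comp == largest
  rows <- range(which(apply(keep, 1, any)))
  cols <- range(which(apply(keep, 2, any)))
  box <- c(max(1L, rows[1] - margin), min(H, rows[2] + margin),
           max(1L, cols[1] - margin), min(W, cols[2] + margin))
  list(image = image[box[1]:box[2], box[3]:box[4], drop = FALSE],
       labels = if (!is.null(labels))
         labels[box[1]:box[2], box[3]:box[4], drop = FALSE],
       box = as.integer(box), full_size = c(H, W), empty = FALSE)
}

#' Undo a body crop
#'
#' Places a (possibly resized) label slice back into the original frame.
#'
#' @param labels 2D integer labels on the cropped grid (any size; resized
#'   to the box by nearest neighbour first).
#' @param box,full_size as returned by [crop_body()].
#' @param fill background value outside the box.
#' @return 2D integer labels on the original `full_size` grid.
#' @export
uncrop_labels <- function(labels, box, full_size, fill = 0L) {
  bh <- box[2] - box[1] + 1L; bw <- box[4] - box[3] + 1L
  if (!all(dim(labels) == c(bh, bw))) {
    labels <- resize_nearest(labels, c(bh, bw))
  }
  out <- matrix(as.integer(fill), full_size[1], full_size[2])
  out[box[1]:box[2], box[3]:box[4]] <- labels
  out
}

# Nearest-neighbour resize of a 2D matrix (used for label maps; the label
# set can never grow).
resize_nearest <- function(x, target) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(round((seq_len(target[1]) - 0.5) * H / target[1] + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(target[2]) - 0.5) * W / target[2] + 0.5), 1), W)
  x[ri, ci, drop = FALSE]
}

#' Resize an image/label pair
#'
#' The image is interpolated bilinearly; labels are resampled by nearest
#' neighbour so no new label values can appear.
#'
#' @param image 2D real matrix.
#' @param labels 2D integer matrix of the same shape (optional).
#' @param target `c(H, W)` output size, positive.
#' @return list with `image` and `labels`.
#' @export
resize_pair <- function(image, labels = NULL, target) {
  stopifnot(length(target) == 2, all(target >= 1))
  target <- as.integer(target)
  img <- .cpp_resize_bl_fwd(as_cube(image), target[1], target[2])[, , 1]
  lab <- if (!is.null(labels)) {
    stopifnot(all(dim(labels) == dim(image)))
    resize_nearest(labels, target)
  }
  list(image = img, labels = lab)
}

# Rotate a 2D matrix about its centre by `degrees`.  mode "bilinear" for
# images, "nearest" for labels; out-of-frame samples get `fill`.
rotate_matrix <- function(x, degrees, mode = c("bilinear", "nearest"),
                          fill = 0) {
  mode <- match.arg(mode)
  H <- nrow(x); W <- ncol(x)
  th <- degrees * pi / 180
  cs <- cos(th); sn <- sin(th)
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  ii <- matrix(seq_len(H), H, W) - ci
  jj <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  # inverse rotation of the output grid into the source frame
  si <- cs * ii + sn * jj + ci
  sj <- -sn * ii + cs * jj + cj
  if (mode == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    out <- matrix(fill, H, W)
    out[ok] <- x[cbind(ri[ok], rj[ok])]
    storage.mode(out) <- storage.mode(x)
    return(out)
  }
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  out <- matrix(0, H, W)
  wsum <- matrix(0, H, W)
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    pi_ <- i0 + d[1]; pj_ <- j0 + d[2]
    w <- (if (d[1] == 0) 1 - wi else wi) * (if (d[2] == 0) 1 - wj else wj)
    ok <- pi_ >= 1 & pi_ <= H & pj_ >= 1 & pj_ <= W
    out[ok] <- out[ok] + w[ok] * x[cbind(pi_[ok], pj_[ok])]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  out[wsum == 0] <- fill
  inside <- wsum > 0 & wsum < 1
  out[inside] <- out[inside] + (1 - wsum[inside]) * fill
  out
}

#' Randomly augment a slice sample
#'
#' Applies the same geometric transform — rotation, random crop, zero
#' padding back to size — to image and labels.  The image is interpolated
#' bilinearly, labels by nearest neighbour, so augmentation never
#' introduces label values outside the input's label set.  Deterministic
#' given the seed.
#'
#' @param sample list with `image` (2D, \[0, 1\]) and `labels` (2D integer).
#' @param seed integer seed.
#' @param max_rotation maximal |rotation| in degrees.
#' @param max_crop maximal cropped fraction per axis, in \[0, 1).
#' @return a sample list of the same shape with `image` and `labels`
#'   transformed identically.
#' @export
augment_sample <- function(sample, seed, max_rotation = 15, max_crop = 0.10) {
  stopifnot(all(dim(sample$image) == dim(sample$labels)))
  H <- nrow(sample$image); W <- ncol(sample$image)
  with_seed(seed, {
    ang <- runif(1, -max_rotation, max_rotation)
    f <- runif(1, 0, max_crop)
    ch <- max(1L, round((1 - f) * H)); cw <- max(1L, round((1 - f) * W))
    r0 <- sample.int(H - ch + 1L, 1L); c0 <- sample.int(W - cw + 1L, 1L)
    pr <- sample.int(H - ch + 1L, 1L); pc <- sample.int(W - cw + 1L, 1L)

    img <- rotate_matrix(sample$image, ang, "bilinear", fill = 0)
    lab <- rotate_matrix(sample$labels, ang, "nearest", fill = 0L)
    img <- img[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
    lab <- lab[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
    out_img <- matrix(0, H, W)
    out_lab <- matrix(0L, H, W)
    out_img[pr:(pr + ch - 1L), pc:(pc + cw - 1L)] <- img
    out_lab[pr:(pr + ch - 1L), pc:(pc + cw - 1L)] <- lab
    res <- sample
    res$image <- out_img
    res$labels <- out_lab
    res
  })
}

#' Preprocess a volume into network-ready slice samples
#'
#' Windows the whole volume, then per axial slice: crops to the body and
#' resizes to the working size.  The per-slice geometry (crop box,
#' original size) is recorded so predictions can be mapped back.
#'
#' @param volume a `phantom_volume` or list with `image` and optionally
#'   `labels` (`H x W x S` arrays).
#' @param spec a [window_spec()].
#' @param target working size `c(H, W)`; must be divisible by
#'   `2^(depth-1)` of the network it feeds.
#' @param crop apply body cropping (disable for pre-cropped data).
#' @return list of slice samples, each with `image`, `labels` (or NULL),
#'   `geom` (box + full size), and `slice` index.
#' @export
preprocess_volume <- function(volume, spec = window_spec(),
                              target = c(64L, 64L), crop = TRUE) {
  win <- apply_window(volume$image, spec)
  S <- dim(win)[3]
  lapply(seq_len(S), function(s) {
    img <- win[, , s]
    lab <- if (!is.null(volume$labels)) volume$labels[, , s]
    if (crop) {
      cr <- crop_body(img, lab)
    } else {
      cr <- list(image = img, labels = lab,
                 box = c(1L, nrow(img), 1L, ncol(img)),
                 full_size = dim(img), empty = FALSE)
    }
    rs <- resize_pair(cr$image, cr$labels, target)
    list(image = rs$image, labels = rs$labels,
         geom = list(box = cr$box, full_size = cr$full_size,
                     empty = cr$empty),
         slice = s)
  })
}
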