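#' Stack per-slice label masks into a volume
#'
#' Re-assembles 2D predictions into a 3D volume in acquisition order.
#' When per-slice geometry records are given (from
#' [preprocess_volume()]), each slice is first mapped back to its
#' original frame (nearest-neighbour resize into the crop box), so
#' evaluation happens in the original geometry.
#'
#' @param slices ordered list of 2D integer label matrices.
#' @param geoms optional list of geometry records (`box`, `full_size`)
#'   parallel to `slices`.
#' @return `H x W x n_slices` integer array.
#' @export
stack_slices <- function(slices, geoms = NULL) {
  stopifnot(length(slices) >= 1)
  if (!is.null(geoms)) {
    stopifnot(length(geoms) == length(slices))
    slices <- lapply(seq_along(slices), function(i) {
      uncrop_labels(slices[[i]], geoms[[i]]$box, geoms[[i]]$full_size)
    })
  }
  d <- dim(slices[[1]])
  for (s in slices) {
    if (!all(dim(s) == d)) stop("inconsistent slice shapes")
  }
  array(as.integer(unlist(slices, use.names = FALSE)),
        dim = c(d[1], d[2], length(slices)))
}

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)` on binary volumes.  When both volumes are
#' empty the structure is absent from both and the overlap is defined
#' as 1.
#'
#' @param a,b binary (logical or 0/1) arrays of identical shape.
#' @return real in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# Boundary voxels: foreground voxels with at least one face neighbour
# outside the mask (the volume border counts as outside).
boundary_voxels <- function(v) {
  v <- v != 0
  d <- dim(v)
  pad <- array(FALSE, dim = d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- v
  interior <- pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])]
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    interior <- interior & pad[1 + sh[1] + seq_len(d[1]),
                               1 + sh[2] + seq_len(d[2]),
                               1 + sh[3] + seq_len(d[3])]
  }
  which(v & !interior, arr.ind = TRUE)
}

#' Hausdorff distance between two binary volumes
#'
#' Full symmetric Hausdorff distance between the boundary-voxel sets of
#' the two masks: the larger of the two directed max-min boundary
#' distances, scaled per-axis by the voxel spacing.  Units are voxels for
#' unit spacing, physical units otherwise.
#'
#' @param a,b binary arrays of identical shape; 2D inputs are treated as
#'   single-slice volumes.
#' @param spacing positive voxel spacing per axis.
#' @return nonnegative real; `NA` (with a warning) when either mask is
#'   empty, where the boundary distance is undefined.
#' @export
hausdorff_distance <- function(a, b, spacing = c(1, 1, 1)) {
  if (length(dim(a)) == 2L) { dim(a) <- c(dim(a), 1L); dim(b) <- c(dim(b), 1L) }
  stopifnot(all(dim(a) == dim(b)), all(spacing > 0),
            length(spacing) == 3)
  if (sum(a != 0) == 0 || sum(b != 0) == 0) {
    warning("Hausdorff distance undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  ba <- boundary_voxels(a)
  bb <- boundary_voxels(b)
  .cpp_hausdorff_pairs(ba, bb, as.numeric(spacing))
}

#' Per-organ scores across patients
#'
#' Computes per-patient dice and Hausdorff distance for every organ and
#' aggregates to the mean with the population variance across patients.
#' Organs absent from a patient's ground truth are excluded from that
#' organ's aggregate (and reported in `n_patients`).
#'
#' @param preds list of predicted 3D label volumes (integer classes).
#' @param gts list of ground-truth 3D label volumes, parallel to `preds`.
#' @param organ_ids integer class ids to score (default: all foreground
#'   classes present in the ground truth).
#' @param organ_names optional names parallel to `organ_ids`.
#' @param spacing voxel spacing passed to [hausdorff_distance()].
#' @return data.frame with one row per organ: `organ`, `class_id`,
#'   `dice_mean`, `dice_var`, `hd_mean`, `hd_var`, `n_patients`; the
#'   per-patient values are kept in the `per_patient` attribute.
#' @export
score_patients <- function(preds, gts, organ_ids = NULL, organ_names = NULL,
                           spacing = c(1, 1, 1)) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  if (is.null(organ_ids)) {
    organ_ids <- sort(setdiff(unique(unlist(lapply(gts, unique))), 0))
  }
  if (is.null(organ_names)) organ_names <- paste0("organ_", organ_ids)
  pvar <- function(x) mean((x - mean(x))^2)
  rows <- list()
  per_patient <- list()
  for (k in seq_along(organ_ids)) {
    id <- organ_ids[k]
    dices <- hds <- numeric(0)
    for (p in seq_along(preds)) {
      gt_bin <- gts[[p]] == id
      if (!any(gt_bin)) {
        message("organ ", organ_names[k], " absent from ground truth of ",
                "patient ", p, "; excluded")
        next
      }
      pr_bin <- preds[[p]] == id
      dices <- c(dices, dice_coefficient(pr_bin, gt_bin))
      hd <- suppressWarnings(hausdorff_distance(pr_bin, gt_bin, spacing))
      hds <- c(hds, hd)
    }
    hds_ok <- hds[!is.na(hds)]
    rows[[k]] <- data.frame(
      organ = organ_names[k], class_id = id,
      dice_mean = if (length(dices)) mean(dices) else NA_real_,
      dice_var = if (length(dices)) pvar(dices) else NA_real_,
      hd_mean = if (length(hds_ok)) mean(hds_ok) else NA_real_,
      hd_var = if (length(hds_ok)) pvar(hds_ok) else NA_real_,
      n_patients = length(dices))
    per_patient[[organ_names[k]]] <- list(dice = dices, hd = hds)
  }
  out <- do.call(rbind, rows)
  attr(out, "per_patient") <- per_patient
  out
}
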