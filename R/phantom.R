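#' Describe one synthetic organ
#'
#' An organ is a blobby superellipse-like region whose centre drifts
#' smoothly across slices.  Intensities are on a pseudo-Hounsfield scale
#' (air about -1000 HU, soft tissue 0-80 HU) so that CT windowing is
#' exercised meaningfully.
#'
#' @param name organ label used in reports.
#' @param mean_hu mean interior intensity in pseudo-HU.
#' @param delta boundary contrast: |interior mean - surrounding body mean|,
#'   in pseudo-HU.  Must be nonnegative and consistent with `mean_hu`
#'   relative to the body intensity of the phantom it is used in.
#' @param size_frac length-2 range (low, high) of the organ area as a
#'   fraction of the slice area; both in (0, 1).
#' @param jitter amplitude of the angular radius modulation that makes the
#'   outline blobby and slice-varying (0 = perfect ellipse).
#' @param anchor length-2 offset (rows, cols) of the organ centre from the
#'   body centre, as fractions of the slice height/width.
#' @return a list of class `organ_spec`.
#' @export
organ_spec <- function(name, mean_hu, delta, size_frac, jitter = 0.15,
                       anchor = c(0, 0)) {
  stopifnot(length(size_frac) == 2, all(size_frac > 0), all(size_frac < 1),
            size_frac[1] <= size_frac[2], delta >= 0, jitter >= 0)
  structure(list(name = name, mean_hu = mean_hu, delta = delta,
                 size_frac = as.numeric(size_frac), jitter = jitter,
                 anchor = as.numeric(anchor)),
            class = "organ_spec")
}

#' Configuration of the synthetic CT phantom generator
#'
#' The defaults emulate the two canonical difficulty regimes of thoracic
#' organ-at-risk segmentation: one large high-contrast structure
#' (lung-like, contrast far above the noise floor) and one small structure
#' whose boundary contrast is below the acquisition noise (esophagus-like).
#'
#' @param n_slices slices per volume.
#' @param height,width slice dimensions in pixels.
#' @param organ_specs list of [organ_spec()]; foreground class `k`
#'   corresponds to `organ_specs[[k]]`.  Class 0 is background.
#' @param noise_sd standard deviation of additive Gaussian acquisition
#'   noise, pseudo-HU.
#' @param body_mean soft-tissue intensity of the body, pseudo-HU.
#' @param air_hu intensity outside the body, pseudo-HU.
#' @param spacing voxel spacing (3 positive reals, arbitrary units).
#' @param seed integer seed; the generator is pure given the seed.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 20L, height = 64L, width = 64L,
                           organ_specs = list(
                             organ_spec("lung", mean_hu = -760, delta = 800,
                                        size_frac = c(0.06, 0.12),
                                        jitter = 0.15, anchor = c(0, -0.18)),
                             organ_spec("esophagus", mean_hu = 55, delta = 15,
                                        size_frac = c(0.006, 0.02),
                                        jitter = 0.2, anchor = c(0.05, 0.16))),
                           noise_sd = 20, body_mean = 40, air_hu = -1000,
                           spacing = c(1, 1, 1), seed = 0L) {
  stopifnot(n_slices >= 1, height >= 16, width >= 16,
            length(organ_specs) >= 1, noise_sd >= 0, all(spacing > 0))
  for (sp in organ_specs) stopifnot(inherits(sp, "organ_spec"))
  cfg <- structure(list(n_slices = as.integer(n_slices),
                        height = as.integer(height),
                        width = as.integer(width),
                        n_classes = length(organ_specs) + 1L,
                        organ_specs = organ_specs,
                        noise_sd = noise_sd, body_mean = body_mean,
                        air_hu = air_hu, spacing = as.numeric(spacing),
                        seed = as.integer(seed)),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  # organs must be able to coexist: their maximal footprints may not fill
  # the body, and anchored centres must be pairwise separated by more than
  # the sum of maximal radii.
  max_fracs <- vapply(cfg$organ_specs, function(s) s$size_frac[2], 0)
  if (sum(max_fracs) > 0.5) {
    stop("organ size fractions cannot coexist without overlap (sum of ",
         "maxima exceeds 0.5 of the slice)")
  }
  n <- length(cfg$organ_specs)
  if (n > 1) {
    area <- cfg$height * cfg$width
    rmax <- vapply(cfg$organ_specs, function(s) {
      sqrt(s$size_frac[2] * area / pi) * (1 + s$jitter)
    }, 0)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ai <- cfg$organ_specs[[i]]$anchor * c(cfg$height, cfg$width)
        aj <- cfg$organ_specs[[j]]$anchor * c(cfg$height, cfg$width)
        if (sqrt(sum((ai - aj)^2)) <= rmax[i] + rmax[j]) {
          stop("organ anchors too close for their maximal sizes: classes ",
               i, " and ", j, " would overlap")
        }
      }
    }
  }
  invisible(cfg)
}

# Rasterize one blobby organ at a target pixel count.  The radius is
# modulated over angle by two low-order harmonics; the base radius is
# rescaled (a few fixed-point iterations) until the pixel count falls
# inside [lo, hi].
rasterize_blob <- function(height, width, centre, target_px, bounds_px,
                           jitter, harmonics, body) {
  r0 <- sqrt(target_px / pi)
  ii <- matrix(seq_len(height), height, width)
  jj <- matrix(seq_len(width), height, width, byrow = TRUE)
  di <- ii - centre[1]
  dj <- jj - centre[2]
  rad <- sqrt(di^2 + dj^2)
  theta <- atan2(dj, di)
  mod <- 1 + jitter * (harmonics$a1 * sin(theta + harmonics$p1) +
                         0.5 * harmonics$a2 * sin(2 * theta + harmonics$p2))
  for (it in 1:8) {
    mask <- (rad <= r0 * mod) & body
    cnt <- sum(mask)
    if (cnt >= bounds_px[1] && cnt <= bounds_px[2] && cnt > 0) break
    r0 <- r0 * sqrt(target_px / max(cnt, 1))
  }
  mask
}

#' Generate a synthetic CT phantom volume
#'
#' Produces a pseudo-HU image volume and matching integer label volume.
#' Each slice contains an elliptical soft-tissue body on an air background
#' plus the configured organs; organ outlines vary smoothly from slice to
#' slice, and per-slice organ pixel counts are kept inside the configured
#' size-fraction ranges.
#'
#' @param config a [phantom_config()].
#' @return a list of class `phantom_volume` with elements `image` and
#'   `labels` (both `height x width x n_slices` arrays), `spacing`, and
#'   `organ_names`.  Labels are 0 (background) to `n_classes - 1`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$height; W <- config$width; S <- config$n_slices
  with_seed(config$seed, {
    image <- array(config$air_hu, dim = c(H, W, S))
    labels <- array(0L, dim = c(H, W, S))
    body_centre <- c((H + 1) / 2, (W + 1) / 2)
    body_ax <- c(0.42 * H, 0.44 * W) * runif(2, 0.95, 1.0)
    ii <- matrix(seq_len(H), H, W)
    jj <- matrix(seq_len(W), H, W, byrow = TRUE)

    n_org <- length(config$organ_specs)
    # per-volume smooth trajectories: phase/amplitude of centre drift and
    # size oscillation, plus fixed outline harmonics per organ
    traj <- lapply(seq_len(n_org), function(k) {
      list(ph_c = runif(2, 0, 2 * pi), amp_c = runif(2, 0.5, 2.0),
           ph_s = runif(1, 0, 2 * pi),
           harmonics = list(a1 = runif(1, 0.5, 1), p1 = runif(1, 0, 2 * pi),
                            a2 = runif(1, 0.5, 1), p2 = runif(1, 0, 2 * pi)))
    })

    for (s in seq_len(S)) {
      body <- ((ii - body_centre[1]) / body_ax[1])^2 +
        ((jj - body_centre[2]) / body_ax[2])^2 <= 1
      img <- matrix(config$air_hu, H, W)
      img[body] <- config$body_mean
      lab <- matrix(0L, H, W)
      t_s <- 2 * pi * (s - 1) / max(S, 2)
      for (k in seq_len(n_org)) {
        sp <- config$organ_specs[[k]]
        tr <- traj[[k]]
        centre <- body_centre + sp$anchor * c(H, W) +
          tr$amp_c * sin(t_s + tr$ph_c)
        lo <- sp$size_frac[1] * H * W
        hi <- sp$size_frac[2] * H * W
        # keep the target inside the interior 80% of the allowed range so
        # rasterization error cannot push the count outside the bounds
        target <- lo + (hi - lo) * (0.5 + 0.4 * sin(t_s + tr$ph_s))
        mask <- rasterize_blob(H, W, centre, target, c(lo, hi),
                               sp$jitter, tr$harmonics, body & lab == 0L)
        sgn <- if (sp$mean_hu >= config$body_mean) 1 else -1
        img[mask] <- config$body_mean + sgn * sp$delta
        lab[mask] <- k
      }
      if (config$noise_sd > 0) {
        img <- img + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
      }
      image[, , s] <- img
      labels[, , s] <- lab
    }
    structure(list(image = image, labels = labels,
                   spacing = config$spacing,
                   organ_names = vapply(config$organ_specs,
                                        function(x) x$name, "")),
              class = "phantom_volume")
  })
}

#' Volume-level train/test split
#'
#' Splits volume indices (never slices) into disjoint, exhaustive train
#' and test sets.
#'
#' @param volume_count number of volumes (at least 2).
#' @param fraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
phantom_train_test_split <- function(volume_count, fraction, seed = 0L) {
  stopifnot(fraction > 0, fraction < 1)
  if (volume_count < 2) stop("need at least 2 volumes to split")
  n_train <- round(fraction * volume_count)
  n_train <- max(1L, min(volume_count - 1L, n_train))
  perm <- with_seed(seed, sample.int(volume_count))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[-seq_len(n_train)]))
}

#' Generate a cohort of phantom volumes
#'
#' @param n_volumes number of volumes.
#' @param config base [phantom_config()]; each volume uses a seed derived
#'   from `config$seed` and the volume index.
#' @return list of `phantom_volume` objects.
#' @export
generate_phantom_cohort <- function(n_volumes, config = phantom_config()) {
  lapply(seq_len(n_volumes), function(v) {
    cfg_v <- config
    cfg_v$seed <- derive_seed(config$seed, v)
    generate_phantom(cfg_v)
  })
}
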