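#' Training configuration
#'
#' Reference protocol: Adam, 200 epochs, learning rate 0.001, batch
#' size 1.  Desk-scale runs shrink epochs and the network, not the
#' protocol.  Ablation flags switch decoders, the uncertainty input and
#' the refinement module on or off; using the uncertainty input requires
#' at least one auxiliary decoder.
#'
#' @param epochs positive integer.
#' @param learning_rate positive real.
#' @param batch_size slices per optimizer step (gradients are averaged).
#' @param optimizer only `"adam"` is provided.
#' @param seed integer seed driving initialization, shuffling and
#'   per-step perturbations.
#' @param use_refinement train and apply the boundary-refinement network.
#' @param use_uncertainty_input feed the uncertainty map to the
#'   refinement network (otherwise a zero map).
#' @param use_aux1,use_aux2 enable the feature-drop / noise auxiliary
#'   decoders.
#' @param augment apply random rotation/crop/pad augmentation per step.
#' @param class_weights optional per-class dice weights.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 0.001,
                         batch_size = 1L, optimizer = "adam", seed = 0L,
                         use_refinement = TRUE, use_uncertainty_input = TRUE,
                         use_aux1 = TRUE, use_aux2 = TRUE, augment = FALSE,
                         class_weights = NULL) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            identical(optimizer, "adam"))
  cfg <- structure(list(epochs = as.integer(epochs),
                        learning_rate = learning_rate,
                        batch_size = as.integer(batch_size),
                        optimizer = optimizer, seed = as.integer(seed),
                        use_refinement = isTRUE(use_refinement),
                        use_uncertainty_input = isTRUE(use_uncertainty_input),
                        use_aux1 = isTRUE(use_aux1),
                        use_aux2 = isTRUE(use_aux2),
                        augment = isTRUE(augment),
                        class_weights = class_weights),
                   class = "train_config")
  validate_train_config(cfg)
  cfg
}

validate_train_config <- function(cfg) {
  if (cfg$use_uncertainty_input && !(cfg$use_aux1 || cfg$use_aux2)) {
    stop("use_uncertainty_input requires at least one auxiliary decoder")
  }
  invisible(cfg)
}

enabled_decoders <- function(train_cfg) {
  c("main", if (train_cfg$use_aux1) "aux1", if (train_cfg$use_aux2) "aux2")
}

# ---- Adam ------------------------------------------------------------------

# One Adam step applied recursively over a gradient tree; `m`/`v` states
# grow lazily with the same structure.  Only leaves present in the
# gradient tree are touched, so batch-norm running statistics are
# untouched.
adam_step_tree <- function(p, g, m, v, lr, t,
                           b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (!is.list(g)) {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    return(list(p = p, m = m, v = v))
  }
  if (is.null(m)) m <- vector("list", length(g))
  if (is.null(v)) v <- vector("list", length(g))
  safe_get <- function(l, k) {
    if (is.character(k)) l[[k]]
    else if (k <= length(l)) l[[k]]
    else NULL
  }
  keys <- if (!is.null(names(g))) names(g) else seq_along(g)
  for (k in keys) {
    if (is.null(g[[k]])) next
    r <- adam_step_tree(p[[k]], g[[k]], safe_get(m, k), safe_get(v, k),
                        lr, t, b1, b2, eps)
    p[[k]] <- r$p
    m[[k]] <- r$m
    v[[k]] <- r$v
  }
  list(p = p, m = m, v = v)
}

# Elementwise combination of two gradient trees (for batch accumulation).
tree_axpy <- function(a, b, alpha = 1) {
  if (is.null(a)) {
    if (is.list(b)) return(lapply(b, function(x) tree_axpy(NULL, x, alpha)))
    return(if (is.null(b)) NULL else alpha * b)
  }
  if (!is.list(a)) return(a + alpha * b)
  keys <- if (!is.null(names(a))) names(a) else seq_along(a)
  for (k in keys) a[[k]] <- tree_axpy(a[[k]], b[[k]], alpha)
  a
}

tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (!is.list(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

# ---- one training step (forward + backward + gradients) --------------------

model_step <- function(seg, ref, gt, image, net_cfg, train_cfg, step_seed,
                       train = TRUE) {
  w <- train_cfg$class_weights
  fw <- segment_forward(image, seg, net_cfg, train = train, perturb = TRUE,
                        seed = step_seed)
  seg <- fw$params
  masks <- fw$masks
  aux_masks <- masks[intersect(names(masks), c("aux1", "aux2"))]

  unc <- NULL
  if (length(aux_masks) > 0) {
    unc <- do.call(compute_uncertainty, c(list(masks$main), unname(aux_masks)))
  }

  lw <- list(main = hybrid_loss_with_grad(gt, masks$main, weights = w))
  dmasks <- list(main = lw$main$grad)
  for (nm in names(aux_masks)) {
    lw[[nm]] <- hybrid_loss_with_grad(gt, masks[[nm]], weights = w)
    dmasks[[nm]] <- lw[[nm]]$grad
  }

  rf <- NULL; g_ref <- NULL; refined_probs <- NULL
  if (!is.null(ref)) {
    z <- if (train_cfg$use_uncertainty_input && !is.null(unc)) {
      unc$uncertainty
    } else {
      array(0, dim = dim(masks$main))
    }
    rf <- refine_forward(masks$main, z, ref, net_cfg, train = train)
    ref <- rf$params
    refined_probs <- softmax_channels(rf$refined)
    lw$refined <- hybrid_loss_with_grad(gt, refined_probs, weights = w)
    dS <- softmax_backward(refined_probs, lw$refined$grad)
    rb <- refine_backward(ref, net_cfg, rf, dS)
    g_ref <- rb$g
    dmain_extra <- dS + rb$dmask_main
    if (train_cfg$use_uncertainty_input && !is.null(unc)) {
      # the binarized disagreement indicator is treated as a constant
      dmain_extra <- dmain_extra + unc$disagreement * rb$dunc
    }
    dmasks$main <- dmasks$main + dmain_extra
  }

  sb <- segment_backward(seg, net_cfg, fw, dmasks)

  terms <- unlist(lapply(lw, function(t) c(ce = t$ce, dice = t$dice)))
  list(seg = seg, ref = ref, g_seg = sb$g, g_ref = g_ref,
       loss = sum(vapply(lw, `[[`, 0, "loss")), breakdown = terms,
       masks = masks, unc = unc,
       refined = if (!is.null(rf)) rf$refined)
}

#' Train the segmentation + refinement model
#'
#' End-to-end joint optimization: every step runs the encoder, the
#' enabled decoders, the uncertainty pipeline and (when enabled) the
#' refinement network, sums the hybrid dice + cross-entropy losses of
#' all supervised masks and takes one Adam step.
#'
#' @param data list of slice samples (`image` 2D in \[0, 1\], `labels` 2D
#'   integer), e.g. flattened output of [preprocess_volume()].
#' @param net_cfg a [net_config()].
#' @param train_cfg a [train_config()].
#' @param val_data optional held-out slice samples; when given, per-class
#'   validation dice is recorded each epoch.
#' @param verbose print per-epoch losses.
#' @return list of class `ubrseg_checkpoint` with elements `seg`, `ref`
#'   (NULL when refinement is off), `net_cfg`, `train_cfg`, and
#'   `history` (data.frame of per-epoch mean losses and per-term means).
#' @export
train_model <- function(data, net_cfg, train_cfg, val_data = NULL,
                        verbose = FALSE) {
  stopifnot(length(data) >= 1)
  validate_train_config(train_cfg)
  decs <- enabled_decoders(train_cfg)
  seg <- init_segmentation(net_cfg, decoders = decs)
  ref <- if (train_cfg$use_refinement) init_refinement(net_cfg)
  m_seg <- v_seg <- m_ref <- v_ref <- NULL
  t_step <- 0L
  lr <- train_cfg$learning_rate
  hist <- vector("list", train_cfg$epochs)

  for (ep in seq_len(train_cfg$epochs)) {
    ord <- with_seed(derive_seed(train_cfg$seed, 7000L + ep),
                     sample.int(length(data)))
    losses <- numeric(0)
    terms <- list()
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + train_cfg$batch_size - 1L, length(ord))]
      g_seg_acc <- g_ref_acc <- NULL
      for (idx in batch) {
        step_seed <- derive_seed(train_cfg$seed,
                                 ep * 100000L + i + which(batch == idx))
        smp <- data[[idx]]
        if (train_cfg$augment) smp <- augment_sample(smp, step_seed)
        st <- model_step(seg, ref, smp$labels, smp$image, net_cfg,
                         train_cfg, step_seed, train = TRUE)
        seg <- st$seg
        ref <- st$ref
        if (length(batch) == 1L) {
          g_seg_acc <- st$g_seg
          g_ref_acc <- st$g_ref
        } else {
          g_seg_acc <- tree_axpy(g_seg_acc, st$g_seg, 1 / length(batch))
          if (!is.null(st$g_ref)) {
            g_ref_acc <- tree_axpy(g_ref_acc, st$g_ref, 1 / length(batch))
          }
        }
        losses <- c(losses, st$loss)
        terms[[length(terms) + 1L]] <- st$breakdown
      }
      t_step <- t_step + 1L
      r <- adam_step_tree(seg, g_seg_acc, m_seg, v_seg, lr, t_step)
      seg <- r$p; m_seg <- r$m; v_seg <- r$v
      if (!is.null(g_ref_acc)) {
        r <- adam_step_tree(ref, g_ref_acc, m_ref, v_ref, lr, t_step)
        ref <- r$p; m_ref <- r$m; v_ref <- r$v
      }
      i <- i + train_cfg$batch_size
    }
    term_means <- colMeans(do.call(rbind, terms))
    row <- data.frame(epoch = ep, loss = mean(losses), n_steps = t_step)
    for (nm in names(term_means)) {
      # "main.ce" -> "ce_main", "refined.dice" -> "dice_refined"
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      row[[paste0(parts[2], "_", parts[1])]] <- term_means[[nm]]
    }
    if (!is.null(val_data)) {
      vd <- validation_dice(seg, ref, val_data, net_cfg, train_cfg)
      for (nm in names(vd)) row[[paste0("val_dice_", nm)]] <- vd[[nm]]
    }
    hist[[ep]] <- row
    if (verbose) {
      message(sprintf("epoch %d/%d loss %.4f", ep, train_cfg$epochs,
                      mean(losses)))
    }
  }
  history <- do.call(rbind, lapply(hist, function(r) {
    miss <- setdiff(names(hist[[length(hist)]]), names(r))
    for (mn in miss) r[[mn]] <- NA_real_
    r
  }))
  structure(list(seg = seg, ref = ref, net_cfg = net_cfg,
                 train_cfg = train_cfg, history = history),
            class = "ubrseg_checkpoint")
}

validation_dice <- function(seg, ref, val_data, net_cfg, train_cfg) {
  n <- net_cfg$n_classes
  inter <- num <- rep(0, n - 1)
  for (s in seq_along(val_data)) {
    smp <- val_data[[s]]
    lab <- predict_slice(seg, ref, smp$image, net_cfg, train_cfg,
                         seed = derive_seed(train_cfg$seed, 90000L + s))$labels
    for (k in seq_len(n - 1)) {
      inter[k] <- inter[k] + 2 * sum(lab == k & smp$labels == k)
      num[k] <- num[k] + sum(lab == k) + sum(smp$labels == k)
    }
  }
  stats::setNames(as.list(ifelse(num > 0, inter / num, 1)),
                  paste0("class", seq_len(n - 1)))
}

predict_slice <- function(seg, ref, image, net_cfg, train_cfg, seed = 0L,
                          use_refinement = TRUE) {
  has_aux <- any(c("aux1", "aux2") %in% names(seg$dec))
  fw <- segment_forward(image, seg, net_cfg, train = FALSE,
                        perturb = has_aux, seed = seed)
  masks <- fw$masks
  unc <- NULL
  aux_masks <- masks[intersect(names(masks), c("aux1", "aux2"))]
  if (length(aux_masks) > 0) {
    unc <- do.call(compute_uncertainty, c(list(masks$main), unname(aux_masks)))
  }
  if (!is.null(ref) && use_refinement) {
    z <- if (train_cfg$use_uncertainty_input && !is.null(unc)) {
      unc$uncertainty
    } else {
      array(0, dim = dim(masks$main))
    }
    rf <- refine(masks$main, z, ref, net_cfg, train = FALSE)
    scores <- rf$refined
  } else {
    scores <- masks$main
  }
  list(labels = refined_to_labels(scores),
       uncertainty = if (!is.null(unc)) unc$uncertainty,
       masks = masks)
}

#' Predict labels for a full volume
#'
#' Per axial slice: preprocess (window, body crop, resize), run the
#' segmentation network, derive the uncertainty map, refine, take the
#' per-pixel argmax, and map the labels back to the original geometry;
#' the slices are then stacked into a 3D volume.
#'
#' @param checkpoint a trained `ubrseg_checkpoint`.
#' @param volume 3D image array in the original intensity scale
#'   (pseudo-HU), or a `phantom_volume`.
#' @param window a [window_spec()].
#' @param target working slice size fed to the network.
#' @param crop apply body cropping.
#' @param use_refinement bypass refinement when FALSE.
#' @param save_uncertainty also return a 3D uncertainty volume (per-pixel
#'   maximum over classes, mapped back to the original geometry).
#' @param seed seed for the perturbed inference passes.
#' @return list with `labels` (3D integer array) and `uncertainty` (3D
#'   array or NULL).
#' @export
predict_volume <- function(checkpoint, volume, window = window_spec(),
                           target = c(64L, 64L), crop = TRUE,
                           use_refinement = TRUE, save_uncertainty = FALSE,
                           seed = 0L) {
  stopifnot(inherits(checkpoint, "ubrseg_checkpoint"))
  if (is.list(volume) && !is.null(volume$image)) volume <- volume$image
  samples <- preprocess_volume(list(image = volume), window, target, crop)
  lab_slices <- vector("list", length(samples))
  unc_slices <- if (save_uncertainty) vector("list", length(samples))
  for (s in seq_along(samples)) {
    pr <- predict_slice(checkpoint$seg, checkpoint$ref, samples[[s]]$image,
                        checkpoint$net_cfg, checkpoint$train_cfg,
                        seed = derive_seed(seed, s),
                        use_refinement = use_refinement)
    lab_slices[[s]] <- pr$labels
    if (save_uncertainty) {
      u2 <- if (!is.null(pr$uncertainty)) {
        apply(pr$uncertainty, c(1, 2), max)
      } else {
        matrix(0, nrow(pr$labels), ncol(pr$labels))
      }
      geom <- samples[[s]]$geom
      bh <- geom$box[2] - geom$box[1] + 1L
      bw <- geom$box[4] - geom$box[3] + 1L
      ub <- .cpp_resize_bl_fwd(as_cube(u2), bh, bw)[, , 1]
      full <- matrix(0, geom$full_size[1], geom$full_size[2])
      full[geom$box[1]:geom$box[2], geom$box[3]:geom$box[4]] <- ub
      unc_slices[[s]] <- full
    }
  }
  labels <- stack_slices(lab_slices, lapply(samples, `[[`, "geom"))
  unc <- if (save_uncertainty) {
    array(unlist(unc_slices), dim = dim(labels))
  }
  list(labels = labels, uncertainty = unc)
}

#' Save / load a checkpoint
#'
#' The checkpoint embeds both configurations alongside all weights, so a
#' reloaded model reproduces predictions bit-identically.
#'
#' @param checkpoint a `ubrseg_checkpoint`.
#' @param path file path.
#' @return `save_checkpoint` returns the path invisibly;
#'   `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "ubrseg_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "ubrseg_checkpoint")) stop("not a ubrseg checkpoint")
  ck
}

#' Run an ablation grid
#'
#' Trains and evaluates one model per configuration row, mirroring the
#' ablation axes of the method: refinement on/off, each auxiliary
#' decoder on/off, and the noise family (gaussian vs uniform) of the
#' second perturbation.
#'
#' @param grid data.frame with any of the columns `use_refinement`,
#'   `use_uncertainty_input`, `use_aux1`, `use_aux2`, `noise_kind`.
#' @param train_data,test_volumes training slice samples and a list of
#'   held-out volumes (each with `image` and `labels` arrays).
#' @param net_cfg,train_cfg base configurations overridden per row.
#' @param window,target,crop prediction-time preprocessing settings.
#' @return data.frame: one row per configuration with the flag columns
#'   plus per-organ `dice_<k>` and `hd_<k>` columns.
#' @export
run_ablation <- function(grid, train_data, test_volumes, net_cfg, train_cfg,
                         window = window_spec(), target = c(64L, 64L),
                         crop = TRUE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    ncfg <- net_cfg
    tcfg <- train_cfg
    for (fl in intersect(names(grid),
                         c("use_refinement", "use_uncertainty_input",
                           "use_aux1", "use_aux2"))) {
      tcfg[[fl]] <- isTRUE(grid[[fl]][r])
    }
    if ("noise_kind" %in% names(grid)) {
      ncfg$noise_kind <- as.character(grid$noise_kind[r])
    }
    validate_train_config(tcfg)
    ck <- train_model(train_data, ncfg, tcfg)
    preds <- lapply(test_volumes, function(v) {
      predict_volume(ck, v$image, window = window, target = target,
                     crop = crop)$labels
    })
    gts <- lapply(test_volumes, `[[`, "labels")
    sc <- score_patients(preds, gts,
                         organ_ids = seq_len(ncfg$n_classes - 1L))
    row <- grid[r, , drop = FALSE]
    for (j in seq_len(nrow(sc))) {
      row[[paste0("dice_", sc$class_id[j])]] <- sc$dice_mean[j]
      row[[paste0("hd_", sc$class_id[j])]] <- sc$hd_mean[j]
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}
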