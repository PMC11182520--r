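#' Initialize boundary-refinement parameters
#'
#' Two identical parallel encoders (one consuming the main mask, one the
#' uncertainty map) and a single decoder that concatenates skips from
#' both encoders at every level.  Each encoder opens with a plain 3x3
#' convolution to `base_channels`, then one convolution block plus 2x2
#' max-pooling per stage with the same channel schedule as the
#' segmentation encoder.  The decoder applies one convolution block and
#' bilinear upsampling (factor 2) per level; a final 3x3 convolution
#' emits the N-channel residual.  The residual head is initialized near
#' zero so refinement starts close to the identity.
#'
#' @param cfg a [net_config()].
#' @param head_gain scale of the residual head initialization.
#' @return nested parameter list with `encY`, `encZ`, `dec`.
#' @export
init_refinement <- function(cfg, head_gain = 0.01) {
  ch <- stage_channels(cfg)
  d <- cfg$depth
  N <- cfg$n_classes
  with_seed(derive_seed(cfg$seed, 9L), {
    mk_enc <- function() {
      stages <- if (d >= 2) {
        lapply(2:d, function(i) init_phi(ch[i - 1], ch[i]))
      } else list()
      list(conv1 = init_conv(N, ch[1], 3L), stages = stages)
    }
    encY <- mk_enc()
    encZ <- mk_enc()
    mids <- if (d >= 3) {
      lapply(seq_len(d - 2), function(i) {
        init_phi(ch[d - i + 1] + 2 * ch[d - i], ch[d - i])
      })
    } else list()
    dec <- list(d0 = init_phi(2 * ch[d], ch[d]),
                mids = mids,
                last = init_phi(ch[2], ch[1]),
                head = init_conv(ch[1], N, 3L, gain = head_gain))
    list(encY = encY, encZ = encZ, dec = dec)
  })
}

refine_encoder_forward <- function(enc, x, cfg, train) {
  d <- cfg$depth
  feats <- caches <- vector("list", d)
  c1 <- conv_apply(enc$conv1, x, want_cache = train)
  f <- c1$y
  feats[[1]] <- f
  caches[[1]] <- c1$cache
  for (i in 2:d) {
    a <- phi_apply(enc$stages[[i - 1]], f, train)
    enc$stages[[i - 1]] <- a$p
    mp <- .cpp_maxpool_fwd(a$y)
    caches[[i]] <- list(phi = a$cache,
                        pool = list(idx = mp$idx, H = dim(a$y)[1],
                                    W = dim(a$y)[2]))
    f <- mp$Y
    feats[[i]] <- f
  }
  list(feats = feats, caches = caches, enc = enc)
}

refine_encoder_backward <- function(enc, caches, dfeats, cfg) {
  d <- cfg$depth
  g <- list(conv1 = NULL, stages = vector("list", d - 1))
  upstream <- NULL
  for (i in rev(seq_len(d))) {
    dy <- dfeats[[i]]
    if (!is.null(upstream)) dy <- dy + upstream
    if (i == 1) {
      cb <- conv_grad(enc$conv1, caches[[1]], dy)
      g$conv1 <- cb$g
      return(list(g = g, dx = cb$dx))
    }
    cc <- caches[[i]]
    dpool <- .cpp_maxpool_bwd(dy, cc$pool$idx, cc$pool$H, cc$pool$W)
    pb <- phi_grad(enc$stages[[i - 1]], cc$phi, dpool)
    g$stages[[i - 1]] <- pb$g
    upstream <- pb$dx
  }
}

#' Refine a segmentation mask
#'
#' Feeds the main mask and the uncertainty map through the dual-encoder
#' refinement network; the decoder output is a per-class residual that is
#' added elementwise to the main mask.  The refined mask is a score
#' array, not a probability mask.
#'
#' @param mask_main `(H, W, N)` main decoder probability mask.
#' @param unc `(H, W, N)` uncertainty map (same shape).
#' @param params parameters from [init_refinement()].
#' @param cfg the [net_config()].
#' @param train batch-norm mode.
#' @return list with `residual` and `refined = mask_main + residual`.
#' @export
refine <- function(mask_main, unc, params, cfg, train = FALSE) {
  fw <- refine_forward(mask_main, unc, params, cfg, train)
  list(residual = fw$residual, refined = fw$refined)
}

refine_forward <- function(mask_main, unc, params, cfg, train = FALSE) {
  stopifnot(all(dim(mask_main) == dim(unc)),
            dim(mask_main)[3] == cfg$n_classes)
  d <- cfg$depth
  ey <- refine_encoder_forward(params$encY, mask_main, cfg, train)
  ez <- refine_encoder_forward(params$encZ, unc, cfg, train)
  params$encY <- ey$enc
  params$encZ <- ez$enc

  x0 <- cat_channels(ey$feats[[d]], ez$feats[[d]])
  a0 <- phi_apply(params$dec$d0, x0, train)
  params$dec$d0 <- a0$p
  cache_mids <- vector("list", max(0, d - 2))
  u <- a0$y
  u_dim <- dim(u)
  up_to <- dim(ey$feats[[d - 1]])
  u <- .cpp_resize_bl_fwd(u, up_to[1], up_to[2])
  if (d >= 3) {
    for (i in seq_len(d - 2)) {
      skip_y <- ey$feats[[d - i]]
      skip_z <- ez$feats[[d - i]]
      x <- cat_channels(u, skip_y, skip_z)
      a <- phi_apply(params$dec$mids[[i]], x, train)
      params$dec$mids[[i]] <- a$p
      cache_mids[[i]] <- list(phi = a$cache, in_dim = dim(u),
                              split = c(dim(u)[3], dim(skip_y)[3],
                                        dim(skip_z)[3]))
      nxt <- if (i < d - 2) dim(ey$feats[[d - i - 1]]) else dim(mask_main)
      u <- .cpp_resize_bl_fwd(a$y, nxt[1], nxt[2])
    }
  }
  al <- phi_apply(params$dec$last, u, train)
  params$dec$last <- al$p
  hd <- conv_apply(params$dec$head, al$y, want_cache = train)
  residual <- hd$y
  refined <- mask_main + residual
  list(residual = residual, refined = refined, params = params,
       cache = list(ey = ey, ez = ez, a0_cache = a0$cache, a0_dim = u_dim,
                    mids = cache_mids, last_cache = al$cache,
                    head_cache = hd$cache, mask_dim = dim(mask_main)))
}

# dresidual: dL/d(residual).  Returns parameter gradients plus gradients
# with respect to the two inputs (main mask and uncertainty map).
refine_backward <- function(params, cfg, fw, dresidual) {
  d <- cfg$depth
  cc <- fw$cache
  hb <- conv_grad(params$dec$head, cc$head_cache, dresidual)
  g_dec <- list(head = hb$g)
  lb <- phi_grad(params$dec$last, cc$last_cache, hb$dx)
  g_dec$last <- lb$g
  du <- lb$dx
  dfy <- lapply(cc$ey$feats, function(f) array(0, dim = dim(f)))
  dfz <- lapply(cc$ez$feats, function(f) array(0, dim = dim(f)))
  g_dec$mids <- vector("list", max(0, d - 2))
  if (d >= 3) {
    for (i in rev(seq_len(d - 2))) {
      mc <- cc$mids[[i]]
      phi_out_dim <- mc$phi$out_dim
      du <- .cpp_resize_bl_bwd(du, phi_out_dim[1], phi_out_dim[2])
      mb <- phi_grad(params$dec$mids[[i]], mc$phi, du)
      g_dec$mids[[i]] <- mb$g
      parts <- split_channels(mb$dx, mc$split)
      dfy[[d - i]] <- dfy[[d - i]] + parts[[2]]
      dfz[[d - i]] <- dfz[[d - i]] + parts[[3]]
      du <- parts[[1]]
    }
  }
  du <- .cpp_resize_bl_bwd(du, cc$a0_dim[1], cc$a0_dim[2])
  b0 <- phi_grad(params$dec$d0, cc$a0_cache, du)
  g_dec$d0 <- b0$g
  nyd <- dim(cc$ey$feats[[d]])[3]
  parts <- split_channels(b0$dx, c(nyd, nyd))
  dfy[[d]] <- dfy[[d]] + parts[[1]]
  dfz[[d]] <- dfz[[d]] + parts[[2]]
  by <- refine_encoder_backward(params$encY, cc$ey$caches, dfy, cfg)
  bz <- refine_encoder_backward(params$encZ, cc$ez$caches, dfz, cfg)
  list(g = list(encY = by$g, encZ = bz$g, dec = g_dec),
       dmask_main = by$dx, dunc = bz$dx)
}

#' Convert refined scores to labels
#'
#' Per-pixel argmax over channels; ties broken toward the lower class
#' index.  Invariant under adding a constant to all channels.
#'
#' @param refined `(H, W, N)` finite score array.
#' @return 2D integer label matrix with values `0..N-1`.
#' @export
refined_to_labels <- function(refined) {
  stopifnot(all(is.finite(refined)))
  d <- dim(refined)
  m <- matrix(refined, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}
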