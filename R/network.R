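#' Network configuration
#'
#' Shared configuration of the segmentation network (one encoder, one
#' main and two auxiliary decoders) and the boundary-refinement network.
#' Channel counts double per encoder stage (`base_channels * 2^(stage-1)`)
#' and spatial size halves per stage after the first.
#'
#' @param n_classes number of segmentation classes N (background
#'   included), at least 2.
#' @param base_channels channels of the first stage (64 reproduces the
#'   reference architecture; small values give desk-scale models).
#' @param depth number of encoder stages (at least 2; 5 is the reference).
#' @param noise_kind `"uniform"` (multiplicative, uniformly distributed
#'   random noise) or `"gaussian"` (additive, scaled by the feature
#'   standard deviation) — the perturbation of the second auxiliary
#'   decoder.
#' @param noise_amplitude nonnegative noise amplitude.
#' @param feature_drop_rate fraction of spatial positions dropped by the
#'   attention-guided feature drop of the first auxiliary decoder,
#'   in (0, 1).
#' @param seed seed for weight initialization.
#' @return list of class `net_config`.
#' @export
net_config <- function(n_classes, base_channels = 64L, depth = 5L,
                       noise_kind = c("uniform", "gaussian"),
                       noise_amplitude = 0.3, feature_drop_rate = 0.3,
                       seed = 0L) {
  noise_kind <- match.arg(noise_kind)
  stopifnot(n_classes >= 2, base_channels >= 1, depth >= 2,
            noise_amplitude >= 0,
            feature_drop_rate > 0, feature_drop_rate < 1)
  structure(list(n_classes = as.integer(n_classes),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), noise_kind = noise_kind,
                 noise_amplitude = noise_amplitude,
                 feature_drop_rate = feature_drop_rate,
                 seed = as.integer(seed)),
            class = "net_config")
}

stage_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

# ---- parameter containers --------------------------------------------------

init_conv <- function(cin, cout, k = 3L, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * cin))
  list(K = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = rep(0, cout), k = as.integer(k))
}

init_phi <- function(cin, cout) {
  c(init_conv(cin, cout, 3L),
    list(gamma = rep(1, cout), beta = rep(0, cout),
         rmean = rep(0, cout), rvar = rep(1, cout)))
}

#' Initialize segmentation-network parameters
#'
#' @param cfg a [net_config()].
#' @param decoders character subset of `c("main", "aux1", "aux2")`.
#' @return nested parameter list (encoder stages, one decoder per name).
#' @export
init_segmentation <- function(cfg, decoders = c("main", "aux1", "aux2")) {
  ch <- stage_channels(cfg)
  d <- cfg$depth
  with_seed(cfg$seed, {
    enc <- lapply(seq_len(d), function(i) {
      cin <- if (i == 1) 1L else ch[i - 1]
      list(phi1 = init_phi(cin, ch[i]), phi2 = init_phi(ch[i], ch[i]))
    })
    dec <- lapply(decoders, function(nm) {
      steps <- lapply(seq_len(d - 1), function(i) {
        cin <- ch[d - i + 1] + ch[d - i]
        list(phi1 = init_phi(cin, ch[d - i]),
             phi2 = init_phi(ch[d - i], ch[d - i]))
      })
      list(steps = steps, head = init_conv(ch[1], cfg$n_classes, 1L))
    })
    names(dec) <- decoders
    list(enc = enc, dec = dec)
  })
}

# ---- layer wrappers --------------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

phi_apply <- function(p, x, train, want_cache = train) {
  r <- .cpp_phi_fwd(x, p$K, p$b, p$gamma, p$beta, p$rmean, p$rvar,
                    BN_EPS, BN_MOMENTUM, train, 3L, want_cache)
  if (train) {
    p$rmean <- as.numeric(r$rmean)
    p$rvar <- as.numeric(r$rvar)
  }
  cache <- if (want_cache) {
    list(P = r$P, xhat = r$xhat,
         sinv = as.numeric(r$sinv), train = train,
         cin = nrow(p$K) %/% 9L, out_dim = dim(r$Y))
  }
  list(y = r$Y, cache = cache, p = p)
}

phi_grad <- function(p, cache, dy) {
  r <- .cpp_phi_bwd(dy, cache$xhat, cache$sinv, p$gamma, p$beta,
                    cache$P, p$K, cache$train, 3L, cache$cin)
  list(dx = r$dX,
       g = list(K = r$dK, b = as.numeric(r$db),
                gamma = as.numeric(r$dgamma), beta = as.numeric(r$dbeta)))
}

conv_apply <- function(p, x, want_cache = FALSE) {
  r <- .cpp_conv_fwd(x, p$K, p$b, p$k, want_cache)
  cache <- if (want_cache) {
    list(P = r$P, cin = nrow(p$K) %/% (p$k^2))
  }
  list(y = r$Y, cache = cache)
}

conv_grad <- function(p, cache, dy) {
  r <- .cpp_conv_bwd(cache$P, p$K, dy, p$k, cache$cin)
  list(dx = r$dX, g = list(K = r$dK, b = as.numeric(r$db)))
}

#' Apply one convolution block
#'
#' The elementary block of the architecture: 3x3 convolution (padding 1),
#' spatial batch normalization, ReLU.  Output spatial size equals input
#' size; all output values are nonnegative.
#'
#' @param x `(H, W, C_in)` feature array.
#' @param out_channels output channel count.
#' @param params optional block parameters (as built by the network
#'   initializers); fresh parameters are drawn when omitted.
#' @param train use batch statistics (TRUE) or running statistics.
#' @param seed seed for fresh parameters.
#' @return `(H, W, out_channels)` feature array.
#' @export
phi_block <- function(x, out_channels, params = NULL, train = TRUE,
                      seed = 0L) {
  x <- as_cube(x)
  if (is.null(params)) {
    params <- with_seed(seed, init_phi(dim(x)[3], out_channels))
  }
  phi_apply(params, x, train)$y
}

# ---- perturbations ---------------------------------------------------------

#' Attention-guided feature drop
#'
#' Zeroes the fraction `rate` of spatial positions with the highest
#' channel-mean activation, across all channels.  Ties (e.g. constant
#' feature maps) are broken by a seeded random ordering, so the operation
#' is deterministic given the seed.
#'
#' @param x `(H, W, C)` feature array.
#' @param rate fraction of positions to drop, in (0, 1).
#' @param seed integer seed for tie-breaking.
#' @return perturbed array with attribute `keep` (the binary spatial keep
#'   mask, used by backpropagation).
#' @export
perturb_feature_drop <- function(x, rate, seed = 0L) {
  stopifnot(rate > 0, rate < 1)
  d <- dim(x)
  m <- rowMeans(matrix(x, d[1] * d[2], d[3]))
  n_drop <- round(rate * length(m))
  tie <- with_seed(seed, runif(length(m)))
  ord <- order(-m, tie)
  keep <- rep(1, length(m))
  keep[ord[seq_len(n_drop)]] <- 0
  keep <- matrix(keep, d[1], d[2])
  out <- x * array(keep, dim = d)
  attr(out, "keep") <- keep
  out
}

#' Random-noise feature perturbation
#'
#' `"uniform"`: multiplicative, `x * (1 + u)` with
#' `u ~ U(-amplitude, amplitude)` elementwise (uniformly distributed
#' random noise).  `"gaussian"`: additive, `x + g` with
#' `g ~ N(0, amplitude * sd(x))`.  Deterministic given the seed;
#' amplitude 0 is the identity.
#'
#' @param x `(H, W, C)` feature array.
#' @param kind `"uniform"` or `"gaussian"`.
#' @param amplitude nonnegative amplitude.
#' @param seed integer seed.
#' @return perturbed array with attribute `mult` (the elementwise factor
#'   applied to incoming gradients).
#' @export
perturb_noise <- function(x, kind = c("uniform", "gaussian"), amplitude,
                          seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0)
  if (amplitude == 0) {
    out <- x
    attr(out, "mult") <- 1
    return(out)
  }
  with_seed(seed, {
    if (kind == "uniform") {
      u <- array(runif(length(x), -amplitude, amplitude), dim = dim(x))
      out <- x * (1 + u)
      attr(out, "mult") <- 1 + u
    } else {
      g <- array(rnorm(length(x), 0, amplitude * stats::sd(x)), dim = dim(x))
      out <- x + g
      attr(out, "mult") <- 1
    }
    out
  })
}

# ---- encoder / decoder -----------------------------------------------------

#' Encode an image into the feature pyramid
#'
#' Stage 1 applies two convolution blocks at full resolution; every later
#' stage applies two blocks and then 2x2 max-pooling, so stage `i` has
#' `base_channels * 2^(i-1)` channels at `1/2^(i-1)` resolution.
#'
#' @param image `(H, W)` matrix or `(H, W, 1)` array; `H` and `W` must be
#'   divisible by `2^(depth-1)`.
#' @param params segmentation parameters from [init_segmentation()].
#' @param cfg the [net_config()].
#' @param train batch-norm mode.
#' @return list of class `feature_pyramid`: per-stage `(H_i, W_i, C_i)`
#'   arrays; the deepest stage is the bottleneck.
#' @export
encode <- function(image, params, cfg, train = FALSE) {
  encode_full(image, params, cfg, train)$pyramid
}

encode_full <- function(image, params, cfg, train) {
  x <- as_cube(image)
  div <- 2L^(cfg$depth - 1L)
  if (dim(x)[1] %% div != 0 || dim(x)[2] %% div != 0) {
    stop("input spatial size must be divisible by 2^(depth-1) = ", div)
  }
  d <- cfg$depth
  pyramid <- caches <- vector("list", d)
  f <- x
  for (i in seq_len(d)) {
    a1 <- phi_apply(params$enc[[i]]$phi1, f, train)
    a2 <- phi_apply(params$enc[[i]]$phi2, a1$y, train)
    params$enc[[i]]$phi1 <- a1$p
    params$enc[[i]]$phi2 <- a2$p
    st_cache <- list(phi1 = a1$cache, phi2 = a2$cache, pool = NULL)
    f <- a2$y
    if (i > 1) {
      mp <- .cpp_maxpool_fwd(f)
      st_cache$pool <- list(idx = mp$idx, H = dim(f)[1], W = dim(f)[2])
      f <- mp$Y
    }
    pyramid[[i]] <- f
    caches[[i]] <- st_cache
  }
  list(pyramid = structure(pyramid, class = "feature_pyramid"),
       caches = caches, params = params)
}

encode_backward <- function(params, caches, dskips, cfg) {
  d <- cfg$depth
  g <- list(enc = vector("list", d))
  upstream <- NULL
  for (i in rev(seq_len(d))) {
    dy <- dskips[[i]]
    if (!is.null(upstream)) dy <- dy + upstream
    cc <- caches[[i]]
    if (!is.null(cc$pool)) {
      dy <- .cpp_maxpool_bwd(dy, cc$pool$idx, cc$pool$H, cc$pool$W)
    }
    b2 <- phi_grad(params$enc[[i]]$phi2, cc$phi2, dy)
    b1 <- phi_grad(params$enc[[i]]$phi1, cc$phi1, b2$dx)
    g$enc[[i]] <- list(phi1 = b1$g, phi2 = b2$g)
    upstream <- if (i > 1) b1$dx
  }
  g
}

#' Decode a feature pyramid into class logits
#'
#' Each decoder step upsamples (bilinear, factor 2), concatenates the
#' matching-resolution encoder skip, and applies two convolution blocks
#' halving the channel count; a final 1x1 convolution emits `n_classes`
#' channels at full resolution.
#'
#' @param pyramid a `feature_pyramid` from [encode()].
#' @param bottleneck bottleneck feature array (possibly perturbed); must
#'   match the deepest pyramid stage's shape.
#' @param dec_params one decoder's parameters
#'   (e.g. `params$dec$main`).
#' @param cfg the [net_config()].
#' @param train batch-norm mode.
#' @return `(H, W, n_classes)` logit array.
#' @export
decode <- function(pyramid, bottleneck, dec_params, cfg, train = FALSE) {
  if (!all(dim(bottleneck) == dim(pyramid[[cfg$depth]]))) {
    stop("bottleneck shape does not match the deepest pyramid stage")
  }
  decode_full(pyramid, bottleneck, dec_params, cfg, train)$logits
}

decode_full <- function(pyramid, bottleneck, dec_params, cfg, train) {
  d <- cfg$depth
  u <- bottleneck
  caches <- vector("list", d - 1)
  for (i in seq_len(d - 1)) {
    skip <- pyramid[[d - i]]
    ho <- dim(skip)[1]; wo <- dim(skip)[2]
    up <- .cpp_resize_bl_fwd(u, ho, wo)
    x <- cat_channels(up, skip)
    a1 <- phi_apply(dec_params$steps[[i]]$phi1, x, train)
    a2 <- phi_apply(dec_params$steps[[i]]$phi2, a1$y, train)
    dec_params$steps[[i]]$phi1 <- a1$p
    dec_params$steps[[i]]$phi2 <- a2$p
    caches[[i]] <- list(phi1 = a1$cache, phi2 = a2$cache,
                        in_dim = dim(u), split = c(dim(up)[3], dim(skip)[3]))
    u <- a2$y
  }
  hd <- conv_apply(dec_params$head, u, want_cache = train)
  list(logits = hd$y, caches = caches, cache_head = hd$cache,
       params = dec_params)
}

decode_backward <- function(dec_params, caches, cache_head, dlogits, cfg) {
  d <- cfg$depth
  hb <- conv_grad(dec_params$head, cache_head, dlogits)
  g <- list(steps = vector("list", d - 1), head = hb$g)
  du <- hb$dx
  dskips <- vector("list", d)
  for (i in rev(seq_len(d - 1))) {
    cc <- caches[[i]]
    b2 <- phi_grad(dec_params$steps[[i]]$phi2, cc$phi2, du)
    b1 <- phi_grad(dec_params$steps[[i]]$phi1, cc$phi1, b2$dx)
    g$steps[[i]] <- list(phi1 = b1$g, phi2 = b2$g)
    parts <- split_channels(b1$dx, cc$split)
    dskips[[d - i]] <- parts[[2]]
    du <- .cpp_resize_bl_bwd(parts[[1]], cc$in_dim[1], cc$in_dim[2])
  }
  list(g = g, dbottleneck = du, dskips = dskips)
}

# ---- full segmentation module ---------------------------------------------

#' Segment a slice with the multi-decoder network
#'
#' Runs the encoder once and up to three decoders: the main decoder on
#' the unperturbed bottleneck, auxiliary decoder 1 on the feature-dropped
#' bottleneck, auxiliary decoder 2 on the noise-perturbed bottleneck.
#' All decoders share the encoder's skip connections but have independent
#' weights.  Each returned mask is a per-pixel softmax over classes.
#'
#' @param image `(H, W)` preprocessed slice in \[0, 1\].
#' @param params parameters from [init_segmentation()].
#' @param cfg the [net_config()].
#' @param train batch-norm mode.
#' @param perturb apply the bottleneck perturbations (training and
#'   uncertainty-producing inference); when FALSE the auxiliary decoders
#'   see the clean bottleneck.
#' @param seed seed for the perturbations.
#' @return named list of `(H, W, N)` probability masks (`main`, and
#'   `aux1`/`aux2` when those decoders exist in `params`).
#' @export
segment <- function(image, params, cfg, train = FALSE, perturb = TRUE,
                    seed = 0L) {
  fw <- segment_forward(image, params, cfg, train = train, perturb = perturb,
                        seed = seed)
  fw$masks
}

segment_forward <- function(image, params, cfg, train = FALSE,
                            perturb = TRUE, seed = 0L) {
  enc <- encode_full(image, params, cfg, train)
  params <- enc$params
  bottleneck <- enc$pyramid[[cfg$depth]]
  decs <- names(params$dec)
  masks <- logits <- dcaches <- dheads <- stats::setNames(
    vector("list", length(decs)), decs)
  perturb_cache <- list()
  for (nm in decs) {
    inb <- bottleneck
    if (nm == "aux1" && perturb) {
      inb <- perturb_feature_drop(bottleneck, cfg$feature_drop_rate,
                                  derive_seed(seed, 1L))
      perturb_cache$aux1 <- attr(inb, "keep")
    } else if (nm == "aux2" && perturb) {
      inb <- perturb_noise(bottleneck, cfg$noise_kind, cfg$noise_amplitude,
                           derive_seed(seed, 2L))
      perturb_cache$aux2 <- attr(inb, "mult")
    }
    df <- decode_full(enc$pyramid, inb, params$dec[[nm]], cfg, train)
    params$dec[[nm]] <- df$params
    logits[[nm]] <- df$logits
    masks[[nm]] <- softmax_channels(df$logits)
    dcaches[[nm]] <- df$caches
    dheads[[nm]] <- df$cache_head
  }
  list(masks = masks, logits = logits, params = params,
       cache = list(enc = enc$caches, dec = dcaches, dec_head = dheads,
                    pyramid = enc$pyramid, perturb = perturb_cache,
                    perturb_on = perturb))
}

# dmasks: list of dL/dprob per decoder (NULL entries allowed).  Returns
# gradients mirroring the parameter tree plus dL/d(input image).
segment_backward <- function(params, cfg, fw, dmasks) {
  d <- cfg$depth
  decs <- names(params$dec)
  dskips_total <- lapply(fw$cache$pyramid, function(p) array(0, dim = dim(p)))
  g_dec <- stats::setNames(vector("list", length(decs)), decs)
  for (nm in decs) {
    if (is.null(dmasks[[nm]])) next
    dlogits <- softmax_backward(fw$masks[[nm]], dmasks[[nm]])
    db <- decode_backward(params$dec[[nm]], fw$cache$dec[[nm]],
                          fw$cache$dec_head[[nm]], dlogits, cfg)
    g_dec[[nm]] <- db$g
    for (i in seq_len(d - 1)) {
      dskips_total[[i]] <- dskips_total[[i]] + db$dskips[[i]]
    }
    dbn <- db$dbottleneck
    if (nm == "aux1" && fw$cache$perturb_on) {
      dbn <- dbn * array(fw$cache$perturb$aux1, dim = dim(dbn))
    } else if (nm == "aux2" && fw$cache$perturb_on) {
      dbn <- dbn * fw$cache$perturb$aux2
    }
    dskips_total[[d]] <- dskips_total[[d]] + dbn
  }
  g_enc <- encode_backward(params, fw$cache$enc, dskips_total, cfg)
  list(g = list(enc = g_enc$enc, dec = g_dec))
}

# ---- parameter accounting --------------------------------------------------

TRAINABLE_LEAVES <- c("K", "b", "gamma", "beta")

walk_params <- function(p, fn, path = character()) {
  if (is.list(p) && !is.null(names(p)) &&
      any(names(p) %in% TRAINABLE_LEAVES)) {
    for (nm in intersect(names(p), TRAINABLE_LEAVES)) {
      fn(p[[nm]], c(path, nm))
    }
    for (nm in setdiff(names(p), c(TRAINABLE_LEAVES, "rmean", "rvar", "k"))) {
      walk_params(p[[nm]], fn, c(path, nm))
    }
  } else if (is.list(p)) {
    for (i in seq_along(p)) {
      nm <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i]
            else as.character(i)
      walk_params(p[[i]], fn, c(path, nm))
    }
  }
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Counts convolution weights/biases and batch-norm scale/shift leaves;
#' running statistics are not parameters.
#'
#' @param params a parameter tree from [init_segmentation()] or
#'   [init_refinement()].
#' @return integer count.
#' @export
count_params <- function(params) {
  total <- 0
  walk_params(params, function(leaf, path) total <<- total + length(leaf))
  total
}
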