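# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a per-step / per-slice seed from a base seed, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587L)
}

# One-hot encode an integer label matrix (values 0..n_classes-1) into an
# (H, W, n_classes) array.
one_hot <- function(labels, n_classes) {
  stopifnot(all(labels >= 0), all(labels < n_classes))
  out <- array(0, dim = c(nrow(labels), ncol(labels), n_classes))
  for (k in seq_len(n_classes)) {
    out[, , k] <- as.numeric(labels == (k - 1L))
  }
  out
}

# Channel-wise softmax of an (H, W, C) score array.
softmax_channels <- function(z) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3])
  mx <- m[, 1]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, m[, c])
  e <- exp(m - mx)
  array(e / rowSums(e), dim = d)
}

# Backward of softmax_channels: given probabilities p and dL/dp, return
# dL/dz.  dz = p * (dp - sum_c p_c dp_c).
softmax_backward <- function(p, dp) {
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  dpm <- matrix(dp, d[1] * d[2], d[3])
  array(pm * (dpm - rowSums(pm * dpm)), dim = d)
}

# Concatenate (H, W, Ci) arrays along the channel axis.
cat_channels <- function(...) {
  parts <- list(...)
  h <- dim(parts[[1]])[1]; w <- dim(parts[[1]])[2]
  array(unlist(parts, use.names = FALSE),
        dim = c(h, w, sum(vapply(parts, function(a) dim(a)[3], 0))))
}

# Split a channel gradient back into the parts cat_channels joined.
split_channels <- function(x, sizes) {
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , at + seq_len(sizes[i]), drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}
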