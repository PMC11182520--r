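# Shared fixtures for the test suite.  Everything is generated in code;
# no binary fixtures.

# A random probability mask: softmax of iid normals, (H, W, C).
random_prob_mask <- function(seed, h = 8, w = 8, c = 3) {
  withr::with_seed(seed, {
    z <- array(rnorm(h * w * c), dim = c(h, w, c))
    ubrseg:::softmax_channels(z)
  })
}

# A random one-hot mask set (list of 3), as produced by binarize_mask.
random_onehot_triplet <- function(seed, h = 8, w = 8, c = 3) {
  lapply(1:3, function(i) binarize_mask(random_prob_mask(seed * 31 + i, h, w, c)))
}

# Tiny network configuration for fast structural tests.
tiny_net <- function(n_classes = 3, base = 2, depth = 2, seed = 1) {
  net_config(n_classes = n_classes, base_channels = base, depth = depth,
             seed = seed)
}

# Small phantom used across tests.
small_phantom <- function(seed = 42, n_slices = 4) {
  generate_phantom(phantom_config(n_slices = n_slices, seed = seed))
}

# A couple of preprocessed training slices from a small phantom.
small_samples <- function(seed = 42, n_slices = 4) {
  preprocess_volume(small_phantom(seed, n_slices))
}
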