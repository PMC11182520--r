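test_that("windowing maps the window interval onto [0, 1] and clamps", {
  spec <- window_spec(level = 30, width = 400)
  expect_equal(apply_window(30, spec), 0.5)
  expect_equal(apply_window(500, spec), 1.0)   # above 230 clamps high
  expect_equal(apply_window(-170, spec), 0.0)  # lower edge of the window
  expect_equal(apply_window(230, spec), 1.0)
  # monotone non-decreasing in HU
  hu <- sort(runif(200, -2000, 2000))
  out <- apply_window(hu, spec)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("body crop keeps the body, excludes a couch bar, flags empty", {
  img <- matrix(0, 64, 64)
  img[20:50, 15:45] <- 0.6           # body blob
  img[60, 5:60] <- 0.4               # separate thin couch bar
  lab <- matrix(0L, 64, 64)
  lab[30:40, 25:35] <- 1L
  cr <- crop_body(img, lab)
  expect_false(cr$empty)
  expect_true(cr$box[2] < 60)        # bar row excluded
  expect_true(all(cr$labels %in% c(0L, 1L)))
  expect_identical(dim(cr$image), dim(cr$labels))

  full <- crop_body(matrix(0.5, 32, 32))
  expect_equal(full$box, c(1L, 32L, 1L, 32L))

  empty <- crop_body(matrix(0, 16, 16))
  expect_true(empty$empty)
  expect_equal(empty$box, c(1L, 16L, 1L, 16L))
})

test_that("crop followed by its inverse restores original geometry", {
  v <- small_phantom()
  win <- apply_window(v$image)
  s <- 2
  cr <- crop_body(win[, , s], v$labels[, , s])
  back <- uncrop_labels(cr$labels, cr$box, cr$full_size)
  expect_identical(dim(back), dim(v$labels[, , s]))
  expect_identical(back[cr$box[1]:cr$box[2], cr$box[3]:cr$box[4]],
                   cr$labels)
})

test_that("resize is identity at own size and preserves constants", {
  img <- matrix(runif(64 * 48), 64, 48)
  lab <- matrix(sample(0:2, 64 * 48, TRUE), 64, 48)
  same <- resize_pair(img, lab, c(64, 48))
  expect_equal(same$image, img, tolerance = 1e-12)
  expect_identical(same$labels, lab)
  const <- resize_pair(matrix(0.7, 32, 32), NULL, c(17, 53))
  expect_equal(range(const$image), c(0.7, 0.7))
  expect_error(resize_pair(img, lab, c(0, 10)))
})

test_that("downscaling a labelled disc scales its area by ~1/4", {
  H <- 128
  ii <- matrix(seq_len(H), H, H)
  jj <- t(ii)
  lab <- ((ii - 64)^2 + (jj - 64)^2 <= 30^2) * 1L
  rs <- resize_pair(matrix(0, H, H), lab, c(64, 64))
  a0 <- sum(lab)
  a1 <- sum(rs$labels)
  expect_lt(abs(a1 - a0 / 4) / (a0 / 4), 0.15)
  # nearest-neighbour resampling cannot create new labels
  expect_true(all(unique(as.vector(rs$labels)) %in% unique(as.vector(lab))))
})

test_that("augmentation applies one transform to both image and labels", {
  smp <- small_samples()[[1]]
  out <- augment_sample(smp, seed = 3)
  expect_identical(dim(out$image), dim(smp$image))
  expect_identical(dim(out$labels), dim(smp$labels))
  expect_true(all(out$labels %in% unique(as.vector(smp$labels))))
  # deterministic given seed
  expect_identical(out, augment_sample(smp, seed = 3))
  # zero rotation, zero crop is the identity
  id <- augment_sample(smp, seed = 3, max_rotation = 0, max_crop = 0)
  expect_equal(id$image, smp$image, tolerance = 1e-12)
  expect_identical(id$labels, smp$labels)
})

test_that("90-degree rotation matches the direct array rotation oracle", {
  withr::with_seed(4, {
    img <- matrix(runif(64 * 64), 64, 64)
    lab <- matrix(sample(0:2, 64 * 64, TRUE), 64, 64)
  })
  rot_i <- ubrseg:::rotate_matrix(img, 90, "bilinear")
  rot_l <- ubrseg:::rotate_matrix(lab, 90, "nearest")
  # independent oracle: rotate coordinates directly.  For a square
  # matrix rotated by +90 deg about its centre, destination (i, j) takes
  # its value from source (j, n + 1 - i).
  n <- 64
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) oracle[i, j] <- img[j, n + 1 - i]
  expect_equal(rot_i, oracle, tolerance = 1e-6)
  oracle_l <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) oracle_l[i, j] <- lab[j, n + 1 - i]
  expect_identical(rot_l, oracle_l)
  back_i <- ubrseg:::rotate_matrix(rot_i, -90, "bilinear")
  expect_equal(back_i, img, tolerance = 1e-6)
  back_l <- ubrseg:::rotate_matrix(rot_l, -90, "nearest")
  expect_identical(back_l, lab)
  # 90-degree rotation is a permutation of the entries (no interpolation)
  expect_setequal(round(as.vector(rot_i), 10), round(as.vector(img), 10))
})

test_that("preprocess_volume yields aligned, windowed, sized samples", {
  v <- small_phantom()
  samp <- preprocess_volume(v, target = c(32, 32))
  expect_length(samp, dim(v$image)[3])
  for (s in samp) {
    expect_identical(dim(s$image), c(32L, 32L))
    expect_identical(dim(s$labels), c(32L, 32L))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})
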