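test_that("stack_slices preserves order and inverts preprocessing", {
  slices <- lapply(1:5, function(s) matrix(s, 4, 4))
  vol <- stack_slices(slices)
  expect_identical(dim(vol), c(4L, 4L, 5L))
  for (s in 1:5) expect_true(all(vol[, , s] == s))
  # unstack -> identity
  expect_identical(lapply(seq_len(5), function(s) vol[, , s] * 1L),
                   lapply(slices, function(m) matrix(as.integer(m), 4, 4)))
  # out-of-order slices differ exactly by the permutation
  perm <- c(3, 1, 2, 5, 4)
  vol2 <- stack_slices(slices[perm])
  expect_identical(vol2, vol[, , perm])
  # geometry records map each slice back to its original frame
  geoms <- lapply(1:5, function(s) list(box = c(2L, 5L, 3L, 6L),
                                        full_size = c(8L, 8L)))
  vol3 <- stack_slices(slices, geoms)
  expect_identical(dim(vol3), c(8L, 8L, 5L))
  expect_true(all(vol3[2:5, 3:6, 1] == 1))
  expect_true(all(vol3[c(1, 6:8), , 1] == 0))
  expect_error(stack_slices(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "inconsistent")
})

test_that("dice coefficient follows the overlap formula", {
  a <- array(0, dim = c(4, 4, 2)); b <- a
  a[1, 1:4, 1] <- 1                  # |A| = 4
  b[1, 2:4, 1] <- 1; b[2, 1:3, 1] <- 1  # |B| = 6, overlap 3
  expect_equal(dice_coefficient(a, b), 0.6)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, array(0, dim = dim(a))), 0)
  expect_equal(dice_coefficient(array(0, dim = c(2, 2, 2)),
                                array(0, dim = c(2, 2, 2))), 1)
  # symmetry and translation invariance
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  shift <- function(x) {
    y <- array(0, dim = dim(x)); y[3:4, , ] <- x[1:2, , ]; y
  }
  expect_equal(dice_coefficient(shift(a), shift(b)), dice_coefficient(a, b))
})

test_that("Hausdorff distance matches the brute-force all-pairs oracle", {
  # two unit cubes offset by 3 voxels along one axis
  a <- array(0, dim = c(8, 8, 8)); b <- a
  a[2, 2, 2] <- 1
  b[5, 2, 2] <- 1
  expect_equal(hausdorff_distance(a, b), 3.0)
  expect_equal(hausdorff_distance(a, a), 0)
  expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
  # anisotropic spacing scales the offset axis
  expect_equal(hausdorff_distance(a, b, spacing = c(2, 1, 1)), 6.0)

  # random volumes against an R brute-force oracle over boundary voxels
  brute <- function(x, y, sp = c(1, 1, 1)) {
    bx <- ubrseg:::boundary_voxels(x)
    by <- ubrseg:::boundary_voxels(y)
    dmat <- outer(seq_len(nrow(bx)), seq_len(nrow(by)),
                  Vectorize(function(i, j) {
                    sqrt(sum(((bx[i, ] - by[j, ]) * sp)^2))
                  }))
    max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  }
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- array(0, dim = c(7, 7, 5))
      y <- array(0, dim = c(7, 7, 5))
      x[sample(length(x), 25)] <- 1
      y[sample(length(y), 25)] <- 1
      sp <- runif(3, 0.5, 2)
      expect_equal(hausdorff_distance(x, y, sp), brute(x, y, sp),
                   tolerance = 1e-12)
    }
  })
  expect_warning(out <- hausdorff_distance(a, array(0, dim = dim(a))),
                 "empty")
  expect_true(is.na(out))
})

test_that("score_patients aggregates mean and population variance", {
  gt <- array(0L, dim = c(6, 6, 2)); gt[2:4, 2:4, ] <- 1L
  pred_perfect <- gt
  pred_off <- gt
  pred_off[2, , ] <- 0L              # drop one row of the organ
  sc <- score_patients(list(pred_perfect, pred_off), list(gt, gt))
  expect_equal(sc$n_patients, 2)
  d1 <- dice_coefficient(pred_off == 1, gt == 1)
  expect_equal(sc$dice_mean, mean(c(1, d1)))
  expect_equal(sc$dice_var, mean((c(1, d1) - mean(c(1, d1)))^2))
  # two patients with dice 0.8 and 1.0 -> mean 0.9, variance 0.01
  pvar_check <- c(0.8, 1.0)
  expect_equal(mean(pvar_check), 0.9)
  expect_equal(mean((pvar_check - 0.9)^2), 0.01)
  # single patient: variance 0; perfect prediction: dice 1, HD 0
  sc1 <- score_patients(list(pred_perfect), list(gt))
  expect_equal(sc1$dice_mean, 1)
  expect_equal(sc1$dice_var, 0)
  expect_equal(sc1$hd_mean, 0)
  # organ missing from one patient's ground truth is excluded + logged
  gt2 <- array(0L, dim = c(6, 6, 2))
  expect_message(
    sc2 <- score_patients(list(pred_perfect, pred_perfect), list(gt, gt2)),
    "absent")
  expect_equal(sc2$n_patients, 1)
})
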