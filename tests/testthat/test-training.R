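# Desk-scale bookkeeping tests use a deliberately tiny model (base 2,
# depth 2, 16x16 slices) so the whole file stays fast.

tiny_train_setup <- function(n_slices = 4, seed = 21) {
  vol <- generate_phantom(phantom_config(n_slices = n_slices, height = 32,
                                         width = 32, seed = seed))
  samples <- preprocess_volume(vol, target = c(16, 16))
  list(vol = vol, samples = samples,
       ncfg = net_config(n_classes = 3, base_channels = 2, depth = 2,
                         seed = 1))
}

test_that("training history has one row per epoch and records all terms", {
  su <- tiny_train_setup()
  tcfg <- train_config(epochs = 2, seed = 3)
  ck <- train_model(su$samples, su$ncfg, tcfg)
  expect_s3_class(ck, "ubrseg_checkpoint")
  expect_equal(nrow(ck$history), 2)
  expect_equal(ck$history$epoch, 1:2)
  expect_equal(ck$history$n_steps, c(4, 8))  # 4 slices, batch 1
  expect_true(all(c("ce_main", "dice_main", "ce_refined", "dice_refined",
                    "ce_aux1", "ce_aux2") %in% names(ck$history)))
  expect_true(all(ck$history$loss > 0))
})

test_that("invalid flag combinations are rejected", {
  expect_error(train_config(use_aux1 = FALSE, use_aux2 = FALSE,
                            use_uncertainty_input = TRUE),
               "auxiliary")
  cfg <- train_config(use_aux1 = FALSE, use_aux2 = FALSE,
                      use_uncertainty_input = FALSE, use_refinement = FALSE)
  expect_s3_class(cfg, "train_config")
})

test_that("ablation flags control which weights exist", {
  su <- tiny_train_setup()
  tcfg <- train_config(epochs = 1, seed = 3, use_refinement = FALSE,
                       use_aux2 = FALSE, use_uncertainty_input = TRUE)
  ck <- train_model(su$samples, su$ncfg, tcfg)
  expect_null(ck$ref)
  expect_named(ck$seg$dec, c("main", "aux1"))
  # plain single-decoder model: no auxiliaries, no refinement
  tcfg2 <- train_config(epochs = 1, seed = 3, use_refinement = FALSE,
                        use_aux1 = FALSE, use_aux2 = FALSE,
                        use_uncertainty_input = FALSE)
  ck2 <- train_model(su$samples, su$ncfg, tcfg2)
  expect_named(ck2$seg$dec, "main")
  # the reduced system is a plain single-encoder/single-decoder network:
  # its parameter set matches a main-only initialization exactly
  expect_identical(count_params(ck2$seg),
                   count_params(init_segmentation(su$ncfg, "main")))
})

test_that("checkpoint round-trip reproduces predictions bit-identically", {
  su <- tiny_train_setup()
  tcfg <- train_config(epochs = 1, seed = 3)
  ck <- train_model(su$samples, su$ncfg, tcfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  p1 <- predict_volume(ck, su$vol, target = c(16, 16), seed = 5)
  p2 <- predict_volume(ck2, su$vol, target = c(16, 16), seed = 5)
  expect_identical(p1$labels, p2$labels)
  # prediction is deterministic on repeat
  p3 <- predict_volume(ck, su$vol, target = c(16, 16), seed = 5)
  expect_identical(p1$labels, p3$labels)
  unlink(path)
})

test_that("training is reproducible given the seed", {
  su <- tiny_train_setup()
  tcfg <- train_config(epochs = 1, seed = 11)
  h1 <- train_model(su$samples, su$ncfg, tcfg)$history
  h2 <- train_model(su$samples, su$ncfg, tcfg)$history
  expect_equal(h1$loss, h2$loss, tolerance = 1e-12)
})

test_that("zeroing the refinement head reduces prediction to the main argmax", {
  su <- tiny_train_setup()
  tcfg <- train_config(epochs = 1, seed = 3)
  ck <- train_model(su$samples, su$ncfg, tcfg)
  ck0 <- ck
  ck0$ref$dec$head$K[] <- 0
  ck0$ref$dec$head$b[] <- 0
  with_ref <- predict_volume(ck0, su$vol, target = c(16, 16), seed = 2)
  no_ref <- predict_volume(ck0, su$vol, target = c(16, 16), seed = 2,
                           use_refinement = FALSE)
  expect_identical(with_ref$labels, no_ref$labels)
})

test_that("predict_volume returns labels in the original geometry", {
  su <- tiny_train_setup()
  tcfg <- train_config(epochs = 1, seed = 3)
  ck <- train_model(su$samples, su$ncfg, tcfg)
  pr <- predict_volume(ck, su$vol, target = c(16, 16), seed = 1,
                       save_uncertainty = TRUE)
  expect_identical(dim(pr$labels), dim(su$vol$labels))
  expect_true(all(pr$labels %in% 0:2))
  expect_identical(dim(pr$uncertainty), dim(su$vol$labels))
  expect_true(all(pr$uncertainty >= 0))
})

test_that("run_ablation emits one complete row per configuration", {
  su <- tiny_train_setup(n_slices = 3)
  grid <- data.frame(use_refinement = c(FALSE, TRUE),
                     use_aux1 = c(FALSE, TRUE),
                     use_aux2 = c(FALSE, TRUE),
                     use_uncertainty_input = c(FALSE, TRUE),
                     noise_kind = c("gaussian", "uniform"))
  tcfg <- train_config(epochs = 1, seed = 2)
  tab <- run_ablation(grid, su$samples, list(su$vol), su$ncfg, tcfg,
                      target = c(16, 16))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("dice_1", "dice_2", "hd_1", "hd_2") %in% names(tab)))
  expect_true(all(is.finite(tab$dice_1)))
})
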