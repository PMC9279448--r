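test_that("BCE loss matches closed forms on hand-computable cases", {
  gt0 <- matrix(0, 2, 2)
  pred_half <- matrix(0.5, 2, 2)
  expect_equal(bce_loss(gt0, pred_half), log(2), tolerance = 1e-12)
  # perfect prediction after clipping
  gt <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(bce_loss(gt, gt, eps = 1e-7), 1e-6)
  # single pixel, gt = 1, pred = exp(-1): loss -log(exp(-1)) = 1
  expect_equal(bce_loss(matrix(1, 1, 1), matrix(exp(-1), 1, 1)), 1,
               tolerance = 1e-12)
  expect_gte(bce_loss(matrix(1, 1, 1), matrix(0.3, 1, 1)), 0)
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0.5, 3, 3)), "dimension")
})

test_that("binarize applies the >= threshold rule", {
  expect_equal(sum(binarize(matrix(0.4, 8, 8), 0.5)), 0)
  expect_equal(sum(binarize(matrix(0.5, 8, 8), 0.5)), 64)  # ties foreground
  set.seed(3)
  pm <- matrix(runif(100), 10, 10)
  expect_equal(sum(binarize(pm, 0.7)), sum(pm >= 0.7))  # brute-force scan
})

test_that("the model produces in-range probability maps of the input size", {
  cfg <- segmentation_config(input_side = 64L,
                             encoder_channels = c(8L, 16L, 32L, 64L, 128L),
                             seed = 9L)
  model <- build_model(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- retinafd:::unet_forward(model, x)$probs
  expect_equal(dim(p1), c(64L, 64L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # deterministic: same seed, same input, identical output
  model2 <- build_model(cfg)
  p2 <- retinafd:::unet_forward(model2, x)$probs
  expect_identical(p1, p2)
  # an input side not divisible by 2^depth is a configuration error
  expect_error(segmentation_config(input_side = 100L), "divisible")
})

test_that("augmentation expands pair lists deterministically and keeps masks binary", {
  pairs <- lapply(1:3, function(i) {
    tree <- generate_vessel_tree(tree_params(seed = i), 96L)
    render_phantom(tree, seed = i)[c("image", "mask")]
  })
  aug <- augment(pairs, 11L, seed = 4L)
  expect_length(aug, 11L)
  aug2 <- augment(pairs, 11L, seed = 4L)
  expect_identical(aug, aug2)
  for (k in 4:11) {
    p <- aug[[k]]
    tr <- attr(p, "transform")
    expect_true(all(p$mask %in% c(0, 1)))
    # replaying the recorded transform on the source reproduces the pair
    redo <- retinafd:::apply_pair_transform(pairs[[tr$source]], tr)
    expect_identical(redo$image, p$image)
    expect_identical(redo$mask, p$mask)
  }
})

test_that("flipping twice along the same axis recovers the original", {
  a <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(retinafd:::flip_array(retinafd:::flip_array(
    a, horizontal = TRUE), horizontal = TRUE), a)
  m <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_identical(retinafd:::flip_array(retinafd:::flip_array(
    m, vertical = TRUE), vertical = TRUE), m)
})

test_that("vesselness segmentation recovers the phantom tree", {
  ph <- default_phantom()
  probs <- segment(ph$image, backend = "vesselness")
  expect_equal(dim(probs), c(512L, 512L))
  expect_true(all(probs >= 0 & probs <= 1))
  mask <- binarize(probs)
  expect_gt(dice(mask, ph$mask), 0.6)
})

test_that("segmentation of a black FOV yields near-zero probabilities", {
  dark <- standardized_image(array(0, c(128, 128, 3)))
  probs <- segment(dark, backend = "vesselness")
  expect_lt(max(probs), 0.01)   # FFT-level residue only, far below threshold
  expect_equal(sum(binarize(probs)), 0)
})

test_that("the cnn backend demands trained weights", {
  ph <- small_phantom(seed = 2L, side = 192L)
  expect_error(segment(ph$image, backend = "cnn"), "weights required")
})

test_that("training reduces the BCE loss and zero epochs is a no-op", {
  cfg0 <- segmentation_config(input_side = 64L,
                              encoder_channels = c(8L, 16L, 32L, 64L, 128L),
                              epochs = 0L, seed = 1L)
  model <- build_model(cfg0)
  fit0 <- train(model, list(list(image = array(0.5, c(64, 64, 3)),
                                 mask = matrix(0L, 64, 64))), cfg0)
  expect_length(fit0$losses, 0)
  expect_identical(fit0$model$enc, model$enc)
  expect_error(train(model, list()), "empty")

  pairs <- lapply(1:4, function(i) {
    tree <- generate_vessel_tree(tree_params(seed = i), 64L)
    render_phantom(tree, seed = i)[c("image", "mask")]
  })
  improved <- vapply(1:3, function(s) {
    cfg <- segmentation_config(input_side = 64L,
                               encoder_channels = c(8L, 16L, 32L, 64L,
                                                    128L),
                               epochs = 2L, seed = s)
    fit <- train(build_model(cfg), pairs, cfg)
    fit$losses[2] < fit$losses[1]
  }, logical(1))
  expect_gte(sum(improved), 2)  # majority of seeds
})

test_that("a single pair can be overfit to near-zero loss", {
  cfg <- segmentation_config(input_side = 64L,
                             encoder_channels = c(8L, 16L, 32L),
                             learning_rate = 5e-3, epochs = 80L, seed = 2L)
  tree <- generate_vessel_tree(tree_params(seed = 1L), 64L)
  pair <- render_phantom(tree, seed = 1L)[c("image", "mask")]
  fit <- train(build_model(cfg), list(pair), cfg)
  expect_lt(tail(fit$losses, 1), 0.1)
})

test_that("model weights survive a checkpoint round trip", {
  cfg <- segmentation_config(input_side = 32L,
                             encoder_channels = c(4L, 8L, 16L), seed = 3L)
  model <- build_model(cfg)
  path <- tempfile(fileext = ".rds")
  save_weights(model, path)
  back <- load_weights(path)
  expect_identical(back$enc, model$enc)
  expect_error(load_weights(tempfile()))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(retinafd:::unet_forward(back, x)$probs,
                   retinafd:::unet_forward(model, x)$probs)
})
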