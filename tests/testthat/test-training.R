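# Splitting, augmentation, focal loss, IoU, and the training loop.

test_that("split sizes follow floor(n*f) with the remainder assigned to train", {
  sp <- split_dataset(sprintf("s%03d", 1:100), c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp), c(train = 80L, val = 10L, test = 10L))
  # n = 601 (the real dataset size): floor rule gives 481/60/60
  sp2 <- split_dataset(sprintf("s%03d", 1:601), c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp2), c(train = 481L, val = 60L, test = 60L))
  # disjoint and exhaustive
  all_ids <- sort(unlist(sp2, use.names = FALSE))
  expect_identical(all_ids, sort(sprintf("s%03d", 1:601)))
  # deterministic under the seed, different for another seed
  expect_identical(sp2, split_dataset(sprintf("s%03d", 1:601), c(0.8, 0.1, 0.1), 1))
  expect_false(identical(sp2, split_dataset(sprintf("s%03d", 1:601),
                                            c(0.8, 0.1, 0.1), 2)))
  expect_error(split_dataset(c("a", "a", "b"), c(0.8, 0.1, 0.1), 1), "unique")
  expect_error(split_dataset(letters[1:5], c(0.8, 0.1, 0.1), 1), "empty")
})

test_that("augmentation applies one shared geometric transform and preserves labels", {
  s <- generate_sample(synthetic_config(image_size = 64, seed = 2), "Col-0", "mock")
  img <- channel(s$image, "bf405")
  cfg <- augment_config(max_rotation_deg = 10, max_shift_px = 6, max_scale_px = 10,
                        per_op_probability = 1)
  a1 <- augment_pair(img, s$mask, cfg, rng = 5)
  a2 <- augment_pair(img, s$mask, cfg, rng = 5)
  expect_identical(a1, a2)
  expect_true(all(unclass(a1$mask) %in% 0:4))
  expect_identical(dim(a1$image), dim(img))
  expect_false(identical(a1$image, img))
  # probability 0 is the identity transform
  id <- augment_pair(img, s$mask, augment_config(per_op_probability = 0), rng = 5)
  expect_equal(id$image, img)
  expect_identical(unclass(id$mask), unclass(s$mask))
})

test_that("focal loss matches its closed form and reduces to cross-entropy", {
  # one pixel, p_t = 0.5, gamma = 2: loss = 0.25 * ln 2
  probs <- array(c(0.5, 0.5, 0, 0, 0), dim = c(1, 1, 5))
  target <- seg_mask(matrix(0L, 1, 1))
  expect_equal(focal_loss(probs, target, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)
  # gamma = 0 equals mean cross-entropy
  set.seed(3)
  z <- array(rnorm(6 * 6 * 5), dim = c(6, 6, 5))
  p <- rootzones:::softmax_hwc(z)
  y <- seg_mask(matrix(sample(0:4, 36, replace = TRUE), 6, 6))
  ce <- -mean(log(matrix(p, ncol = 5)[cbind(1:36, as.integer(y) + 1L)]))
  expect_equal(focal_loss(p, y, gamma = 0), ce, tolerance = 1e-8)
  # perfect one-hot prediction: loss at the epsilon floor
  ph <- array(0, dim = c(2, 2, 5)); ph[, , 1] <- 1
  expect_lt(focal_loss(ph, seg_mask(matrix(0L, 2, 2)), 2), 1e-7)
})

test_that("IoU matches hand-computed cases and the brute-force oracle", {
  a <- seg_mask(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(iou(a, a, 1), 1.0)
  b <- seg_mask(matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(iou(a, b, 1), 0.0)
  # pred covers 2 of 4 truth pixels plus 2 false positives: 2/6
  truth <- seg_mask(matrix(c(2, 2, 2, 2, 0, 0, 0, 0, 0), 3, 3))
  pred <- seg_mask(matrix(c(2, 2, 0, 0, 2, 2, 0, 0, 0), 3, 3))
  expect_equal(iou(pred, truth, 2), 2 / 6)
  expect_true(is.na(iou(a, b, 3)))          # class absent: union empty
  expect_error(iou(a, seg_mask(matrix(0L, 3, 3)), 1), "shape")
  set.seed(4)
  for (i in 1:200) {
    p <- matrix(sample(0:4, 64, replace = TRUE), 8, 8)
    t <- matrix(sample(0:4, 64, replace = TRUE), 8, 8)
    cls <- sample(0:4, 1)
    expect_equal(iou(seg_mask(p), seg_mask(t), cls), iou_oracle(p, t, cls))
  }
})

test_that("evaluate aggregates per-image IoU the documented way", {
  m <- micro_model()
  set.seed(5)
  ds <- lapply(1:3, function(i) {
    x <- matrix(runif(32 * 32), 32, 32)
    list(x = x, y = seg_mask(matrix(sample(0:2, 32 * 32, TRUE), 32, 32)))
  })
  rep <- evaluate(m, ds)
  manual <- sapply(0:4, function(cid) {
    v <- vapply(ds, function(s) iou(predict(m, s$x)$mask, s$y, cid), numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  expect_equal(unname(rep$per_class_iou), manual)
  # truth lacks LEZ(3)/MZ(4): they are NA and excluded from the mean
  expect_true(is.na(rep$per_class_iou[["LEZ"]]) ||
              is.finite(rep$per_class_iou[["LEZ"]]))
  expect_equal(rep$mean_iou, mean(rep$per_class_iou[c("EEZ", "LEZ", "MZ")],
                                  na.rm = TRUE))
  expect_error(evaluate(m, list()), "empty")
})

test_that("deterministic training is bit-exact reproducible", {
  ds <- generate_dataset(synthetic_config(image_size = 32, seed = 6), 3,
                         groups = list(c("Col-0", "mock")))
  samples <- as_training_samples(ds)
  tc <- train_config(epochs = 2, batch_size = 2, learning_rate = 1e-3,
                     seed = 9, deterministic = TRUE,
                     augment = augment_config(per_op_probability = 0.5,
                                              max_shift_px = 4, max_scale_px = 6))
  run <- function() {
    m <- build_model(arch_config("micro"), seed = 9)
    train(m, samples, tc, val_dataset = samples)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$final_model$params, f2$final_model$params)
  expect_identical(f1$metrics, f2$metrics)
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("training reduces the focal loss on an easy task", {
  ds <- generate_dataset(synthetic_config(image_size = 32, seed = 7), 4,
                         groups = list(c("Col-0", "mock")))
  samples <- as_training_samples(ds)
  tc <- train_config(epochs = 4, batch_size = 2, learning_rate = 3e-3,
                     augment = augment_config(per_op_probability = 0),
                     seed = 10, deterministic = TRUE)
  m <- build_model(arch_config("micro"), seed = 10)
  fit <- train(m, samples, tc, val_dataset = samples)
  expect_lt(fit$metrics$loss[4], fit$metrics$loss[1])
  expect_identical(nrow(fit$metrics), 4L)
})
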