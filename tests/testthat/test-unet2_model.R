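# Model architecture, parameter accounting, prediction contracts, and a
# finite-difference check of the whole backward pass.

# Independent analytic layer-sum oracle: every block is a chain of 3x3
# convolutions; a conv a -> b has 9ab weights + b biases.
oracle_conv <- function(a, b) 9 * a * b + b
oracle_rsu <- function(L, I, M, O) {
  oracle_conv(I, O) + oracle_conv(O, M) + (L - 1) * oracle_conv(M, M) +
    (L - 2) * oracle_conv(2 * M, M) + oracle_conv(2 * M, O)
}
oracle_rsu4f <- function(I, M, O) {
  oracle_conv(I, O) + oracle_conv(O, M) + 3 * oracle_conv(M, M) +
    2 * oracle_conv(2 * M, M) + oracle_conv(2 * M, O)
}

test_that("tiny preset parameter count equals the analytic layer-sum oracle", {
  m <- build_model(arch_config("tiny"), seed = 1)
  expected <- oracle_rsu(5, 1, 8, 16) + oracle_rsu(4, 16, 8, 32) +
    oracle_rsu4f(32, 16, 64) + oracle_rsu4f(64, 16, 64) +
    oracle_rsu(5, 48, 8, 16) + oracle_rsu(4, 96, 8, 32) +
    oracle_rsu4f(128, 16, 64) +
    sum(vapply(c(16, 32, 64, 64), function(ch) 9 * ch * 5 + 5, numeric(1))) +
    (4 * 5) * 5 + 5
  expect_identical(count_trainable_parameters(m), as.numeric(expected))
})

test_that("a single 3x3 convolution from 1 to 5 channels counts 50 parameters", {
  m <- build_model(arch_config("linear"), seed = 1)
  expect_identical(count_trainable_parameters(m), 50)   # 1*5*9 + 5
})

test_that("freezing a layer removes exactly its element count", {
  m <- build_model(arch_config("micro"), seed = 1)
  n0 <- count_trainable_parameters(m)
  layer_n <- length(m$params$out$conv$w) + length(m$params$out$conv$b)
  m2 <- freeze_layer(m, "out", "conv")
  expect_identical(count_trainable_parameters(m2), n0 - layer_n)
  expect_error(freeze_layer(m, "nope"), "no such layer")
})

test_that("weight initialization is seed-deterministic", {
  m1 <- build_model(arch_config("micro"), seed = 5)
  m2 <- build_model(arch_config("micro"), seed = 5)
  m3 <- build_model(arch_config("micro"), seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("prediction yields normalized probabilities and a deterministic argmax mask", {
  m <- micro_model()
  set.seed(1)
  bf <- matrix(runif(64 * 64), 64, 64)
  p1 <- predict(m, bf)
  p2 <- predict(m, bf)
  expect_identical(p1$mask, p2$mask)
  expect_lt(max(abs(apply(p1$prob_map$probs, c(1, 2), sum) - 1)), 1e-6)
  expect_true(all(p1$prob_map$probs >= 0 & p1$prob_map$probs <= 1))
  # argmax ties break toward the lowest class index: all-zero weights give
  # uniform logits, so every pixel is assigned class 0 (background)
  mz <- m
  mz$params <- rapply(mz$params, function(a) a * 0, how = "replace")
  expect_true(all(unclass(predict(mz, bf)$mask) == 0L))
})

test_that("inputs that do not fit the pooling ladder are padded and cropped back", {
  m <- micro_model()
  set.seed(2)
  for (d in list(c(50, 70), c(63, 63), c(64, 96))) {
    pr <- predict(m, matrix(runif(prod(d)), d[1], d[2]))
    expect_identical(dim(unclass(pr$mask)), as.integer(d))
  }
})

test_that("checkpoints roundtrip with a JSON sidecar", {
  m <- micro_model(seed = 8)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$params, m$params)
  sc <- jsonlite::read_json(paste0(p, ".json"))
  expect_identical(sc$config$scale, "micro")
  expect_identical(sc$seed, 8L)
  expect_equal(sc$n_trainable, count_trainable_parameters(m))
})

test_that("analytic gradients match central finite differences", {
  m <- micro_model(seed = 7)
  # move biases off zero so no ReLU kink sits exactly at the expansion point
  flat <- rootzones:::flatten_params(m$params)
  set.seed(11)
  for (nm in grep("\\.b$", names(flat), value = TRUE)) {
    flat[[nm]][] <- rnorm(length(flat[[nm]]), sd = 0.05)
  }
  m$params <- rootzones:::unflatten_params(flat, m$params)
  set.seed(12)
  H <- 8
  x <- array(runif(H * H), dim = c(H, H, 1))
  y <- seg_mask(matrix(sample(0:4, H * H, replace = TRUE), H, H))
  ctx <- rootzones:::nn_ctx()
  loss_of <- function(mm) {
    fw <- rootzones:::u2net_fw(mm, x, ctx)
    rootzones:::focal_loss_grad(fw$d0, y, 2)$loss
  }
  fw <- rootzones:::u2net_fw(m, x, ctx)
  fl <- rootzones:::focal_loss_grad(fw$d0, y, 2)
  bw <- rootzones:::u2net_bw(m, fw, fl$g, ctx)
  gflat <- rootzones:::flatten_params(bw$g)
  eps <- 1e-6
  set.seed(13)
  for (nm in sample(names(flat), 10)) {
    k <- sample(length(flat[[nm]]), 1)
    fp <- flat
    fp[[nm]][k] <- fp[[nm]][k] + eps
    m2 <- m; m2$params <- rootzones:::unflatten_params(fp, m$params)
    lp <- loss_of(m2)
    fp[[nm]][k] <- fp[[nm]][k] - 2 * eps
    m2$params <- rootzones:::unflatten_params(fp, m$params)
    lm <- loss_of(m2)
    num <- (lp - lm) / (2 * eps)
    ana <- gflat[[nm]][k]
    expect_lt(abs(num - ana) / max(1e-7, abs(num) + abs(ana)), 1e-4,
              label = sprintf("gradient of %s[%d]", nm, k))
  }
  # gradient with respect to the input image
  k <- 17
  x2 <- x; x2[k] <- x[k] + eps
  lp <- loss_of_input <- local({
    fw2 <- rootzones:::u2net_fw(m, x2, ctx)
    rootzones:::focal_loss_grad(fw2$d0, y, 2)$loss
  })
  x2[k] <- x[k] - eps
  fw3 <- rootzones:::u2net_fw(m, x2, ctx)
  lm <- rootzones:::focal_loss_grad(fw3$d0, y, 2)$loss
  expect_equal((lp - lm) / (2 * eps), bw$gx[k], tolerance = 1e-5)
})
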