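# Shared fixtures. Everything is generated in code at test time; the trained
# tiny model is expensive (a few minutes) and is built once per test run and
# memoized for all tests that need predicted segmentations.

.fixture_env <- new.env(parent = emptyenv())

# The desk-scale training world: 64 px synthetic images at the generator's
# default noise (0.05), four groups, 25 samples each (100 images total),
# split 80/10/10.
easy_world_config <- function(seed = 20L) {
  synthetic_config(image_size = 64L, noise_sd = 0.05, seed = seed)
}

as_training_samples <- function(dataset) {
  lapply(dataset$samples, function(s) {
    list(x = channel(s$image, "bf405"), y = s$mask)
  })
}

# Train the tiny model once on the 100-image world; returns model, metrics,
# the split, and the per-subset sample lists.
get_trained_tiny <- function() {
  if (!is.null(.fixture_env$trained)) return(.fixture_env$trained)
  ds <- generate_dataset(easy_world_config(), 25)
  samples <- as_training_samples(ds)
  sp <- split_dataset(names(samples), c(0.8, 0.1, 0.1), seed = 42L)
  tc <- train_config(epochs = 8L, batch_size = 4L, learning_rate = 3e-3,
                     augment = augment_config(per_op_probability = 0),
                     seed = 42L, deterministic = TRUE)
  model0 <- build_model(arch_config("tiny"), seed = 42L)
  fit <- train(model0, samples[sp$train], tc, val_dataset = samples[sp$val])
  .fixture_env$trained <- list(model = fit$model, metrics = fit$metrics,
                               split = sp, samples = samples,
                               metadata = ds$metadata,
                               val_report = evaluate(fit$model, samples[sp$val]),
                               config = easy_world_config())
  .fixture_env$trained
}

# A small untrained model for contract tests that only need a forward pass.
micro_model <- function(seed = 2L) build_model(arch_config("micro"), seed = seed)

# Textbook Welch formulas, written independently of the package routine.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# Brute-force IoU on per-class pixel sets.
iou_oracle <- function(pred, truth, cls) {
  inter <- 0; uni <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == cls
    t <- truth[i] == cls
    inter <- inter + (p && t)
    uni <- uni + (p || t)
  }
  if (uni == 0) NA_real_ else inter / uni
}
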