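#' Architecture configuration for the segmentation model
#'
#' The segmentation network is a two-level nested encoder-decoder built from
#' residual U-blocks (RSU): each stage of the outer U-Net is itself a small
#' U-Net whose output is added to a stage-local residual. The `"full"` preset
#' reproduces the published full-scale configuration of this architecture
#' (adapted to a single brightfield input channel and five zone classes); the
#' `"tiny"` preset keeps the same block topology at reduced depth and filter
#' widths for desk-scale training; `"micro"` is a minimal variant for gradient
#' checking; `"linear"` is a single linear convolution used to validate
#' attribution code against closed-form gradients.
#'
#' Every convolution can be preceded by a dropout layer; these layers are
#' inactive (rate 0) during training and standard prediction and are only
#' switched on for Monte Carlo Dropout uncertainty estimation.
#'
#' @param scale one of `"full"`, `"tiny"`, `"micro"`, `"linear"`.
#' @param in_channels number of input channels (1: the bf-405nm channel).
#' @param n_classes number of output classes (5 zone classes).
#' @param dropout_rate dropout probability applied before each convolution
#'   when Monte Carlo Dropout mode is enabled.
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(scale = c("tiny", "full", "micro", "linear"),
                        in_channels = 1L, n_classes = 5L, dropout_rate = 0) {
  scale <- match.arg(scale)
  stopifnot(n_classes >= 2, dropout_rate >= 0, dropout_rate <= 1)
  structure(list(scale = scale, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), dropout_rate = dropout_rate),
            class = "arch_config")
}

# Stage tables. Each stage: type "rsu" (with L pooling levels) or "rsu4f"
# (fully dilated, constant resolution); I/M/O are in/mid/out channel widths.
rsu_stage <- function(type, L, I, M, O) list(type = type, L = L, I = I, M = M, O = O)

arch_spec <- function(config) {
  ic <- config$in_channels
  nc <- config$n_classes
  if (config$scale == "linear") {
    return(list(linear = TRUE, n_classes = nc, in_channels = ic))
  }
  stages <- switch(config$scale,
    full = list(
      enc = list(
        rsu_stage("rsu", 7L, ic, 32L, 64L),
        rsu_stage("rsu", 6L, 64L, 32L, 128L),
        rsu_stage("rsu", 5L, 128L, 64L, 256L),
        rsu_stage("rsu", 4L, 256L, 128L, 512L),
        rsu_stage("rsu4f", NA, 512L, 256L, 512L),
        rsu_stage("rsu4f", NA, 512L, 256L, 512L)),
      dec = list(
        rsu_stage("rsu", 7L, 128L, 16L, 64L),
        rsu_stage("rsu", 6L, 256L, 32L, 64L),
        rsu_stage("rsu", 5L, 512L, 64L, 128L),
        rsu_stage("rsu", 4L, 1024L, 128L, 256L),
        rsu_stage("rsu4f", NA, 1024L, 256L, 512L))),
    tiny = list(
      enc = list(
        rsu_stage("rsu", 5L, ic, 8L, 16L),
        rsu_stage("rsu", 4L, 16L, 8L, 32L),
        rsu_stage("rsu4f", NA, 32L, 16L, 64L),
        rsu_stage("rsu4f", NA, 64L, 16L, 64L)),
      dec = list(
        rsu_stage("rsu", 5L, 48L, 8L, 16L),
        rsu_stage("rsu", 4L, 96L, 8L, 32L),
        rsu_stage("rsu4f", NA, 128L, 16L, 64L))),
    micro = list(
      enc = list(
        rsu_stage("rsu", 4L, ic, 2L, 4L),
        rsu_stage("rsu4f", NA, 4L, 2L, 8L)),
      dec = list(
        rsu_stage("rsu", 4L, 12L, 2L, 4L))))
  n <- length(stages$enc)
  side_in <- c(vapply(stages$dec, function(s) s$O, numeric(1)),
               stages$enc[[n]]$O)
  list(linear = FALSE, enc = stages$enc, dec = stages$dec,
       side_in = side_in, n_classes = nc, in_channels = ic)
}

# Enumerate every convolution of a spec as (name, k, cin, cout, dil).
rsu_conv_table <- function(stage) {
  I <- stage$I; M <- stage$M; O <- stage$O
  if (stage$type == "rsu4f") {
    data.frame(conv = c("convin", "conv1", "conv2", "conv3", "conv4",
                        "conv3d", "conv2d", "conv1d"),
               k = 3L,
               cin = c(I, O, M, M, M, 2L * M, 2L * M, 2L * M),
               cout = c(O, M, M, M, M, M, M, O),
               dil = c(1L, 1L, 2L, 4L, 8L, 4L, 2L, 1L))
  } else {
    L <- stage$L
    data.frame(conv = c("convin",
                        paste0("conv", seq_len(L)),
                        paste0("conv", rev(seq_len(L - 1)), "d")),
               k = 3L,
               cin = c(I, O, rep(M, L - 1), rep(2L * M, L - 1)),
               cout = c(O, rep(M, L - 1), M, rep(M, L - 2), O),
               dil = c(rep(1L, L), 2L, rep(1L, L - 1)))
  }
}

conv_table <- function(spec) {
  if (spec$linear) {
    return(data.frame(stage = "out", conv = "conv", k = 3L,
                      cin = spec$in_channels, cout = spec$n_classes, dil = 1L))
  }
  rows <- list()
  for (i in seq_along(spec$enc)) {
    tb <- rsu_conv_table(spec$enc[[i]])
    tb$stage <- paste0("en", i)
    rows[[length(rows) + 1]] <- tb
  }
  for (i in seq_along(spec$dec)) {
    tb <- rsu_conv_table(spec$dec[[i]])
    tb$stage <- paste0("de", i)
    rows[[length(rows) + 1]] <- tb
  }
  ns <- length(spec$side_in)
  rows[[length(rows) + 1]] <- data.frame(
    stage = paste0("side", seq_len(ns)), conv = "conv", k = 3L,
    cin = spec$side_in, cout = spec$n_classes, dil = 1L)
  rows[[length(rows) + 1]] <- data.frame(
    stage = "out", conv = "conv", k = 1L,
    cin = ns * spec$n_classes, cout = spec$n_classes, dil = 1L)
  out <- do.call(rbind, rows)
  out[, c("stage", "conv", "k", "cin", "cout", "dil")]
}

#' Build a segmentation model
#'
#' Weight initialization is He-normal (sd = sqrt(2 / fan_in)), biases zero,
#' drawn from a dedicated seeded stream so two builds with the same seed are
#' bit-identical.
#'
#' @param config an [arch_config()].
#' @param seed integer seed controlling weight initialization.
#' @return an object of class `unet2_model`.
#' @export
build_model <- function(config, seed = 42L) {
  stopifnot(inherits(config, "arch_config"))
  spec <- arch_spec(config)
  tab <- conv_table(spec)
  params <- list()
  with_seed(derive_seed(seed, "init"), {
    for (i in seq_len(nrow(tab))) {
      st <- tab$stage[i]; cv <- tab$conv[i]
      k <- tab$k[i]; cin <- tab$cin[i]; cout <- tab$cout[i]
      w <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout))
      if (is.null(params[[st]])) params[[st]] <- list()
      params[[st]][[cv]] <- list(w = w, b = numeric(cout))
    }
  })
  structure(list(config = config, spec = spec, params = params,
                 seed = as.integer(seed)),
            class = "unet2_model")
}

#' Count trainable parameters of a model
#'
#' Counts the elements of every weight and bias array not marked frozen.
#'
#' @param model a `unet2_model`.
#' @return integer-valued count (as double, counts can exceed 2^31 elsewhere).
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "unet2_model"))
  flat <- flatten_params(model$params)
  sum(vapply(flat, function(a) {
    if (isTRUE(attr(a, "frozen"))) 0 else length(a)
  }, numeric(1)))
}

#' Freeze one named convolution layer
#'
#' Marks the layer's weight and bias arrays as non-trainable; frozen layers
#' are excluded from [count_trainable_parameters()] and skipped by the
#' optimizer.
#'
#' @param model a `unet2_model`.
#' @param stage stage name, e.g. `"en1"`, `"de2"`, `"side1"`, `"out"`.
#' @param conv convolution name within the stage, e.g. `"convin"`, `"conv1d"`.
#' @export
freeze_layer <- function(model, stage, conv = "conv") {
  pr <- model$params[[stage]][[conv]]
  if (is.null(pr)) stop("no such layer: ", stage, "/", conv)
  attr(pr$w, "frozen") <- TRUE
  attr(pr$b, "frozen") <- TRUE
  model$params[[stage]][[conv]] <- pr
  model
}

#' @export
print.unet2_model <- function(x, ...) {
  cat(sprintf("<unet2_model> scale=%s in=%d classes=%d  %s trainable parameters\n",
              x$config$scale, x$config$in_channels, x$config$n_classes,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the parameter arrays, accompanied by
#' a JSON sidecar (`<path>.json`) recording the architecture configuration and
#' initialization seed.
#'
#' @param model a `unet2_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config), seed = model$seed,
                  n_trainable = count_trainable_parameters(model),
                  package = "rootzones",
                  version = as.character(utils::packageVersion("rootzones")))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet2_model")) stop("not a rootzones checkpoint: ", path)
  model
}
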