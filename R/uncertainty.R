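#' Monte Carlo Dropout configuration
#'
#' The published setting is T = 10 stochastic forward passes with dropout
#' probability 0.5 applied before every convolutional layer.
#'
#' @param T number of stochastic forward passes (>= 1).
#' @param dropout_rate dropout probability in [0, 1].
#' @param seed integer seed of the dedicated dropout RNG stream (independent
#'   of training seeds).
#' @return an `mc_dropout_config` object.
#' @export
mc_dropout_config <- function(T = 10L, dropout_rate = 0.5, seed = 1L) {
  if (T < 1) stop("T must be >= 1")
  stopifnot(dropout_rate >= 0, dropout_rate <= 1)
  structure(list(T = as.integer(T), dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "mc_dropout_config")
}

# Moments of a stack of softmax outputs across T passes: mean and the
# population (divisor T) standard deviation, per pixel and class. The
# variance is computed from deviations (two-pass) so that identical passes
# (dropout rate 0, or T = 1) give exactly zero, as the contract requires.
mc_moments <- function(prob_stack) {
  T <- length(prob_stack)
  d <- dim(prob_stack[[1]])
  s1 <- array(0, dim = d)
  for (p in prob_stack) s1 <- s1 + p
  mean_p <- s1 / T
  s2 <- array(0, dim = d)
  for (p in prob_stack) s2 <- s2 + (p - mean_p)^2
  list(mean = mean_p, std = sqrt(s2 / T))
}

#' Epistemic uncertainty maps via Monte Carlo Dropout
#'
#' Runs `T` seeded stochastic forward passes with dropout active before
#' every convolution, and summarizes the spread of the softmax outputs:
#' the per-pixel, per-class standard deviation (population convention,
#' divisor T) approximates the epistemic uncertainty of the Bayesian
#' predictive distribution; `mean_probs` is the Monte Carlo estimate of the
#' predictive distribution itself. The scalar per-image map is the standard
#' deviation of the softmax probability of the per-pixel predicted class
#' (argmax of `mean_probs`); the full per-class maps are always retained.
#'
#' @param model a `unet2_model` (dropout layers are present in every model).
#' @param brightfield H x W matrix, the bf-405nm channel.
#' @param config an [mc_dropout_config()].
#' @return an `uncertainty_map`: list with `per_class_std` (H x W x C),
#'   `scalar_map` (H x W), `mean_probs` (H x W x C), `mask`
#'   (argmax of the mean predictive distribution), `T`, `dropout_rate`.
#' @export
mc_dropout_predict <- function(model, brightfield, config = mc_dropout_config()) {
  stopifnot(inherits(model, "unet2_model"), inherits(config, "mc_dropout_config"))
  x <- normalize01(as.matrix(brightfield))
  n <- if (model$spec$linear) 1L else length(model$spec$enc)
  xa <- array(x, dim = c(nrow(x), ncol(x), model$config$in_channels))
  pad <- reflect_pad_to(xa, 2^(n - 1))
  ctx <- nn_ctx(drop_p = config$dropout_rate)
  if (config$dropout_rate == 0 || config$T == 1) {
    # all passes are identical: one forward pass, exactly zero spread
    fw <- with_seed(derive_seed(config$seed, "mcpass1"),
                    u2net_fw(model, pad$x, ctx))
    logits <- fw$d0[seq_len(pad$H), seq_len(pad$W), , drop = FALSE]
    p1 <- softmax_hwc(logits)
    mom <- list(mean = p1, std = array(0, dim = dim(p1)))
  } else {
    stack <- vector("list", config$T)
    for (t in seq_len(config$T)) {
      fw <- with_seed(derive_seed(config$seed, paste0("mcpass", t)),
                      u2net_fw(model, pad$x, ctx))
      logits <- fw$d0[seq_len(pad$H), seq_len(pad$W), , drop = FALSE]
      stack[[t]] <- softmax_hwc(logits)
    }
    mom <- mc_moments(stack)
  }
  pred <- argmax_hwc(mom$mean)
  d <- dim(mom$std)
  idx <- cbind(rep(seq_len(d[1]), d[2]),
               rep(seq_len(d[2]), each = d[1]),
               as.vector(pred) + 1L)
  scalar <- matrix(mom$std[idx], d[1], d[2])
  structure(list(per_class_std = mom$std, scalar_map = scalar,
                 mean_probs = mom$mean, mask = seg_mask(pred),
                 T = config$T, dropout_rate = config$dropout_rate),
            class = "uncertainty_map")
}
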