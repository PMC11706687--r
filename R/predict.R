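#' Segmentation mask object
#'
#' Per-pixel integer labels with the fixed class encoding
#' background(0), root(1), EEZ(2), LEZ(3), MZ(4).
#'
#' @param labels integer matrix with values in 0..4.
#' @return an object of class `seg_mask` (an integer matrix).
#' @export
seg_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (length(labels) && (min(labels) < 0L || max(labels) > 4L)) {
    stop("mask labels must lie in 0..4")
  }
  structure(labels, class = "seg_mask", class_names = names(ZONE_CLASSES))
}

#' @export
print.seg_mask <- function(x, ...) {
  tb <- table(factor(unclass(x), levels = ZONE_CLASSES,
                     labels = names(ZONE_CLASSES)))
  cat(sprintf("<seg_mask> %d x %d pixels\n", nrow(x), ncol(x)))
  print(tb)
  invisible(x)
}

# Reflect-pad a (H, W, C) array on the bottom/right to multiples of `m`.
reflect_pad_to <- function(x, m) {
  d <- dim(x)
  H2 <- ceiling(d[1] / m) * m
  W2 <- ceiling(d[2] / m) * m
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, H = d[1], W = d[2]))
  refl <- function(n, n2) {
    i <- seq_len(n2)
    i[i > n] <- 2 * n - i[i > n]   # mirror without repeating the edge
    i
  }
  list(x = x[refl(d[1], H2), refl(d[2], W2), , drop = FALSE], H = d[1], W = d[2])
}

#' Predict a segmentation from a brightfield image
#'
#' Runs a deterministic forward pass (dropout inactive) on the bf-405nm
#' channel. The input is min-max normalized to [0, 1]; sizes that do not fit
#' the pooling ladder are reflect-padded and the output cropped back. The
#' mask is the per-pixel argmax over class probabilities, ties broken toward
#' the lowest class index.
#'
#' @param object a `unet2_model`.
#' @param brightfield numeric matrix (H x W), the bf-405nm channel.
#' @param normalize min-max normalize the input (default TRUE).
#' @param ... unused.
#' @return a list with `prob_map` (class `class_prob_map`: `probs` and
#'   `logits`, both H x W x C arrays) and `mask` (a [seg_mask()]).
#' @export
predict.unet2_model <- function(object, brightfield, normalize = TRUE, ...) {
  x <- as.matrix(brightfield)
  if (normalize) x <- normalize01(x)
  n <- if (object$spec$linear) 1L else length(object$spec$enc)
  xa <- array(x, dim = c(nrow(x), ncol(x), object$config$in_channels))
  pad <- reflect_pad_to(xa, 2^(n - 1))
  fw <- u2net_fw(object, pad$x, nn_ctx())
  logits <- fw$d0[seq_len(pad$H), seq_len(pad$W), , drop = FALSE]
  probs <- softmax_hwc(logits)
  pm <- structure(list(probs = probs, logits = logits), class = "class_prob_map")
  list(prob_map = pm, mask = seg_mask(argmax_hwc(probs)))
}
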