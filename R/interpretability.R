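#' Class score for segmentation attribution
#'
#' The scalar explained by the attribution methods: the sum of the target
#' class's logits over exactly those pixels the model predicts as that class
#' (argmax equals the target). Pixels predicted as other classes contribute
#' nothing, which makes the score, and hence the attribution, class
#' discriminative.
#'
#' @param logits H x W x C logit array (or a `class_prob_map`).
#' @param predicted_mask the argmax [seg_mask()] from the same forward pass.
#' @param target_class integer class id (0..C-1).
#' @return scalar score (0 when no pixel is predicted as the target class).
#' @export
class_score <- function(logits, predicted_mask, target_class) {
  if (inherits(logits, "class_prob_map")) logits <- logits$logits
  d <- dim(logits)
  if (target_class < 0 || target_class >= d[3]) {
    stop("invalid class id: ", target_class)
  }
  sel <- unclass(predicted_mask) == target_class
  sum(logits[, , target_class + 1][sel])
}

# Gradient of class_score with respect to the logits.
class_score_grad <- function(logits_dim, predicted_mask, target_class) {
  g <- array(0, dim = logits_dim)
  plane <- matrix(0, logits_dim[1], logits_dim[2])
  plane[unclass(predicted_mask) == target_class] <- 1
  g[, , target_class + 1] <- plane
  g
}

# Shared preparation: normalized, padded input and a deterministic forward.
attr_forward <- function(model, image) {
  x <- normalize01(as.matrix(image))
  n <- if (model$spec$linear) 1L else length(model$spec$enc)
  xa <- array(x, dim = c(nrow(x), ncol(x), model$config$in_channels))
  pad <- reflect_pad_to(xa, 2^(n - 1))
  fw <- u2net_fw(model, pad$x, nn_ctx())
  logits <- fw$d0[seq_len(pad$H), seq_len(pad$W), , drop = FALSE]
  list(fw = fw, pad = pad, logits = logits,
       mask = seg_mask(argmax_hwc(softmax_hwc(logits))))
}

# Pad a cropped logit-space gradient back to the padded grid.
pad_grad <- function(g, full_dim) {
  gp <- array(0, dim = full_dim)
  gp[seq_len(dim(g)[1]), seq_len(dim(g)[2]), ] <- g
  gp
}

#' Guided Backpropagation map for one class
#'
#' The gradient of the masked class score with respect to the input image,
#' computed with the guided rule: negative gradients are blocked at every
#' ReLU during the backward pass, yielding a fine-grained map of the pixels
#' that would increase the class score the most.
#'
#' @param model a `unet2_model`.
#' @param image H x W brightfield matrix.
#' @param target_class integer class id (0..C-1).
#' @return H x W signed gradient map (all zero if no pixel is predicted as
#'   the target class).
#' @export
guided_backprop <- function(model, image, target_class) {
  af <- attr_forward(model, image)
  H <- nrow(as.matrix(image)); W <- ncol(as.matrix(image))
  if (!any(unclass(af$mask) == target_class)) return(matrix(0, H, W))
  g0 <- class_score_grad(dim(af$logits), af$mask, target_class)
  bw <- u2net_bw(model, af$fw, pad_grad(g0, dim(af$fw$d0)), nn_ctx(guided = TRUE))
  bw$gx[seq_len(H), seq_len(W), 1]
}

#' Grad-CAM map for one class
#'
#' Channel-wise weights are the spatially averaged gradients of the masked
#' class score at the chosen convolutional stage; the map is the ReLU of the
#' weighted activation sum, bilinearly upsampled to the input size. The
#' default layer is the final decoder stage's output ("de1"), the highest-
#' resolution semantic feature map; any stage name ("de1".."deK", "en1"..
#' "enN") can be selected.
#'
#' @param model a `unet2_model`.
#' @param image H x W brightfield matrix.
#' @param target_class integer class id.
#' @param layer stage name exposing activations (default "de1").
#' @return H x W non-negative map.
#' @export
grad_cam <- function(model, image, target_class, layer = "de1") {
  af <- attr_forward(model, image)
  if (!layer %in% names(af$fw$stage_out)) {
    stop("invalid attribution layer: ", layer, " (available: ",
         paste(names(af$fw$stage_out), collapse = ", "), ")")
  }
  H <- nrow(as.matrix(image)); W <- ncol(as.matrix(image))
  if (!any(unclass(af$mask) == target_class)) return(matrix(0, H, W))
  g0 <- class_score_grad(dim(af$logits), af$mask, target_class)
  bw <- u2net_bw(model, af$fw, pad_grad(g0, dim(af$fw$d0)), nn_ctx(),
                 cam_layer = layer)
  A <- af$fw$stage_out[[layer]]
  wts <- apply(bw$cam, 3, mean)
  cam <- array(0, dim = dim(A)[1:2])
  for (k in seq_along(wts)) cam <- cam + wts[k] * A[, , k]
  cam <- cam * (cam > 0)
  up <- .resize_bilinear_fw(array(cam, dim = c(dim(cam), 1L)),
                            dim(af$fw$d0)[1], dim(af$fw$d0)[2])
  up[seq_len(H), seq_len(W), 1]
}

#' Guided Grad-CAM attribution map
#'
#' Element-wise product of the Guided Backpropagation map (fine-grained,
#' signed) and the Grad-CAM map (coarse, class-discriminative, non-negative)
#' for one target class; both components are retained. Maps are exported
#' raw; any [0, 1] scaling is applied only for display.
#'
#' @inheritParams grad_cam
#' @return an `attribution_map`: list with `values` (H x W), `target_class`,
#'   and `components` (list with `guided_backprop`, `grad_cam`).
#' @export
guided_grad_cam <- function(model, image, target_class, layer = "de1") {
  af <- attr_forward(model, image)
  if (!layer %in% names(af$fw$stage_out)) {
    stop("invalid attribution layer: ", layer)
  }
  H <- nrow(as.matrix(image)); W <- ncol(as.matrix(image))
  empty <- !any(unclass(af$mask) == target_class)
  if (empty) {
    z <- matrix(0, H, W)
    return(structure(list(values = z, target_class = target_class,
                          components = list(guided_backprop = z, grad_cam = z)),
                     class = "attribution_map"))
  }
  g0 <- pad_grad(class_score_grad(dim(af$logits), af$mask, target_class),
                 dim(af$fw$d0))
  gbp <- u2net_bw(model, af$fw, g0, nn_ctx(guided = TRUE))$gx[seq_len(H), seq_len(W), 1]
  bw <- u2net_bw(model, af$fw, g0, nn_ctx(), cam_layer = layer)
  A <- af$fw$stage_out[[layer]]
  wts <- apply(bw$cam, 3, mean)
  cam <- array(0, dim = dim(A)[1:2])
  for (k in seq_along(wts)) cam <- cam + wts[k] * A[, , k]
  cam <- cam * (cam > 0)
  cam <- .resize_bilinear_fw(array(cam, dim = c(dim(cam), 1L)),
                             dim(af$fw$d0)[1], dim(af$fw$d0)[2])[seq_len(H), seq_len(W), 1]
  structure(list(values = gbp * cam, target_class = target_class,
                 components = list(guided_backprop = gbp, grad_cam = cam)),
            class = "attribution_map")
}
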