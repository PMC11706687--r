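#' Training and augmentation configuration
#'
#' Defaults follow the published training protocol where one is stated
#' (80/10/10 split; rotation up to 10 degrees, shift up to 26 px, scale
#' change up to 51 px, each applied independently with probability 0.5;
#' focal loss). Optimizer settings are plain configuration: Adam with
#' learning rate 1e-3 and focal gamma 2 by default.
#'
#' @param epochs number of training epochs (>= 1).
#' @param batch_size gradient-accumulation batch size.
#' @param learning_rate Adam learning rate.
#' @param focal_gamma focusing exponent of the focal loss.
#' @param augment an [augment_config()].
#' @param seed integer seed; all training randomness derives from it.
#' @param deterministic force seeded, order-stable execution (the package's
#'   kernels are single-threaded, so this yields bit-exact reproducibility).
#'   When FALSE, data order, augmentation draws and initialization are taken
#'   from the session RNG without seeding.
#' @param split train/val/test fractions summing to 1.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 74L, batch_size = 4L, learning_rate = 1e-3,
                         focal_gamma = 2, augment = augment_config(),
                         seed = 42L, deterministic = TRUE,
                         split = c(train = 0.8, val = 0.1, test = 0.1)) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, focal_gamma >= 0,
            abs(sum(split) - 1) < 1e-8)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, focal_gamma = focal_gamma,
                 augment = augment, seed = as.integer(seed),
                 deterministic = isTRUE(deterministic), split = split),
            class = "train_config")
}

#' @param max_rotation_deg maximum rotation in degrees.
#' @param max_shift_px maximum shift in pixels (each axis).
#' @param max_scale_px maximum linear size change of the crop/zoom in pixels.
#' @param per_op_probability probability of applying each operation.
#' @rdname train_config
#' @export
augment_config <- function(max_rotation_deg = 10, max_shift_px = 26,
                           max_scale_px = 51, per_op_probability = 0.5) {
  stopifnot(max_rotation_deg >= 0, max_shift_px >= 0, max_scale_px >= 0,
            per_op_probability >= 0, per_op_probability <= 1)
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_shift_px = max_shift_px, max_scale_px = max_scale_px,
                 per_op_probability = per_op_probability),
            class = "augment_config")
}

#' Split sample ids into train/validation/test sets
#'
#' Ids are sorted lexicographically, shuffled under the seed, and partitioned
#' with sizes floor(n * f); remainder ids are assigned to the training set.
#'
#' @param sample_ids unique sample identifiers.
#' @param fractions length-3 fractions (train, val, test) summing to 1.
#' @param seed integer seed for the shuffle.
#' @return a list with `train`, `val`, `test` id vectors.
#' @export
split_dataset <- function(sample_ids, fractions = c(0.8, 0.1, 0.1), seed = 42L) {
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n <- length(sample_ids)
  ids <- sort(as.character(sample_ids))
  ids <- with_seed(derive_seed(seed, "split"), sample(ids))
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test          # remainder goes to train
  out <- list(train = ids[seq_len(n_train)],
              val = ids[n_train + seq_len(n_val)],
              test = ids[n_train + n_val + seq_len(n_test)])
  if (any(lengths(out) == 0)) stop("a split subset is empty; use more samples")
  out
}

# Homogeneous 3x3 affine helpers (coordinates are 0-based (row, col)).
aff_translate <- function(dy, dx) matrix(c(1, 0, 0, 0, 1, 0, dy, dx, 1), 3, 3)
aff_rotate <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}
aff_scale <- function(s) matrix(c(s, 0, 0, 0, s, 0, 0, 0, 1), 3, 3)

#' Jointly augment an image and its mask
#'
#' Applies, each independently with `per_op_probability`: a rotation (up to
#' `max_rotation_deg`), a shift (up to `max_shift_px` per axis) and a
#' crop/zoom whose linear size change is at most `max_scale_px`, in that
#' fixed order. The identical geometric transform is applied to the image
#' (bilinear) and mask (nearest neighbour); the output size is unchanged and
#' out-of-view pixels are filled with 0 (background).
#'
#' @param image numeric matrix or (H, W, C) array.
#' @param mask a [seg_mask()] (or integer matrix) on the same pixel grid.
#' @param config an [augment_config()].
#' @param rng integer seed for the augmentation draws.
#' @return a list with the transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, config = augment_config(), rng = 1L) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  stopifnot(nrow(mask) == H, ncol(mask) == W)
  tr <- with_seed(rng, {
    list(rot = runif(1) < config$per_op_probability,
         theta = runif(1, -1, 1) * config$max_rotation_deg * pi / 180,
         shift = runif(1) < config$per_op_probability,
         dyx = runif(2, -1, 1) * config$max_shift_px,
         scale = runif(1) < config$per_op_probability,
         dpx = runif(1, -1, 1) * config$max_scale_px)
  })
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  Tm <- diag(3)
  if (tr$rot && config$max_rotation_deg > 0) {
    Tm <- aff_translate(cy, cx) %*% aff_rotate(tr$theta) %*%
      aff_translate(-cy, -cx) %*% Tm
  }
  if (tr$shift && config$max_shift_px > 0) {
    Tm <- aff_translate(tr$dyx[1], tr$dyx[2]) %*% Tm
  }
  if (tr$scale && config$max_scale_px > 0) {
    s <- (H + tr$dpx) / H
    Tm <- aff_translate(cy, cx) %*% aff_scale(s) %*% aff_translate(-cy, -cx) %*% Tm
  }
  Ainv <- solve(Tm)[1:2, , drop = FALSE]
  warp1 <- function(m, interp) .warp_affine(m, Ainv, interp, 0)
  if (length(d) == 3) {
    img_out <- array(0, dim = d)
    for (c in seq_len(d[3])) img_out[, , c] <- warp1(image[, , c], 1L)
  } else {
    img_out <- warp1(image, 1L)
  }
  mask_out <- warp1(matrix(as.double(mask), H, W), 0L)
  list(image = img_out, mask = seg_mask(mask_out))
}

#' Focal loss for pixel-wise multi-class predictions
#'
#' Mean over pixels of \eqn{-(1 - p_t)^\gamma \log p_t}, where \eqn{p_t} is
#' the predicted probability of the true class, floored at 1e-8 inside the
#' logarithm. With `gamma = 0` this is the mean cross-entropy.
#'
#' @param probs a `class_prob_map` or an (H, W, C) probability array.
#' @param target a [seg_mask()] (labels 0..C-1).
#' @param gamma non-negative focusing exponent.
#' @return non-negative scalar loss.
#' @export
focal_loss <- function(probs, target, gamma = 2) {
  if (inherits(probs, "class_prob_map")) probs <- probs$probs
  d <- dim(probs)
  P <- matrix(probs, ncol = d[3])
  t1 <- as.integer(target) + 1L
  stopifnot(length(t1) == nrow(P), all(t1 >= 1L), all(t1 <= d[3]))
  pt <- pmax(P[cbind(seq_along(t1), t1)], 1e-8)
  mean(-(1 - pt)^gamma * log(pt))
}

# Focal loss and its gradient with respect to the logits.
focal_loss_grad <- function(logits, target, gamma) {
  d <- dim(logits)
  probs <- softmax_hwc(logits)
  P <- matrix(probs, ncol = d[3])
  t1 <- as.integer(target) + 1L
  npix <- nrow(P)
  pt <- pmax(P[cbind(seq_len(npix), t1)], 1e-8)
  loss <- mean(-(1 - pt)^gamma * log(pt))
  dl_dpt <- if (gamma == 0) -1 / pt else {
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  }
  onehot <- matrix(0, npix, d[3])
  onehot[cbind(seq_len(npix), t1)] <- 1
  gz <- (dl_dpt * pt / npix) * (onehot - P)
  list(loss = loss, g = array(gz, dim = d), probs = probs)
}

#' Intersection-over-union for one class
#'
#' \eqn{|pred_c \cap truth_c| / |pred_c \cup truth_c|} on the binary per-class
#' masks. Returns `NA` (not evaluable) when the union is empty.
#'
#' @param pred,truth [seg_mask()] objects (or integer matrices) of equal shape.
#' @param class_id integer class id (0..4).
#' @return IoU in [0, 1], or `NA` if the class is absent from both masks.
#' @export
iou <- function(pred, truth, class_id) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  p <- unclass(pred) == class_id
  t <- unclass(truth) == class_id
  u <- sum(p | t)
  if (u == 0) return(NA_real_)
  sum(p & t) / u
}

#' Evaluate segmentation performance on a labeled dataset
#'
#' Per-class IoU is averaged over the images in which the class union is
#' non-empty; classes absent from every image are reported as `NA` and
#' excluded from the mean. `mean_iou` averages the specialized zone classes
#' (EEZ, LEZ, MZ), the model-selection metric; `mean_iou_all` averages all
#' five classes.
#'
#' @param model a `unet2_model`.
#' @param dataset list of samples, each a list with `x` (brightfield matrix)
#'   and `y` ([seg_mask()]).
#' @return an `iou_report`: list with `per_class_iou`, `mean_iou`,
#'   `mean_iou_all`, `n_images`.
#' @export
evaluate <- function(model, dataset) {
  if (length(dataset) == 0) stop("empty dataset")
  per_image <- vapply(dataset, function(s) {
    mask <- predict(model, s$x)$mask
    vapply(ZONE_CLASSES, function(cid) iou(mask, s$y, cid), numeric(1))
  }, numeric(length(ZONE_CLASSES)))
  per_class <- apply(per_image, 1, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(per_class) <- names(ZONE_CLASSES)
  spec_iou <- per_class[SPECIALIZED_ZONES]
  structure(list(per_class_iou = per_class,
                 mean_iou = mean(spec_iou, na.rm = TRUE),
                 mean_iou_all = mean(per_class, na.rm = TRUE),
                 n_images = length(dataset)),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report> %d images; mean IoU (EEZ/LEZ/MZ) = %.4f\n",
              x$n_images, x$mean_iou))
  print(round(x$per_class_iou, 4))
  invisible(x)
}

# One Adam update over the flat parameter list; state is updated in place
# (environment). Frozen arrays are skipped.
adam_step <- function(state, flat_params, flat_grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat_params)) {
    if (isTRUE(attr(flat_params[[nm]], "frozen"))) next
    gr <- flat_grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    flat_params[[nm]] <- flat_params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  flat_params
}

#' Train a segmentation model
#'
#' Optimizes the focal loss with Adam, accumulating gradients over
#' `batch_size` images. With `deterministic = TRUE` every random draw (data
#' order, augmentation) is taken from seeded streams and all numeric kernels
#' are order-stable, so two runs with the same configuration produce
#' bit-identical weights and metrics. The returned model carries the
#' parameters of the epoch with the best validation mean IoU (EEZ/LEZ/MZ).
#'
#' @param model a `unet2_model` (its dropout is inactive during training).
#' @param dataset named list of samples (`x` brightfield matrix, `y`
#'   [seg_mask()]); names are sample ids.
#' @param config a [train_config()].
#' @param val_dataset optional validation samples; if NULL, validation
#'   metrics are computed on the training set.
#' @return list with `model` (best checkpoint), `final_model` (last epoch),
#'   and `metrics` (one data.frame row per epoch).
#' @export
train <- function(model, dataset, config, val_dataset = NULL) {
  stopifnot(inherits(model, "unet2_model"), inherits(config, "train_config"))
  if (config$epochs < 1) stop("at least one epoch is required")
  if (length(dataset) == 0) stop("empty training dataset")
  if (is.null(val_dataset)) val_dataset <- dataset
  n <- length(dataset)
  xs <- lapply(dataset, function(s) normalize01(as.matrix(s$x)))
  ys <- lapply(dataset, function(s) s$y)
  npad <- if (model$spec$linear) 1L else length(model$spec$enc)
  padm <- 2^(npad - 1)

  flat <- flatten_params(model$params)
  state <- new.env(parent = emptyenv())
  state$t <- 0
  state$m <- lapply(flat, function(a) array(0, dim = dim(a) %||% length(a)))
  state$v <- state$m

  metrics <- list()
  best <- list(iou = -Inf, flat = flat)
  aug_on <- config$augment$per_op_probability > 0
  ctx <- nn_ctx()
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$deterministic) {
      with_seed(derive_seed(config$seed, paste0("order", epoch)), sample.int(n))
    } else sample.int(n)
    epoch_loss <- 0
    nb <- 0
    acc <- NULL
    model$params <- unflatten_params(flat, model$params)
    for (i in seq_along(ord)) {
      si <- ord[i]
      x <- xs[[si]]
      y <- ys[[si]]
      if (aug_on) {
        rs <- if (config$deterministic) {
          derive_seed(config$seed, paste0("aug", epoch, "_", i))
        } else sample.int(2^30, 1)
        a <- augment_pair(x, y, config$augment, rng = rs)
        x <- a$image
        y <- a$mask
      }
      xa <- array(x, dim = c(nrow(x), ncol(x), 1L))
      pad <- reflect_pad_to(xa, padm)
      fw <- u2net_fw(model, pad$x, ctx)
      logits <- fw$d0[seq_len(pad$H), seq_len(pad$W), , drop = FALSE]
      fl <- focal_loss_grad(logits, y, config$focal_gamma)
      if (!is.finite(fl$loss)) {
        stop(sprintf("divergent loss (%.4g) at epoch %d, sample %d", fl$loss, epoch, i))
      }
      epoch_loss <- epoch_loss + fl$loss
      gpad <- array(0, dim = dim(fw$d0))
      gpad[seq_len(pad$H), seq_len(pad$W), ] <- fl$g
      bw <- u2net_bw(model, fw, gpad, ctx)
      gflat <- flatten_params(bw$g)
      acc <- if (is.null(acc)) gflat else {
        Map(function(a, b) a + b, acc, gflat)
      }
      nb <- nb + 1
      if (nb == config$batch_size || i == length(ord)) {
        acc <- lapply(acc, function(a) a / nb)
        flat <- adam_step(state, flat, acc[names(flat)], config$learning_rate)
        model$params <- unflatten_params(flat, model$params)
        acc <- NULL
        nb <- 0
      }
    }
    model$params <- unflatten_params(flat, model$params)
    rep_val <- evaluate(model, val_dataset)
    row <- data.frame(epoch = epoch, loss = epoch_loss / n,
                      mean_iou = rep_val$mean_iou,
                      mean_iou_all = rep_val$mean_iou_all)
    for (cn in names(ZONE_CLASSES)) {
      row[[paste0("iou_", cn)]] <- rep_val$per_class_iou[[cn]]
    }
    metrics[[epoch]] <- row
    if (is.finite(rep_val$mean_iou) && rep_val$mean_iou > best$iou) {
      best <- list(iou = rep_val$mean_iou, flat = flat)
    }
  }
  final_model <- model
  model$params <- unflatten_params(best$flat, model$params)
  list(model = model, final_model = final_model,
       metrics = do.call(rbind, metrics))
}
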