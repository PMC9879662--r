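#' Training hyperparameters
#'
#' The three quantities searched by the genetic tuner: learning rate in
#' `(0, 1]`, epoch count and batch size (both positive integers).
#'
#' @param learning_rate SGD step size.
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @return an object of class `"hyperparameters"`.
#' @export
hyperparameters <- function(learning_rate, epochs, batch_size) {
  lr <- as.numeric(learning_rate)
  if (!is.finite(lr) || lr <= 0 || lr > 1)
    stop_config("learning_rate must lie in (0, 1], got ", learning_rate)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (is.na(epochs) || epochs < 1L) stop_config("epochs must be >= 1")
  if (is.na(batch_size) || batch_size < 1L)
    stop_config("batch_size must be >= 1")
  structure(list(learning_rate = lr, epochs = epochs,
                 batch_size = batch_size), class = "hyperparameters")
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat(sprintf("<hyperparameters> lr = %g, epochs = %d, batch = %d\n",
              x$learning_rate, x$epochs, x$batch_size))
  invisible(x)
}

#' Intersection over union of two binary masks
#'
#' The Jaccard index `|U intersect V| / |U union V|` over foreground pixels.
#' When both masks are empty the ratio is 0/0 and is pinned to 1 (two empty
#' segmentations agree perfectly).
#'
#' @param u,v binary masks (matrices or arrays of 0/1) of identical shape.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
#' n <- matrix(0, 4, 4); n[1:2, 2:3] <- 1
#' iou(m, n)  # 2/6
iou <- function(u, v) {
  if (!identical(dim(u), dim(v)))
    stop_config("masks must have identical dimensions")
  if (any(u != 0 & u != 1) || any(v != 0 & v != 1))
    stop_config("masks must be binary (0/1)")
  union <- sum(u == 1 | v == 1)
  if (union == 0) return(1)
  sum(u == 1 & v == 1) / union
}

# Stable pixelwise binary cross-entropy on logits; gradient is mean-scaled.
bce_logits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  list(loss = loss, grad = (stats::plogis(z) - y) / n)
}

# Soft Dice on probabilities (optional loss term)
dice_soft <- function(p, y, eps = 1) {
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  denom <- sp + sy + eps
  dice <- (2 * spy + eps) / denom
  grad_p <- -(2 * y * denom - (2 * spy + eps)) / denom^2
  list(loss = 1 - dice, grad_p = grad_p)
}

sample_loss_grad <- function(model, sample, dice_weight = 0) {
  fwd <- forward_one(model, sample$image, keep = TRUE)
  z <- fwd$out
  y <- array(sample$mask, dim = dim(z))
  bce <- bce_logits(z, y)
  loss <- bce$loss
  gz <- bce$grad
  if (dice_weight > 0) {
    p <- stats::plogis(z)
    dc <- dice_soft(p, y)
    loss <- loss + dice_weight * dc$loss
    gz <- gz + dice_weight * dc$grad_p * p * (1 - p)
  }
  list(loss = loss, fwd = fwd, gz = gz)
}

#' Train a segmentation network with plain SGD
#'
#' Minimises pixelwise binary cross-entropy (optionally mixed with a soft
#' Dice term) by stochastic gradient descent at exactly the given learning
#' rate — no momentum or adaptive scaling, so the learning-rate gene of the
#' genetic tuner is the sole step-size control. Minibatch order is reshuffled
#' every epoch from the run seed; identical inputs and seed reproduce the
#' trajectory bit for bit on a given platform.
#'
#' @param model a `"segnet"` from [build_model()] (left untouched; the
#'   updated copy is returned inside the fit).
#' @param train_samples,val_samples non-empty lists of samples
#'   (`list(image=, mask=, sample_id=)`, as produced by
#'   [generate_dataset()]).
#' @param hp a [hyperparameters()] object; `batch_size` must not exceed the
#'   training-set size.
#' @param seed integer seed for minibatch shuffling.
#' @param dice_weight weight of the optional soft-Dice loss term (0 = plain
#'   binary cross-entropy).
#' @param threshold binarisation threshold used for the validation IoU.
#' @return an object of class `"segnet_fit"`: the trained model plus
#'   `per_epoch_loss` (mean training loss per epoch, length `hp$epochs`),
#'   `final_val_loss`, `val_iou` and the trained `weights_digest`.
#' @export
train_segnet <- function(model, train_samples, val_samples, hp, seed = 1L,
                         dice_weight = 0, threshold = 0.5) {
  if (!inherits(model, "segnet")) stop_config("model must be a segnet")
  if (!length(train_samples) || !length(val_samples))
    stop_config("train and validation sets must be non-empty")
  if (!inherits(hp, "hyperparameters")) hp <- do.call(hyperparameters, hp)
  n <- length(train_samples)
  if (hp$batch_size > n)
    stop_config("batch_size (", hp$batch_size,
                ") exceeds training-set size (", n, ")")
  per_epoch <- numeric(hp$epochs)
  with_seed(seed, {
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1L, n)]
        total <- NULL
        bl <- 0
        for (i in idx) {
          sl <- sample_loss_grad(model, train_samples[[i]], dice_weight)
          total <- accumulate_pgrads(total,
                                     backward_graph(model, sl$fwd, sl$gz))
          bl <- bl + sl$loss
        }
        model <- sgd_update(model, total, hp$learning_rate,
                            scale = 1 / length(idx))
        losses <- c(losses, bl / length(idx))
      }
      per_epoch[ep] <- mean(losses)
    }
  })
  val_loss <- mean(vapply(val_samples, function(s) {
    z <- forward_one(model, s$image)$out
    bce_logits(z, array(s$mask, dim = dim(z)))$loss
  }, 0))
  fit <- structure(list(model = model, hp = hp, seed = seed,
                        per_epoch_loss = per_epoch,
                        final_val_loss = val_loss,
                        val_iou = evaluate_model(model, val_samples,
                                                 threshold = threshold),
                        weights_digest = weights_digest(model)),
                   class = "segnet_fit")
  fit
}

#' Binarise a model's probability map
#'
#' A pixel is foreground iff its predicted probability strictly exceeds
#' `threshold` (ties go to background, a fixed deterministic rule).
#'
#' @param model a `"segnet"` or `"segnet_fit"`.
#' @param image `H x W` intensity matrix.
#' @param threshold number in `(0, 1)`.
#' @return binary `H x W` mask.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (inherits(model, "segnet_fit")) model <- model$model
  if (threshold <= 0 || threshold >= 1)
    stop_config("threshold must lie in (0, 1)")
  (forward(model, image) > threshold) * 1
}

#' Mean IoU of a model over a sample set
#'
#' @param model a `"segnet"` or `"segnet_fit"`.
#' @param samples non-empty list of samples with `image` and `mask`.
#' @param threshold binarisation threshold.
#' @return mean of per-sample [iou()] values.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  if (!length(samples)) stop_config("cannot evaluate on an empty sample set")
  if (inherits(model, "segnet_fit")) model <- model$model
  mean(vapply(samples, function(s)
    iou(s$mask, predict_mask(model, s$image, threshold)), 0))
}

# ---- segnet_fit methods ----------------------------------------------------

#' @export
print.segnet_fit <- function(x, ...) {
  cat(sprintf(
    "<segnet_fit> %s | lr %g, %d epochs, batch %d | val loss %.4f, val IoU %.3f\n",
    x$model$spec$family, x$hp$learning_rate, x$hp$epochs, x$hp$batch_size,
    x$final_val_loss, x$val_iou))
  invisible(x)
}

#' @export
summary.segnet_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %s | weights digest: %s...\n",
              format(graph_param_count(object$model), big.mark = ","),
              substr(object$weights_digest, 1L, 16L)))
  cat(sprintf("  training loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              object$per_epoch_loss[1L],
              object$per_epoch_loss[length(object$per_epoch_loss)],
              length(object$per_epoch_loss)))
  invisible(object)
}

#' @export
predict.segnet_fit <- function(object, images, ...) {
  predict(object$model, images, ...)
}

#' @export
coef.segnet_fit <- function(object, ...) {
  unlist(lapply(object$model$nodes, function(nd)
    if (is.null(nd$param)) NULL else c(nd$param$W, nd$param$b)),
    use.names = FALSE)
}

#' @export
plot.segnet_fit <- function(x, ...) {
  graphics::plot(seq_along(x$per_epoch_loss), x$per_epoch_loss, type = "b",
                 xlab = "epoch", ylab = "mean training loss",
                 main = sprintf("%s training trajectory", x$model$spec$family),
                 ...)
  invisible(x)
}
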