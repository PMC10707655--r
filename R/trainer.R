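#' Pixelwise binary cross-entropy segmentation loss
#'
#' Mean per-pixel binary cross-entropy (in nats) between a predicted
#' instrument-probability map and a binary mask. Probabilities are clamped
#' to `[eps, 1 - eps]` for numerical safety.
#'
#' @param seg_prob Matrix of probabilities in `[0, 1]`.
#' @param tool_mask Binary matrix of the same dimensions.
#' @param eps Clamp applied to the probabilities.
#' @return Non-negative scalar loss in nats.
#' @examples
#' seg_loss(matrix(0.5, 4, 4), matrix(0, 4, 4))  # log(2)
#' @export
seg_loss <- function(seg_prob, tool_mask, eps = 1e-7) {
  if (!identical(dim(seg_prob), dim(tool_mask))) {
    stop_validation("seg_prob and tool_mask dimensions differ")
  }
  p <- pmin(pmax(as.numeric(seg_prob), eps), 1 - eps)
  m <- as.numeric(tool_mask)
  -mean(m * log(p) + (1 - m) * log(1 - p))
}

#' Cross-entropy event-detection loss
#'
#' Negative log probability assigned to the true class (in nats).
#'
#' @param cls_prob Length-2 probability vector `(p_no_blood, p_blood)`;
#'   must sum to 1 within `1e-6`.
#' @param blood_label True class, 0 or 1.
#' @param eps Clamp applied to the probability of the true class.
#' @return Non-negative scalar loss in nats.
#' @examples
#' cls_loss(c(0.5, 0.5), 0)       # log(2)
#' cls_loss(c(0.9, 0.1), 1)       # -log(0.1)
#' @export
cls_loss <- function(cls_prob, blood_label, eps = 1e-7) {
  if (length(cls_prob) != 2 || any(cls_prob < 0) ||
      abs(sum(cls_prob) - 1) > 1e-6) {
    stop_validation("cls_prob must be a normalized length-2 probability vector")
  }
  if (!blood_label %in% c(0, 1)) stop_validation("blood_label must be 0 or 1")
  -log(pmin(pmax(cls_prob[[blood_label + 1]], eps), 1 - eps))
}

#' Multi-task loss: unweighted sum of both branch losses
#'
#' `total = seg_loss + cls_loss`, with the components reported separately.
#'
#' @inheritParams seg_loss
#' @inheritParams cls_loss
#' @return A `loss_breakdown` list with `seg_loss`, `cls_loss`, `total`.
#' @export
multi_task_loss <- function(seg_prob, tool_mask, cls_prob, blood_label,
                            eps = 1e-7) {
  s <- seg_loss(seg_prob, tool_mask, eps)
  c <- cls_loss(cls_prob, blood_label, eps)
  structure(list(seg_loss = s, cls_loss = c, total = s + c),
            class = "loss_breakdown")
}

#' Tally classification outcomes
#'
#' @param predicted Integer vector of predicted classes (0/1).
#' @param truth Integer vector of true classes (0/1).
#' @return A `metric_counts` list: `correct_predictions`, `samples`,
#'   `per_class_correct`, `per_class_total` (named "0", "1").
#' @export
metric_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_validation("predicted and truth lengths differ")
  }
  classes <- c("0", "1")
  per_total <- vapply(c(0, 1), function(k) sum(truth == k), numeric(1))
  per_correct <- vapply(c(0, 1), function(k) {
    sum(truth == k & predicted == truth)
  }, numeric(1))
  names(per_total) <- names(per_correct) <- classes
  structure(list(
    correct_predictions = sum(predicted == truth),
    samples = length(truth),
    per_class_correct = per_correct,
    per_class_total = per_total
  ), class = "metric_counts")
}

#' Classification accuracy
#'
#' Overall accuracy is `correct_predictions / samples`; per-class
#' accuracies divide the per-class tallies.
#'
#' @param counts A `metric_counts` object ([metric_counts()]).
#' @return List with `accuracy` (fraction) and `per_class` (named numeric
#'   vector; `NA` for classes with no samples).
#' @examples
#' classification_accuracy(metric_counts(c(1, 1, 0), c(1, 0, 0)))
#' @export
classification_accuracy <- function(counts) {
  stopifnot(inherits(counts, "metric_counts"))
  if (counts$samples == 0) {
    stop_validation("accuracy undefined for zero samples")
  }
  per <- ifelse(counts$per_class_total > 0,
                counts$per_class_correct / counts$per_class_total, NA_real_)
  names(per) <- names(counts$per_class_total)
  list(accuracy = counts$correct_predictions / counts$samples,
       per_class = per)
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param selection_epoch Epoch whose weights become the selected model
#'   (defaults to the final epoch).
#' @param rng_seed Seed controlling shuffling (weight initialisation is
#'   seeded in [build_network()]).
#' @param val_fraction Fraction held out for validation when the dataset
#'   is not pre-split (stratified by class).
#' @param eps Probability clamp inside both cross-entropies.
#' @param verbose Print one line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30, batch_size = 16, learning_rate = 1e-3,
                         selection_epoch = epochs, rng_seed = 1L,
                         val_fraction = 0.2, eps = 1e-7, verbose = FALSE) {
  if (selection_epoch > epochs) {
    stop_validation("selection_epoch (%d) must be <= epochs (%d)",
                    selection_epoch, epochs)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 selection_epoch = as.integer(selection_epoch),
                 rng_seed = as.integer(rng_seed),
                 val_fraction = val_fraction, eps = eps, verbose = verbose),
            class = "train_config")
}

samples_to_arrays <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], n))
  m <- array(0, dim = c(d[1], d[2], n))
  y <- integer(n)
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    m[, , i] <- samples[[i]]$tool_mask
    y[i] <- samples[[i]]$blood_label
  }
  list(x = x, mask = m, label = y)
}

adam_init <- function(weights) {
  lapply(weights, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                   mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(weights, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (nm in names(weights)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    weights[[nm]]$W <- weights[[nm]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    weights[[nm]]$b <- weights[[nm]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

# Predicted class per validation frame, evaluated in modest batches to
# bound memory.
predict_classes <- function(weights, ecfg, val, chunk = 25L) {
  n <- dim(val$x)[4]
  preds <- integer(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out <- eng_forward(weights, ecfg, val$x[, , , idx, drop = FALSE])
    preds[idx] <- as.integer(out$cls[2, ] > out$cls[1, ])
  }
  preds
}

#' Train the multi-task network
#'
#' Minimises the unweighted multi-task loss (pixelwise binary
#' cross-entropy for segmentation plus cross-entropy for event detection)
#' with Adam. Records per-epoch training losses and validation
#' event-detection accuracy (overall and per class), and returns the
#' weights as of `selection_epoch`.
#'
#' @param net An `mtl_net` from [build_network()].
#' @param dataset Either a list of `frame_sample` objects (split
#'   internally, stratified by class) or a list with elements `train` and
#'   `val`, each a list of `frame_sample` objects.
#' @param config A [train_config()].
#' @return An `mtl_fit` list: `network` (selected weights), `history`
#'   (data frame: epoch, train_total, train_seg, train_cls, val_accuracy,
#'   val_acc_class0, val_acc_class1), `selection_epoch`, `final_network`.
#' @export
train_network <- function(net, dataset, config = train_config()) {
  stopifnot(inherits(net, "mtl_net"), inherits(config, "train_config"))
  if (!is.null(dataset$train)) {
    train_s <- dataset$train
    val_s <- dataset$val
  } else {
    if (length(dataset) == 0) stop_validation("empty dataset")
    labels <- vapply(dataset, `[[`, integer(1), "blood_label")
    val_idx <- with_seed(derive_seed(config$rng_seed, 777L), {
      unlist(lapply(c(0, 1), function(k) {
        ids <- which(labels == k)
        sample(ids, size = round(config$val_fraction * length(ids)))
      }))
    })
    train_s <- dataset[setdiff(seq_along(dataset), val_idx)]
    val_s <- dataset[val_idx]
  }
  if (length(train_s) == 0 || length(val_s) == 0) {
    stop_validation("empty train/validation split")
  }
  tr <- samples_to_arrays(train_s)
  va <- samples_to_arrays(val_s)
  ecfg <- engine_cfg(net$config)
  weights <- net$weights
  state <- adam_init(weights)
  n_tr <- dim(tr$x)[4]
  history <- data.frame(epoch = integer(0), train_total = numeric(0),
                        train_seg = numeric(0), train_cls = numeric(0),
                        val_accuracy = numeric(0),
                        val_acc_class0 = numeric(0),
                        val_acc_class1 = numeric(0))
  selected <- NULL
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$rng_seed, ep), sample.int(n_tr))
    ep_seg <- ep_cls <- 0
    n_batches <- 0L
    for (start in seq(1, n_tr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      res <- eng_train_batch(weights, ecfg,
                             tr$x[, , , idx, drop = FALSE],
                             tr$mask[, , idx, drop = FALSE],
                             tr$label[idx], config$eps)
      step <- step + 1L
      upd <- adam_step(weights, res$grads, state, config$learning_rate, step)
      weights <- upd$weights
      state <- upd$state
      ep_seg <- ep_seg + res$seg_loss
      ep_cls <- ep_cls + res$cls_loss
      n_batches <- n_batches + 1L
    }
    preds <- predict_classes(weights, ecfg, va)
    acc <- classification_accuracy(metric_counts(preds, va$label))
    seg_ep <- ep_seg / n_batches
    cls_ep <- ep_cls / n_batches
    history[ep, ] <- list(ep, seg_ep + cls_ep, seg_ep, cls_ep,
                          acc$accuracy, acc$per_class[["0"]],
                          acc$per_class[["1"]])
    if (config$verbose) {
      message(sprintf("epoch %2d  loss %.4f (seg %.4f cls %.4f)  val acc %.4f",
                      ep, (ep_seg + ep_cls) / n_batches, ep_seg / n_batches,
                      ep_cls / n_batches, acc$accuracy))
    }
    if (ep == config$selection_epoch) {
      selected <- weights
    }
  }
  structure(list(
    network = structure(list(config = net$config, weights = selected),
                        class = "mtl_net"),
    final_network = structure(list(config = net$config, weights = weights),
                              class = "mtl_net"),
    history = history,
    selection_epoch = config$selection_epoch
  ), class = "mtl_fit")
}

#' @export
print.mtl_fit <- function(x, ...) {
  n <- nrow(x$history)
  sel <- x$history[x$selection_epoch, ]
  cat(sprintf("Multi-task training: %d epochs, model selected at epoch %d\n",
              n, x$selection_epoch))
  cat(sprintf("  selected-epoch validation accuracy: %.2f%% (class 0: %.2f%%, class 1: %.2f%%)\n",
              100 * sel$val_accuracy, 100 * sel$val_acc_class0,
              100 * sel$val_acc_class1))
  invisible(x)
}

#' @export
plot.mtl_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$train_total, type = "l", xlab = "epoch",
       ylab = "training loss (nats)", main = "Multi-task training loss")
  plot(x$history$epoch, x$history$val_accuracy, type = "l", xlab = "epoch",
       ylab = "validation accuracy", ylim = c(0, 1),
       main = "Event-detection accuracy")
  invisible(x)
}

#' Write a training history CSV
#'
#' @param fit An `mtl_fit`.
#' @param path Output CSV path.
#' @export
write_history <- function(fit, path) {
  stopifnot(inherits(fit, "mtl_fit"))
  tryCatch(write.csv(fit$history, path, row.names = FALSE),
           error = function(e) stop_io("cannot write history: %s",
                                       conditionMessage(e)))
  invisible(path)
}
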