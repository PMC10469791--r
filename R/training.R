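#' Training configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 1e-4,
#' up to 800 epochs with minibatches of 32, early stopping when the
#' validation loss has not strictly decreased for 100 consecutive epochs,
#' best-validation-loss weights restored.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param patience_epochs early-stopping patience (must be <= `max_epochs`).
#' @param seed seed controlling shuffling and dropout.
#' @param shuffle reshuffle the training set every epoch.
#' @param verbose print one line per epoch.
#' @return An object of class `lgct_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 800L,
                         batch_size = 32L, patience_epochs = 100L,
                         seed = 1L, shuffle = TRUE, verbose = FALSE) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, batch_size >= 1L,
            patience_epochs >= 1L)
  if (patience_epochs > max_epochs)
    stop("patience_epochs must be <= max_epochs")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "lgct_train_config")
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-sum_m y_true[m] * log(y_pred[m])`. Predicted
#' probabilities are clamped below at 1e-12 before the logarithm.
#'
#' @param y_pred numeric matrix (rows = trials, columns = class
#'   probabilities summing to 1) or a single probability vector.
#' @param y_true matching one-hot matrix/vector, or an integer vector of
#'   0-based class labels.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(y_pred, y_true) {
  if (is.null(dim(y_pred))) y_pred <- matrix(y_pred, nrow = 1L)
  if (is.null(dim(y_true)) && length(y_true) == ncol(y_pred) &&
      nrow(y_pred) == 1L && any(y_true == 1)) {
    y_true <- matrix(y_true, nrow = 1L)
  } else if (is.null(dim(y_true))) {
    y_true <- onehot(as.integer(y_true), ncol(y_pred))
  }
  stopifnot(all(dim(y_pred) == dim(y_true)))
  -mean(rowSums(y_true * log(pmax(y_pred, 1e-12))))
}

onehot <- function(labels, n_classes) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Predict class probabilities and labels
#'
#' Evaluation mode (dropout off, batch-norm running statistics), so repeated
#' calls are bit-identical. Labels are the row-wise argmax with the lowest
#' class index winning ties.
#'
#' @param model a built (optionally trained) `lgct_model`.
#' @param data an `lgct_multiband` input.
#' @param batch_size forward-pass chunk size (memory control only; does not
#'   affect values).
#' @return A list with `probs` (trials x classes matrix, rows sum to 1) and
#'   `labels` (0-based integer vector).
#' @export
predict_model <- function(model, data, batch_size = 64L) {
  stopifnot(inherits(data, "lgct_multiband"))
  bands <- lapply(data$epochs, function(e) aperm(e$data, c(3L, 2L, 1L)))
  if (dim(bands[[1L]])[2L] != model$cfg$n_channels ||
      dim(bands[[1L]])[1L] != model$cfg$n_samples)
    stop("input dimensions (", dim(bands[[1L]])[2L], " ch x ",
         dim(bands[[1L]])[1L], " samples) do not match model config")
  N <- dim(bands[[1L]])[3L]
  probs <- matrix(0, N, model$cfg$n_classes)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    chunk <- lapply(bands, function(b) b[, , idx, drop = FALSE])
    probs[idx, ] <- model_forward_core(model, chunk, training = FALSE)$probs
  }
  list(probs = probs, labels = max.col(probs, ties.method = "first") - 1L)
}

#' Train a model with Adam and early stopping
#'
#' Minibatch Adam with a seeded shuffle each epoch. After every epoch the
#' validation loss is computed in evaluation mode; any strict decrease resets
#' the patience counter. Training stops when the validation loss has not
#' improved for `patience_epochs` consecutive epochs (or at `max_epochs`),
#' and the weights of the best-validation-loss epoch are restored.
#'
#' @param model a freshly built `lgct_model`.
#' @param train_set,val_set lists with `data` (an `lgct_multiband`) and
#'   `labels` (0-based integers). The validation set must be non-empty.
#' @param cfg a [train_config()].
#' @return A list with `model` (best weights) and `history` (data.frame with
#'   per-epoch `epoch`, `train_loss`, `val_loss`, `val_acc`, `patience`;
#'   attributes `best_epoch`, `stopped_epoch`).
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(cfg, "lgct_train_config"))
  if (is.null(val_set) || length(val_set$labels) == 0L)
    stop("empty validation set: early stopping is undefined without one")
  bands_tr <- lapply(train_set$data$epochs,
                     function(e) aperm(e$data, c(3L, 2L, 1L)))
  y_tr <- as.integer(train_set$labels)
  n_tr <- length(y_tr)
  Y_tr <- onehot(y_tr, model$cfg$n_classes)
  set.seed(cfg$seed)
  adam <- adam_state_new(model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric(),
                     patience = integer())
  best <- list(loss = Inf, epoch = 0L, model = NULL)
  wait <- 0L
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- if (cfg$shuffle) sample.int(n_tr) else seq_len(n_tr)
    batch_losses <- c()
    for (start in seq(1L, n_tr, by = cfg$batch_size)) {
      idx <- order_idx[start:min(start + cfg$batch_size - 1L, n_tr)]
      chunk <- lapply(bands_tr, function(b) b[, , idx, drop = FALSE])
      fwd <- model_forward_core(model, chunk, training = TRUE,
                                keep_cache = TRUE)
      Y <- Y_tr[idx, , drop = FALSE]
      batch_losses <- c(batch_losses, cross_entropy(fwd$probs, Y))
      genv <- new.env(parent = emptyenv())
      dlogits <- (fwd$probs - Y) / length(idx)
      model_backward_core(model, dlogits, fwd$cache, genv)
      upd <- adam_step(model$params, as.list(genv), adam, cfg$learning_rate)
      model$params <- upd$params
      adam <- upd$state
    }
    val_pred <- predict_model(model, val_set$data)
    val_loss <- cross_entropy(val_pred$probs,
                              onehot(as.integer(val_set$labels),
                                     model$cfg$n_classes))
    val_acc <- mean(val_pred$labels == as.integer(val_set$labels))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch,
                   model = snapshot_model(model))
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(batch_losses),
                                   val_loss = val_loss, val_acc = val_acc,
                                   patience = wait))
    if (cfg$verbose)
      lgct_log("INFO", sprintf(
        "epoch %d  train_loss %.4f  val_loss %.4f  val_acc %.3f  patience %d",
        epoch, mean(batch_losses), val_loss, val_acc, wait))
    if (wait >= cfg$patience_epochs) {
      stopped <- epoch
      break
    }
  }
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopped_epoch") <- stopped
  list(model = best$model, history = hist)
}

#' Classification accuracy (%)
#' @param labels_pred,labels_true 0-based label vectors.
#' @return Accuracy in percent.
#' @export
accuracy <- function(labels_pred, labels_true) {
  100 * mean(as.integer(labels_pred) == as.integer(labels_true))
}

#' @export
predict.lgct_model <- function(object, data, ...) {
  predict_model(object, data)
}
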