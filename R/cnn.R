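#' Architecture specification of the 1D convolutional network
#'
#' Four feature-extraction blocks, each convolution (stride 1, same
#' padding) -> batch normalization -> ReLU -> max pooling (window 2,
#' stride 2), followed by flatten and three fully connected layers; FC1 and
#' FC2 are each followed by ReLU, batch normalization and dropout. Kernel
#' counts/sizes default to 16/32/64/128 channels with kernels 21/11/5/3:
#' large kernels early capture broad spectral context, small kernels late
#' resolve individual bands. Because convolutions preserve length, the
#' length after block `b` is `floor(L/2)` of its input; e.g. a 2046-point
#' spectrum maps to 1023, 511, 255, 127, giving a flattened feature of
#' 127 x 128 = 16256.
#'
#' @param input_length Spectrum length fed to the network (default 2046).
#' @param block_channels Four convolution channel counts.
#' @param block_kernels Four odd kernel sizes.
#' @param fc_sizes Widths of FC1 and FC2 (default 256, 64).
#' @param dropout_p Dropout probability after FC1/FC2 (default 0.7).
#' @param n_classes Number of output classes (default 4).
#' @param output_activation `"softmax"` (default: mutually exclusive class
#'   probabilities) or `"log_sigmoid"` (literal per-class log-sigmoid
#'   output; reported scores are the exponentiated values, i.e. sigmoids).
#' @return An object of class `model_spec`; `$block_lengths` traces the
#'   per-block output lengths and `$flatten` the flattened feature size.
#' @export
model_spec <- function(input_length = 2046L,
                       block_channels = c(16L, 32L, 64L, 128L),
                       block_kernels = c(21L, 11L, 5L, 3L),
                       fc_sizes = c(256L, 64L),
                       dropout_p = 0.7,
                       n_classes = 4L,
                       output_activation = c("softmax", "log_sigmoid")) {
  output_activation <- match.arg(output_activation)
  stopifnot(length(block_channels) == 4L, length(block_kernels) == 4L,
            all(block_kernels %% 2L == 1L), length(fc_sizes) == 2L,
            dropout_p >= 0, dropout_p < 1, n_classes >= 2L)
  L <- as.integer(input_length)
  lens <- integer(4L)
  for (b in seq_len(4L)) {
    if (L < 2L)
      stop("input_length ", input_length,
           " too short: block ", b, " receives length ", L,
           " and cannot be max-pooled", call. = FALSE)
    L <- L %/% 2L
    lens[b] <- L
  }
  structure(list(input_length = as.integer(input_length),
                 block_channels = as.integer(block_channels),
                 block_kernels = as.integer(block_kernels),
                 fc_sizes = as.integer(fc_sizes),
                 dropout_p = dropout_p,
                 n_classes = as.integer(n_classes),
                 output_activation = output_activation,
                 block_lengths = lens,
                 flatten = lens[4L] * as.integer(block_channels[4L])),
            class = "model_spec")
}

#' Training configuration
#'
#' The training recipe: rectified Adam (RAdam) at learning rate 1e-4, batch
#' size 128, class-weighted cross-entropy to counter the 30/30/30/20 group
#' imbalance, and best-validation-accuracy model selection.
#'
#' @param learning_rate RAdam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Training epochs (default 300).
#' @param class_weight_mode `"inverse_frequency"` (default: weights
#'   proportional to `N/n_c`, mean 1, up-weighting rare classes),
#'   `"literal_frequency"` (`n_c/N`), or `"none"`.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         max_epochs = 300L,
                         class_weight_mode = c("inverse_frequency",
                                               "literal_frequency", "none"),
                         seed = 1L) {
  class_weight_mode <- match.arg(class_weight_mode)
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 class_weight_mode = class_weight_mode,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Per-class loss weights
#'
#' @param labels Factor (or character) of class labels, every class
#'   represented.
#' @param mode `"inverse_frequency"`: `N/n_c` renormalized to mean 1;
#'   `"literal_frequency"`: the class frequency `n_c/N` itself;
#'   `"none"`: all ones.
#' @param classes Class order for the returned vector.
#' @return Named numeric weight vector in `classes` order.
#' @export
class_weights <- function(labels,
                          mode = c("inverse_frequency", "literal_frequency",
                                   "none"),
                          classes = sers_classes()) {
  mode <- match.arg(mode)
  labels <- factor(as.character(labels), levels = classes)
  n_c <- table(labels)
  if (any(n_c == 0))
    stop("class(es) with no labels: ",
         paste(names(n_c)[n_c == 0], collapse = ", "), call. = FALSE)
  w <- switch(mode,
              literal_frequency = as.numeric(n_c) / sum(n_c),
              inverse_frequency = {
                v <- sum(n_c) / as.numeric(n_c)
                v / mean(v)
              },
              none = rep(1, length(n_c)))
  names(w) <- classes
  w
}

set_to_xy <- function(x, spec, need_labels = TRUE, classes = sers_classes()) {
  if (n_points(x) != spec$input_length)
    stop("spectra length ", n_points(x), " does not match model input_length ",
         spec$input_length, call. = FALSE)
  y <- NULL
  if (need_labels) {
    if (anyNA(x$group)) stop("unlabeled spectra in training data",
                             call. = FALSE)
    y <- as.integer(factor(as.character(x$group), levels = classes))
  }
  list(X = x$intensity, y = y)
}

predict_matrix <- function(params, running, spec, X, chunk = 256L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, spec$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(n, s + chunk - 1L)
    out[i, ] <- nn_forward(params, running, spec,
                           X[i, , drop = FALSE])$logits
  }
  out
}

#' Fit the 1D convolutional SERS classifier
#'
#' Trains the four-block 1D-CNN on labeled spectra by mini-batch rectified
#' Adam on the class-weighted cross-entropy, tracking per-epoch training
#' loss and validation accuracy, and returns the parameters of the epoch
#' with the best validation accuracy. Deterministic for a given
#' `config$seed` (single-threaded numerics assumed).
#'
#' @param train A labeled [spectra_set()] whose spectra have
#'   `spec$input_length` points (deep-track preprocessed and augmented).
#' @param val Validation `spectra_set` used for model selection.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `sers_cnn` with elements `spec`, `config`,
#'   `params`, `running`, `history` (data frame: epoch, loss,
#'   val_accuracy), `best_epoch`, `classes`, `class_weights`.
#' @seealso [predict.sers_cnn()], [gradcam()]
#' @export
sers_cnn <- function(train, val, spec = model_spec(),
                     config = train_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "train_config"))
  if (n_spectra(train) == 0L || n_spectra(val) == 0L)
    stop("empty training or validation set", call. = FALSE)
  classes <- sers_classes()[seq_len(spec$n_classes)]
  tr <- set_to_xy(train, spec, classes = classes)
  va <- set_to_xy(val, spec, classes = classes)
  w <- class_weights(train$group, config$class_weight_mode, classes)
  loss_fn <- if (spec$output_activation == "softmax") ce_loss_grad
             else logsig_loss_grad
  set.seed(config$seed)
  st <- nn_init(spec)
  params <- st$params; running <- st$running
  opt <- radam_init(params)
  n <- nrow(tr$X)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_accuracy = numeric(0))
  best <- list(acc = -Inf, loss = Inf, params = params, running = running,
               epoch = 0L)
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; nb <- 0L
    for (s in starts) {
      idx <- ord[s:min(n, s + config$batch_size - 1L)]
      if (length(idx) < 2L && length(starts) > 1L) next # BN needs > 1
      fw <- nn_forward(params, running, spec,
                       tr$X[idx, , drop = FALSE], training = TRUE,
                       keep_cache = TRUE)
      running <- fw$running
      lg <- loss_fn(fw$logits, tr$y[idx], w)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             call. = FALSE)
      grads <- nn_backward(params, spec, fw$cache, lg$dlogits)
      stp <- radam_step(opt, params, grads, config$learning_rate)
      opt <- stp$opt; params <- stp$params
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- predict_matrix(params, running, spec, va$X)
    acc <- mean(max.col(vl, ties.method = "first") == va$y)
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   val_accuracy = acc))
    # ties in validation accuracy go to the better-converged epoch
    if (acc > best$acc || (acc == best$acc && ep_loss / nb < best$loss))
      best <- list(acc = acc, loss = ep_loss / nb, params = params,
                   running = running, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f", ep,
                      ep_loss / nb, acc))
  }
  structure(list(spec = spec, config = config, params = best$params,
                 running = best$running, history = hist,
                 best_epoch = best$epoch, classes = classes,
                 class_weights = w),
            class = "sers_cnn")
}

#' Predict classes or class scores for spectra
#'
#' Inference is deterministic: dropout is disabled and batch normalization
#' uses its running statistics. In `softmax` mode score rows sum to 1; in
#' `log_sigmoid` mode scores are per-class sigmoids in `[0, 1]`.
#'
#' @param object A fitted [sers_cnn()] model.
#' @param newdata A [spectra_set()] (or intensity matrix) with
#'   `input_length` points per spectrum.
#' @param type `"class"` (factor of predicted labels), `"score"`
#'   (numeric matrix, one column per class) or `"both"`.
#' @param ... Unused.
#' @return Per `type`: a factor, a matrix, or a list with both.
#' @export
predict.sers_cnn <- function(object, newdata,
                             type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_set")) newdata$intensity
       else as.matrix(newdata)
  if (ncol(X) != object$spec$input_length)
    stop("newdata length does not match model input_length", call. = FALSE)
  logits <- predict_matrix(object$params, object$running, object$spec, X)
  scores <- if (object$spec$output_activation == "softmax")
    softmax_rows(logits) else 1 / (1 + exp(-logits))
  colnames(scores) <- object$classes
  cls <- factor(object$classes[max.col(scores, ties.method = "first")],
                levels = object$classes)
  switch(type, class = cls, score = scores,
         both = list(class = cls, score = scores))
}

#' @export
print.sers_cnn <- function(x, ...) {
  cat(sprintf(
    "<sers_cnn> input %d, blocks %s (kernels %s), FC %s -> %d classes\n",
    x$spec$input_length,
    paste(x$spec$block_channels, collapse = "/"),
    paste(x$spec$block_kernels, collapse = "/"),
    paste(x$spec$fc_sizes, collapse = "/"), x$spec$n_classes))
  cat(sprintf("trained %d epochs; best val accuracy %.3f at epoch %d\n",
              nrow(x$history), max(x$history$val_accuracy), x$best_epoch))
  invisible(x)
}

#' @export
summary.sers_cnn <- function(object, ...) {
  print(object)
  cat("class weights:",
      paste(sprintf("%s=%.3f", names(object$class_weights),
                    object$class_weights), collapse = ", "), "\n")
  cat(sprintf("final epoch loss %.4f; val accuracy trace: %s\n",
              utils::tail(object$history$loss, 1),
              paste(sprintf("%.2f",
                            utils::tail(object$history$val_accuracy, 5)),
                    collapse = " ")))
  invisible(object)
}

#' Plot training history
#'
#' Training loss and validation accuracy against the epoch index.
#'
#' @param x A fitted [sers_cnn()] model.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sers_cnn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(x$history$epoch, x$history$val_accuracy, type = "l",
                 xlab = "epoch", ylab = "validation accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}
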