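# Model fitting: training configuration, classifier fine-tuning, the ReLU
# regression network, and the user-facing dnfold_fit()/dnfoldr_fit()
# modelling interface with its S3 methods.

#' Describe a deep network architecture
#'
#' @param layer_sizes integer vector of layer widths, input first, single
#'   output unit last; at least one hidden layer (so >= 3 entries).
#' @param epochs fine-tuning epochs associated with this architecture.
#' @param tag free-text label (e.g. `"MODEL 8"`).
#' @return object of class `architecture_spec`.
#' @examples
#' architecture_spec(c(84, 100, 100, 35, 1), epochs = 60)
#' @export
architecture_spec <- function(layer_sizes, epochs = 25, tag = "") {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L) {
    stop("architecture needs at least input, one hidden, and output layer", call. = FALSE)
  }
  if (any(layer_sizes < 1L)) stop("layer sizes must be positive", call. = FALSE)
  if (layer_sizes[length(layer_sizes)] != 1L) {
    stop("output layer must have a single unit", call. = FALSE)
  }
  if (epochs < 1) stop("epochs must be positive", call. = FALSE)
  structure(list(layer_sizes = layer_sizes, epochs = as.integer(epochs), tag = tag),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("architecture %s: %s, %d epochs\n",
              if (nzchar(x$tag)) x$tag else "(untagged)",
              paste(x$layer_sizes, collapse = "-"), x$epochs))
  invisible(x)
}

#' Training configuration for the classifier
#'
#' Defaults: mini-batches of 1000 examples, 25 pretraining and 25
#' fine-tuning epochs, RBM and backpropagation learning rates of 0.1,
#' momentum 0.5 for the first 5 epochs then 0.9, RBM weight decay 2e-4.
#' `positive_weight` optionally up-weights the rare positive class in the
#' cross-entropy (default 1 = no reweighting).
#'
#' @param batch_size mini-batch size (>= 1).
#' @param pretrain_epochs CD-1 epochs per RBM.
#' @param finetune_epochs backpropagation epochs (used when the
#'   architecture does not carry its own epoch count).
#' @param learning_rate_rbm,learning_rate_backprop positive step sizes.
#' @param momentum_initial,momentum_final,momentum_switch momentum is
#'   `momentum_initial` for the first `momentum_switch` epochs, then
#'   `momentum_final`.
#' @param weight_decay L2 penalty applied to RBM weights during CD-1.
#' @param positive_weight multiplier on the positive-class cross-entropy.
#' @param seed integer driving every source of randomness in training.
#' @return list of class `dnfold_control`.
#' @export
dnfold_control <- function(batch_size = 1000, pretrain_epochs = 25,
                           finetune_epochs = 25, learning_rate_rbm = 0.1,
                           learning_rate_backprop = 0.1,
                           momentum_initial = 0.5, momentum_final = 0.9,
                           momentum_switch = 5, weight_decay = 2e-4,
                           positive_weight = 1, seed = 1L) {
  stopifnot(batch_size >= 1, pretrain_epochs >= 0, finetune_epochs >= 1,
            learning_rate_rbm > 0, learning_rate_backprop > 0,
            momentum_initial >= 0, momentum_initial < 1,
            momentum_final >= 0, momentum_final < 1,
            weight_decay >= 0, positive_weight > 0)
  structure(list(batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate_rbm = learning_rate_rbm,
                 learning_rate_backprop = learning_rate_backprop,
                 momentum_initial = momentum_initial,
                 momentum_final = momentum_final,
                 momentum_switch = momentum_switch,
                 weight_decay = weight_decay,
                 positive_weight = positive_weight,
                 seed = as.integer(seed)),
            class = "dnfold_control")
}

#' Training configuration for the TM-score regressor
#'
#' Defaults match the regression network's training regime: plain
#' stochastic gradient descent with learning rate 0.01, batches of 1000,
#' at most 50 epochs, weights initialized uniformly in `[-0.5, 0.5]`.
#'
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs.
#' @param learning_rate SGD step size.
#' @param init_range half-width of the uniform weight initialization.
#' @param seed integer seed.
#' @return list of class `dnfoldr_control`.
#' @export
dnfoldr_control <- function(batch_size = 1000, epochs = 50,
                            learning_rate = 0.01, init_range = 0.5,
                            seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0, init_range > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 init_range = init_range,
                 seed = as.integer(seed)),
            class = "dnfoldr_control")
}

new_deepnet_model <- function(layers, arch, kind, hidden_kind, output_kind,
                              scaling = NULL, loss_history = numeric(),
                              fitted_values = NULL, y = NULL, call = NULL) {
  structure(list(layers = layers, arch = arch, kind = kind,
                 hidden_kind = hidden_kind, output_kind = output_kind,
                 scaling = scaling, loss_history = loss_history,
                 fitted_values = fitted_values, y = y, call = call),
            class = "deepnet_model")
}

#' Fine-tune a pretrained stack into a fold classifier
#'
#' Converts a list of pretrained RBMs into sigmoid hidden layers (weights
#' and hidden biases carried over), adds a randomly initialized sigmoid
#' output unit, and runs mini-batch backpropagation minimizing binary
#' cross-entropy. The returned model's training-set loss is never worse
#' than at initialization (the best epoch-end parameters are kept).
#'
#' @param stack list of RBMs from [pretrain_stack()].
#' @param features numeric matrix already scaled to `[0, 1]`.
#' @param binary_labels vector of 0/1 labels (1 = same fold).
#' @param control a [dnfold_control()] list.
#' @param epochs fine-tuning epochs; defaults to `control$finetune_epochs`.
#' @return a `deepnet_model` (no feature scaling attached; see
#'   [dnfold_fit()] for the full pipeline).
#' @export
fine_tune_classifier <- function(stack, features, binary_labels,
                                 control = dnfold_control(), epochs = NULL) {
  features <- as_feature_matrix(features)
  if (!all(binary_labels %in% c(0, 1))) {
    stop("binary_labels must be 0/1", call. = FALSE)
  }
  if (length(binary_labels) != nrow(features)) {
    stop("one label per feature row required", call. = FALSE)
  }
  epochs <- epochs %||% control$finetune_epochs
  with_seed(control$seed, {
    layers <- lapply(stack, function(r) list(W = r$weights, b = r$hidden_bias))
    n_last <- ncol(stack[[length(stack)]]$weights)
    layers[[length(layers) + 1L]] <- list(W = matrix(rnorm(n_last, sd = 0.01), n_last, 1L),
                                          b = 0)
    fit <- nnet_train(layers, features, binary_labels, "sigmoid", "sigmoid",
                      epochs = epochs, batch_size = control$batch_size,
                      learning_rate = control$learning_rate_backprop,
                      momentum_initial = control$momentum_initial,
                      momentum_final = control$momentum_final,
                      momentum_switch = control$momentum_switch,
                      pos_weight = control$positive_weight)
    sizes <- c(ncol(features), vapply(layers, function(l) ncol(l$W), 1L))
    arch <- architecture_spec(sizes, epochs = epochs)
    model <- new_deepnet_model(fit$layers, arch, "classifier", "sigmoid", "sigmoid",
                               loss_history = fit$loss_history)
    model$final_loss <- fit$final_loss
    model$fitted_values <- nnet_forward(fit$layers, features, "sigmoid", "sigmoid")$output
    model$y <- binary_labels
    model
  })
}

#' Train the rectified-linear TM-score regression network
#'
#' ReLU hidden layers with a linear output unit, all weights initialized
#' uniformly in `[-init_range, init_range]`, trained by mini-batch
#' stochastic gradient descent on the mean squared error (the Gaussian
#' log-likelihood up to scale). Default architecture: two hidden layers of
#' 100 units. The best epoch-end parameters on the training set are kept,
#' so the reported final loss never exceeds the initial loss.
#'
#' @param features numeric matrix.
#' @param tm_scores regression targets in `[0, 1]`.
#' @param arch an [architecture_spec()] or integer layer vector; `NULL`
#'   for the default `c(F, 100, 100, 1)`.
#' @param control a [dnfoldr_control()] list.
#' @return a `deepnet_model` with linear output.
#' @export
train_regressor <- function(features, tm_scores, arch = NULL,
                            control = dnfoldr_control()) {
  features <- as_feature_matrix(features)
  if (any(tm_scores < 0 | tm_scores > 1)) {
    stop("tm_scores must lie in [0, 1]", call. = FALSE)
  }
  if (length(tm_scores) != nrow(features)) {
    stop("one target per feature row required", call. = FALSE)
  }
  F <- ncol(features)
  if (is.null(arch)) arch <- architecture_spec(c(F, 100, 100, 1), epochs = control$epochs)
  if (!inherits(arch, "architecture_spec")) {
    arch <- architecture_spec(arch, epochs = control$epochs)
  }
  sizes <- arch$layer_sizes
  if (sizes[1L] != F) {
    stop(sprintf("architecture input width %d does not match feature width %d",
                 sizes[1L], F), call. = FALSE)
  }
  with_seed(control$seed, {
    layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
      list(W = matrix(runif(sizes[i] * sizes[i + 1L], -control$init_range,
                            control$init_range), sizes[i], sizes[i + 1L]),
           b = runif(sizes[i + 1L], -control$init_range, control$init_range))
    })
    fit <- nnet_train(layers, features, tm_scores, "relu", "linear",
                      epochs = arch$epochs, batch_size = control$batch_size,
                      learning_rate = control$learning_rate)
    model <- new_deepnet_model(fit$layers, arch, "regressor", "relu", "linear",
                               loss_history = fit$loss_history)
    model$final_loss <- fit$final_loss
    raw <- nnet_forward(fit$layers, features, "relu", "linear")$output
    model$fitted_values <- pmin(pmax(raw, 0), 1)
    model$y <- tm_scores
    model
  })
}

resolve_xy <- function(x, y, need = c("label", "tm")) {
  need <- match.arg(need)
  if (inherits(x, "pair_dataset")) {
    if (is.null(x$features)) stop("dataset has no features", call. = FALSE)
    if (need == "label") {
      y <- x$pairs$binary_label
      keep <- rep(TRUE, length(y))
    } else {
      y <- x$pairs$tm_score
      if (is.null(y)) stop("dataset has no tm_score column", call. = FALSE)
      keep <- !is.na(y)
      if (!all(keep)) {
        message(sprintf("dropping %d pairs without a TM-score", sum(!keep)))
      }
    }
    list(x = x$features[keep, , drop = FALSE], y = y[keep])
  } else {
    x <- as_feature_matrix(x)
    if (is.null(y)) stop("y must be supplied when x is a matrix", call. = FALSE)
    if (need == "tm") {
      keep <- !is.na(y)
      if (!all(keep)) message(sprintf("dropping %d pairs without a TM-score", sum(!keep)))
      x <- x[keep, , drop = FALSE]
      y <- y[keep]
    }
    list(x = x, y = y)
  }
}

#' Fit the RBM-pretrained deep network fold classifier
#'
#' The full single-model pipeline: per-feature min-max scaling to `[0, 1]`
#' (statistics stored in the model and re-applied at prediction time),
#' greedy RBM pretraining of every hidden layer by CD-1, then supervised
#' backpropagation fine-tuning minimizing binary cross-entropy. The default
#' architecture is `F-100-100-35-1` with 25 fine-tuning epochs.
#'
#' @param x a [pair_dataset()] with features, or a numeric feature matrix.
#' @param y 0/1 same-fold labels (ignored when `x` is a `pair_dataset`).
#' @param arch an [architecture_spec()] or integer layer vector; `NULL`
#'   for the default.
#' @param control a [dnfold_control()] list.
#' @return object of class `deepnet_model` (kind `"classifier"`) with
#'   `print`, `summary`, `predict`, `coef`, `fitted`, `residuals` and
#'   `plot` methods.
#' @examples
#' sim <- simulate_fold_data(fold_sim_config(feature_count = 8, seed = 3))
#' fit <- dnfold_fit(sim, arch = c(8, 16, 8, 1),
#'                   control = dnfold_control(pretrain_epochs = 2,
#'                                            finetune_epochs = 3, seed = 3))
#' summary(fit)
#' @export
dnfold_fit <- function(x, y = NULL, arch = NULL, control = dnfold_control()) {
  cl <- match.call()
  xy <- resolve_xy(x, y, "label")
  if (!all(xy$y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  F <- ncol(xy$x)
  if (is.null(arch)) arch <- architecture_spec(c(F, 100, 100, 35, 1),
                                               epochs = control$finetune_epochs)
  if (!inherits(arch, "architecture_spec")) {
    arch <- architecture_spec(arch, epochs = control$finetune_epochs)
  }
  if (arch$layer_sizes[1L] != F) {
    stop(sprintf("architecture input width %d does not match feature width %d",
                 arch$layer_sizes[1L], F), call. = FALSE)
  }
  scaling <- minmax_fit(xy$x)
  xs <- minmax_apply(xy$x, scaling)
  hidden_sizes <- arch$layer_sizes[-length(arch$layer_sizes)]
  stack <- pretrain_stack(xs, hidden_sizes, control)
  ft_control <- control
  ft_control$seed <- control$seed + 97L
  model <- fine_tune_classifier(stack, xs, xy$y, ft_control, epochs = arch$epochs)
  model$arch <- arch
  model$scaling <- scaling
  model$call <- cl
  model
}

#' Fit the rectified-linear TM-score regression network
#'
#' Min-max scales features (statistics stored in the model) and trains the
#' ReLU regression network of [train_regressor()]. Pairs without a
#' TM-score are dropped with a message.
#'
#' @param x a [pair_dataset()] carrying `tm_score`, or a feature matrix.
#' @param tm_scores targets in `[0, 1]` (ignored when `x` is a
#'   `pair_dataset`).
#' @param arch architecture; `NULL` for the default two-hidden-layer
#'   `c(F, 100, 100, 1)`.
#' @param control a [dnfoldr_control()] list.
#' @return object of class `deepnet_model` (kind `"regressor"`).
#' @export
dnfoldr_fit <- function(x, tm_scores = NULL, arch = NULL,
                        control = dnfoldr_control()) {
  cl <- match.call()
  xy <- resolve_xy(x, tm_scores, "tm")
  scaling <- minmax_fit(xy$x)
  xs <- minmax_apply(xy$x, scaling)
  model <- train_regressor(xs, xy$y, arch, control)
  model$scaling <- scaling
  model$call <- cl
  model
}

#' Predict same-fold probabilities or TM-scores from a fitted network
#'
#' Applies the model's stored min-max scaling to new features and runs the
#' forward pass. Classifier outputs are sigmoid probabilities in `[0, 1]`;
#' regressor outputs are clamped to `[0, 1]` for reporting and ranking
#' (`type = "raw"` returns the unclamped linear output).
#'
#' @param object a `deepnet_model`.
#' @param newdata a [pair_dataset()] or numeric feature matrix; defaults
#'   to the training data's fitted values.
#' @param type `"response"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.deepnet_model <- function(object, newdata = NULL,
                                  type = c("response", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(object$fitted_values)
  if (inherits(newdata, "pair_dataset")) newdata <- newdata$features
  newdata <- as_feature_matrix(newdata)
  expected <- object$arch$layer_sizes[1L]
  if (ncol(newdata) != expected) {
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), expected), call. = FALSE)
  }
  if (!is.null(object$scaling)) newdata <- minmax_apply(newdata, object$scaling)
  out <- nnet_forward(object$layers, newdata, object$hidden_kind,
                      object$output_kind)$output
  if (type == "response" && object$output_kind == "linear") {
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' @export
print.deepnet_model <- function(x, ...) {
  cat(sprintf("Deep network %s (%s hidden units), architecture %s\n",
              x$kind, x$hidden_kind, paste(x$arch$layer_sizes, collapse = "-")))
  if (length(x$loss_history)) {
    final <- x$final_loss %||% x$loss_history[length(x$loss_history)]
    cat(sprintf("  training %s: %.6f (initial) -> %.6f (final), %d epochs\n",
                if (x$kind == "classifier") "cross-entropy" else "MSE",
                x$loss_history[1L], final, length(x$loss_history) - 1L))
  }
  invisible(x)
}

#' @export
summary.deepnet_model <- function(object, ...) {
  shapes <- vapply(object$layers, function(l) sprintf("%dx%d", nrow(l$W), ncol(l$W)), "")
  n_par <- sum(vapply(object$layers, function(l) length(l$W) + length(l$b), 1))
  out <- list(kind = object$kind, arch = object$arch, layer_shapes = shapes,
              n_parameters = n_par, loss_history = object$loss_history,
              final_loss = object$final_loss %||% object$loss_history[length(object$loss_history)])
  if (!is.null(object$fitted_values) && !is.null(object$y)) {
    if (object$kind == "classifier") {
      out$training_accuracy <- mean((object$fitted_values >= 0.5) == (object$y == 1))
      out$training_auc <- auc_score(object$fitted_values, object$y)
    } else {
      out$training_mad <- mean_absolute_deviation(object$fitted_values, object$y)
    }
  }
  class(out) <- "summary.deepnet_model"
  out
}

#' @export
print.summary.deepnet_model <- function(x, ...) {
  cat(sprintf("Deep network %s, architecture %s (%d parameters)\n", x$kind,
              paste(x$arch$layer_sizes, collapse = "-"), x$n_parameters))
  cat("  layer shapes:", paste(x$layer_shapes, collapse = ", "), "\n")
  cat(sprintf("  training loss: %.6f -> %.6f over %d epochs\n",
              x$loss_history[1L], x$final_loss, length(x$loss_history) - 1L))
  if (!is.null(x$training_accuracy)) {
    cat(sprintf("  training accuracy %.3f, training AUC %.3f\n",
                x$training_accuracy, x$training_auc))
  }
  if (!is.null(x$training_mad)) {
    cat(sprintf("  training mean absolute deviation %.4f\n", x$training_mad))
  }
  invisible(x)
}

#' @export
coef.deepnet_model <- function(object, ...) {
  lapply(object$layers, function(l) list(weights = l$W, bias = l$b))
}

#' @export
fitted.deepnet_model <- function(object, ...) object$fitted_values

#' @export
residuals.deepnet_model <- function(object, ...) object$y - object$fitted_values

#' Plot the training loss trajectory of a fitted network
#'
#' @param x a `deepnet_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deepnet_model <- function(x, ...) {
  loss <- x$loss_history
  plot(seq_along(loss) - 1L, loss, type = "b", xlab = "epoch",
       ylab = if (x$kind == "classifier") "cross-entropy" else "MSE", ...)
  invisible(x)
}

#' Save and load fitted networks
#'
#' A single self-describing file holding the format version, architecture,
#' scaling statistics and all weight layers. Loading and predicting is
#' bit-identical to predicting before the save.
#'
#' @param model a `deepnet_model`.
#' @param path file path.
#' @return `load_deepnet` returns the model; `save_deepnet` the path,
#'   invisibly.
#' @export
save_deepnet <- function(model, path) {
  stopifnot(inherits(model, "deepnet_model"))
  saveRDS(list(format = "dnfold_deepnet", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_deepnet
#' @export
load_deepnet <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "dnfold_deepnet")) {
    stop("not a dnfold deep-network model file: ", path, call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported model file version: ", obj$version, call. = FALSE)
  }
  if (!inherits(obj$model, "deepnet_model")) {
    stop("corrupt model file: ", path, call. = FALSE)
  }
  obj$model
}
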