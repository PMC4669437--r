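# Feed-forward networks: forward pass, backpropagation gradients, and the
# mini-batch gradient-descent trainer shared by the sigmoid classifier and
# the rectified-linear regressor.
#
# A network is a list of layers, each `list(W, b)` with W of shape
# (fan-in x fan-out); all layers but the last use the hidden nonlinearity,
# the last is the output unit (sigmoid for the classifier, linear for the
# regressor).

nnet_forward <- function(layers, x, hidden_kind = c("sigmoid", "relu"),
                         output_kind = c("sigmoid", "linear")) {
  hidden_kind <- match.arg(hidden_kind)
  output_kind <- match.arg(output_kind)
  act <- if (hidden_kind == "sigmoid") sigmoid else relu
  n_layers <- length(layers)
  activations <- vector("list", n_layers + 1L)
  activations[[1L]] <- x
  a <- x
  for (i in seq_len(n_layers)) {
    z <- add_bias(a %*% layers[[i]]$W, layers[[i]]$b)
    a <- if (i < n_layers) act(z) else if (output_kind == "sigmoid") sigmoid(z) else z
    activations[[i + 1L]] <- a
  }
  list(output = drop(a), activations = activations)
}

# Forward-only mean loss (no gradients); used for epoch-end monitoring.
nnet_loss <- function(layers, x, y, hidden_kind, output_kind, pos_weight = 1) {
  yhat <- nnet_forward(layers, x, hidden_kind, output_kind)$output
  n <- nrow(x)
  if (output_kind == "sigmoid") {
    w <- ifelse(y == 1, pos_weight, 1)
    p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / n
  } else {
    sum((yhat - y)^2) / n
  }
}

# Mean loss and its gradient with respect to all weights and biases.
# Classifier: (weighted) binary cross-entropy on a sigmoid output.
# Regressor: mean squared error on a linear output (Gaussian likelihood up
# to scale).
nnet_loss_grad <- function(layers, x, y, hidden_kind, output_kind,
                           pos_weight = 1) {
  fwd <- nnet_forward(layers, x, hidden_kind, output_kind)
  n <- nrow(x)
  n_layers <- length(layers)
  yhat <- fwd$activations[[n_layers + 1L]]
  y <- matrix(y, ncol = 1L)
  if (output_kind == "sigmoid") {
    w <- ifelse(y == 1, pos_weight, 1)
    p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
    loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / n
    # d(loss)/d(z_out): p*(1 - y + w*y) - w*y, the weighted sigmoid CE delta
    delta <- (yhat * (1 - y + w * y) - w * y) / n
  } else {
    loss <- sum((yhat - y)^2) / n
    delta <- 2 * (yhat - y) / n
  }
  grads <- vector("list", n_layers)
  for (i in rev(seq_len(n_layers))) {
    a_prev <- fwd$activations[[i]]
    grads[[i]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (i > 1L) {
      back <- delta %*% t(layers[[i]]$W)
      a <- fwd$activations[[i]]
      dact <- if (hidden_kind == "sigmoid") a * (1 - a) else (a > 0) * 1
      delta <- back * dact
    }
  }
  list(loss = loss, grads = grads, output = drop(yhat))
}

# Mini-batch gradient descent with an optional momentum schedule. Batches
# are formed after a seeded shuffle each epoch; the final short batch is
# used as-is. Returns the epoch-end parameters with the lowest
# full-training-set loss (initialization included), so the reported final
# loss is never worse than the initial loss, plus the loss before and
# after each epoch.
nnet_train <- function(layers, x, y, hidden_kind, output_kind, epochs,
                       batch_size, learning_rate, momentum_initial = 0,
                       momentum_final = 0, momentum_switch = 0,
                       pos_weight = 1) {
  n <- nrow(x)
  inc <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  full_loss <- function() nnet_loss(layers, x, y, hidden_kind, output_kind,
                                    pos_weight)
  history <- numeric(epochs + 1L)
  history[1L] <- full_loss()
  best <- list(loss = history[1L], layers = layers)
  for (epoch in seq_len(epochs)) {
    mom <- if (epoch <= momentum_switch) momentum_initial else momentum_final
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (idx in batches) {
      lg <- nnet_loss_grad(layers, x[idx, , drop = FALSE], y[idx],
                           hidden_kind, output_kind, pos_weight)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d; lower the learning rate", epoch),
             call. = FALSE)
      }
      for (i in seq_along(layers)) {
        inc[[i]]$W <- mom * inc[[i]]$W - learning_rate * lg$grads[[i]]$W
        inc[[i]]$b <- mom * inc[[i]]$b - learning_rate * lg$grads[[i]]$b
        layers[[i]]$W <- layers[[i]]$W + inc[[i]]$W
        layers[[i]]$b <- layers[[i]]$b + inc[[i]]$b
      }
    }
    history[epoch + 1L] <- full_loss()
    if (history[epoch + 1L] < best$loss) {
      best <- list(loss = history[epoch + 1L], layers = layers)
    }
  }
  list(layers = best$layers, loss_history = history, final_loss = best$loss)
}

#' Mean absolute deviation between predicted and true similarity scores
#'
#' The averaged deviation `mean(|predicted - truth|)` used to summarize
#' TM-score regression accuracy.
#'
#' @param predicted,truth numeric vectors of equal length.
#' @return a single number.
#' @examples
#' mean_absolute_deviation(c(0.5), c(0.4))  # 0.1
#' @export
mean_absolute_deviation <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  mean(abs(predicted - truth))
}
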