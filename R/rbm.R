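# Restricted Boltzmann machines trained by one-step contrastive divergence
# (CD-1), and layer-by-layer stacking used to initialize the deep network.
#
# Hyperparameter defaults follow standard RBM practice: learning rate 0.1,
# momentum 0.5 for the first 5 epochs then 0.9, weight decay 2e-4, weights
# initialized N(0, 0.01^2), zero biases.

#' Train a restricted Boltzmann machine with CD-1
#'
#' Visible units are Bernoulli with the data rows interpreted as activation
#' probabilities, so all inputs must lie in `[0, 1]` (rescale with min-max
#' scaling first; [dnfold_fit()] does this automatically). One full Gibbs
#' half-step reconstruction per mini-batch (contrastive divergence with one
#' step), momentum and L2 weight decay. Training is reproducible bit for
#' bit given the same data, configuration and seed.
#'
#' @param data numeric matrix in `[0, 1]`, one training case per row.
#' @param n_hidden number of hidden units (>= 1).
#' @param control a [dnfold_control()] list; relevant fields are
#'   `pretrain_epochs`, `batch_size`, `learning_rate_rbm`, momentum
#'   schedule, `weight_decay` and `seed`.
#' @return list of class `rbm` with `weights` (visible x hidden),
#'   `visible_bias`, `hidden_bias`.
#' @export
train_rbm <- function(data, n_hidden, control = dnfold_control()) {
  data <- as_feature_matrix(data)
  if (any(data < 0 | data > 1)) {
    stop("RBM training data must lie in [0, 1]; min-max scale features first",
         call. = FALSE)
  }
  if (n_hidden < 1) stop("n_hidden must be >= 1", call. = FALSE)
  n_visible <- ncol(data)
  n <- nrow(data)
  with_seed(control$seed, {
    W <- matrix(rnorm(n_visible * n_hidden, sd = 0.01), n_visible, n_hidden)
    vb <- numeric(n_visible)
    hb <- numeric(n_hidden)
    inc_W <- matrix(0, n_visible, n_hidden)
    inc_vb <- numeric(n_visible)
    inc_hb <- numeric(n_hidden)
    lr <- control$learning_rate_rbm
    for (epoch in seq_len(control$pretrain_epochs)) {
      mom <- if (epoch <= control$momentum_switch) control$momentum_initial else control$momentum_final
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      for (idx in batches) {
        v0 <- data[idx, , drop = FALSE]
        nb <- nrow(v0)
        h0p <- sigmoid(add_bias(v0 %*% W, hb))
        h0s <- matrix(runif(nb * n_hidden) < h0p, nb, n_hidden) * 1
        v1p <- sigmoid(add_bias(h0s %*% t(W), vb))
        h1p <- sigmoid(add_bias(v1p %*% W, hb))
        dW <- (crossprod(v0, h0p) - crossprod(v1p, h1p)) / nb - control$weight_decay * W
        dvb <- colMeans(v0 - v1p)
        dhb <- colMeans(h0p - h1p)
        inc_W <- mom * inc_W + lr * dW
        inc_vb <- mom * inc_vb + lr * dvb
        inc_hb <- mom * inc_hb + lr * dhb
        W <- W + inc_W
        vb <- vb + inc_vb
        hb <- hb + inc_hb
      }
    }
    structure(list(weights = W, visible_bias = vb, hidden_bias = hb), class = "rbm")
  })
}

#' Hidden-unit activation probabilities of an RBM
#'
#' The logistic of the affine transform `data %*% W + hidden_bias`; these
#' probabilities serve as the visible layer of the next RBM in the stack.
#'
#' @param rbm an [train_rbm()] result.
#' @param data numeric matrix, one case per row, width matching the RBM's
#'   visible layer.
#' @return matrix in `[0, 1]`, rows x hidden units.
#' @export
rbm_hidden_probabilities <- function(rbm, data) {
  data <- as_feature_matrix(data)
  if (ncol(data) != nrow(rbm$weights)) {
    stop(sprintf("data width %d does not match RBM visible layer %d",
                 ncol(data), nrow(rbm$weights)), call. = FALSE)
  }
  sigmoid(add_bias(data %*% rbm$weights, rbm$hidden_bias))
}

#' Greedy layer-by-layer RBM pretraining
#'
#' Trains one RBM per adjacent pair of layers, starting from the visible
#' (input) layer and proceeding to the last hidden layer; each RBM is
#' trained on the previous RBM's hidden activation probabilities. The
#' output unit is not pretrained.
#'
#' @param data numeric matrix in `[0, 1]`.
#' @param layer_sizes integer vector of input and hidden layer sizes (the
#'   final output unit excluded); e.g. `c(84, 100, 100, 35)` yields three
#'   RBMs of shapes 84x100, 100x100, 100x35.
#' @param control a [dnfold_control()] list.
#' @return list of `rbm` objects, length `length(layer_sizes) - 1`.
#' @export
pretrain_stack <- function(data, layer_sizes, control = dnfold_control()) {
  data <- as_feature_matrix(data)
  if (length(layer_sizes) < 2L) stop("need at least input and one hidden layer", call. = FALSE)
  if (layer_sizes[1L] != ncol(data)) {
    stop(sprintf("layer_sizes[1] (%d) must equal feature width (%d)",
                 layer_sizes[1L], ncol(data)), call. = FALSE)
  }
  stack <- vector("list", length(layer_sizes) - 1L)
  current <- data
  for (i in seq_along(stack)) {
    ctl <- control
    ctl$seed <- if (is.null(control$seed)) NULL else control$seed + i - 1L
    stack[[i]] <- train_rbm(current, layer_sizes[i + 1L], ctl)
    current <- rbm_hidden_probabilities(stack[[i]], current)
  }
  stack
}
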