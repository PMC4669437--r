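# Independent oracles used to check the implementation: exact RBM
# likelihood by state enumeration, central finite differences for
# gradients, and brute-force ranking statistics.

# Exact log-likelihood of binary data rows under a Bernoulli RBM, by
# enumerating all 2^(nv+nh) joint states. Only feasible for tiny machines.
rbm_exact_loglik <- function(rbm, data) {
  nv <- nrow(rbm$weights)
  nh <- ncol(rbm$weights)
  vis <- as.matrix(expand.grid(rep(list(0:1), nv)))
  hid <- as.matrix(expand.grid(rep(list(0:1), nh)))
  negE <- vis %*% rbm$weights %*% t(hid) +
    as.numeric(vis %*% rbm$visible_bias) +
    matrix(as.numeric(hid %*% rbm$hidden_bias), nrow(vis), nrow(hid), byrow = TRUE)
  logZ <- log(sum(exp(negE)))
  row_ll <- apply(data, 1, function(v) {
    idx <- which(apply(vis, 1, function(r) all(r == v)))
    log(sum(exp(negE[idx, ])))
  })
  sum(row_ll) - nrow(data) * logZ
}

# Maximum relative discrepancy between analytic gradients and central
# finite differences over every weight and bias of a random small network.
gradient_check <- function(hidden_kind, output_kind, seed, eps = 1e-5) {
  set.seed(seed)
  sizes <- c(5, 4, 3, 1)
  layers <- lapply(seq_len(3), function(i) list(
    W = matrix(rnorm(sizes[i] * sizes[i + 1], sd = 0.5), sizes[i], sizes[i + 1]),
    b = rnorm(sizes[i + 1], sd = 0.3)))
  x <- matrix(runif(10 * 5), 10, 5)
  y <- if (output_kind == "sigmoid") rbinom(10, 1, 0.5) else runif(10)
  analytic <- dnfold:::nnet_loss_grad(layers, x, y, hidden_kind, output_kind)
  loss_at <- function(l) dnfold:::nnet_loss_grad(l, x, y, hidden_kind, output_kind)$loss
  max_rel <- 0
  for (i in seq_along(layers)) {
    for (what in c("W", "b")) {
      for (j in seq_along(layers[[i]][[what]])) {
        lp <- layers; lp[[i]][[what]][j] <- lp[[i]][[what]][j] + eps
        lm <- layers; lm[[i]][[what]][j] <- lm[[i]][[what]][j] - eps
        num <- (loss_at(lp) - loss_at(lm)) / (2 * eps)
        ana <- analytic$grads[[i]][[what]][j]
        max_rel <- max(max_rel, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  max_rel
}

# Brute-force AUC: fraction of (positive, negative) pairs ordered
# correctly, ties counting one half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive confusion-matrix sweep for the precision-style
# specificity/sensitivity curve.
brute_force_curve <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    data.frame(threshold = t, specificity = tp / (tp + fp),
               sensitivity = tp / (tp + fn))
  }))
}

# Small strongly separable binary fixture: label 1 iff the first feature
# is above 0.5, with a margin around the boundary.
make_separable_data <- function(n = 200, seed = 5) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x1 <- ifelse(y == 1, runif(n, 0.7, 1), runif(n, 0, 0.3))
  cbind_x <- cbind(x1, runif(n))
  list(x = cbind_x, y = y)
}
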