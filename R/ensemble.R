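# Architecture pool, AUC-ranked sequential ensembling, and the score-sum
# meta-combiner.

#' The 14-architecture candidate pool
#'
#' The standard pool of deep-network architectures explored for the fold
#' classifier, parameterized by the input width `F`: hidden layouts of one
#' to three layers (100/120/150/250 units wide, 25/30/35-unit final hidden
#' layers) with 30 or 60 fine-tuning epochs.
#'
#' @param F input layer width (number of pairwise features).
#' @return list of 14 [architecture_spec()] objects tagged
#'   `"MODEL 1" .. "MODEL 14"`.
#' @examples
#' default_architecture_pool(84)[[8]]  # 84-100-100-35-1, 60 epochs
#' @export
default_architecture_pool <- function(F = 84) {
  hidden <- list(
    c(100, 100, 30), c(250, 35), c(100, 100, 25), c(100, 100, 25),
    c(150, 150, 25), c(120, 120, 30), c(250, 35), c(100, 100, 35),
    c(100, 35), c(100, 100, 30), c(100, 100, 35), c(250),
    c(150, 150, 25), c(150, 150, 35))
  epochs <- c(60, 60, 30, 60, 60, 30, 30, 60, 30, 30, 30, 30, 30, 30)
  lapply(seq_along(hidden), function(i) {
    architecture_spec(c(F, hidden[[i]], 1), epochs = epochs[i],
                      tag = sprintf("MODEL %d", i))
  })
}

#' Average the predictions of several models
#'
#' Simple elementwise arithmetic mean of aligned per-pair prediction
#' vectors; the ensembling rule used to combine the architecture pool.
#'
#' @param predictions a list of equal-length numeric vectors, or a matrix
#'   with one column per model.
#' @return numeric vector of averaged predictions.
#' @export
ensemble_average <- function(predictions) {
  if (is.list(predictions)) {
    lens <- lengths(predictions)
    if (length(predictions) < 1L) stop("need at least one prediction vector", call. = FALSE)
    if (length(unique(lens)) != 1L) {
      stop("prediction vectors must have equal length", call. = FALSE)
    }
    predictions <- do.call(cbind, predictions)
  }
  if (!is.matrix(predictions)) predictions <- matrix(predictions, ncol = 1L)
  rowMeans(predictions)
}

#' Build a model pool from per-model out-of-fold predictions
#'
#' @param predictions matrix of per-pair scores, one column per model (NA
#'   rows allowed for pairs removed by the cross-validation template rule).
#' @param labels 0/1 same-fold labels aligned with the rows.
#' @param archs optional list of [architecture_spec()] for the columns.
#' @return object of class `model_pool`: members with predictions and
#'   pooled out-of-fold AUC.
#' @export
model_pool <- function(predictions, labels, archs = NULL) {
  stopifnot(is.matrix(predictions), nrow(predictions) == length(labels))
  scored <- !is.na(predictions[, 1L])
  aucs <- apply(predictions, 2L, function(p) auc_score(p[scored], labels[scored]))
  structure(list(predictions = predictions, labels = labels,
                 archs = archs, aucs = aucs),
            class = "model_pool")
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("model_pool: %d members over %d pairs\n",
              ncol(x$predictions), nrow(x$predictions)))
  for (i in seq_along(x$aucs)) {
    tag <- if (!is.null(x$archs)) x$archs[[i]]$tag else sprintf("member %d", i)
    cat(sprintf("  %-10s AUC %.4f\n", tag, x$aucs[i]))
  }
  invisible(x)
}

#' Sequential AUC-ranked ensembles of a model pool
#'
#' Members are sorted by AUC ascending (ties broken by pool index) and
#' integrated sequentially: ensemble `k` is the simple average of the `k`
#' lowest-AUC members, so the last ensemble averages the full pool. Each
#' ensemble's AUC is recomputed on its averaged predictions.
#'
#' @param pool a [model_pool()].
#' @return list with `order` (member indices by ascending AUC),
#'   `ensembles` (list of averaged prediction vectors) and `aucs` (per
#'   ensemble).
#' @export
sequential_ensembles <- function(pool) {
  stopifnot(inherits(pool, "model_pool"))
  ord <- order(pool$aucs, seq_along(pool$aucs))
  scored <- !is.na(pool$predictions[, 1L])
  m <- length(ord)
  ensembles <- vector("list", m)
  aucs <- numeric(m)
  for (k in seq_len(m)) {
    ensembles[[k]] <- ensemble_average(pool$predictions[, ord[seq_len(k)], drop = FALSE])
    aucs[k] <- auc_score(ensembles[[k]][scored], pool$labels[scored])
  }
  list(order = ord, ensembles = ensembles, aucs = aucs)
}

#' Score-sum meta-combination of two fold-recognition methods
#'
#' The meta-score is the elementwise sum of two aligned score vectors
#' (e.g. the deep-network ensemble and a random-forest method), used only
#' for ranking templates; the result lies in `[0, 2]`. Both inputs must be
#' on a common `[0, 1]` scale — normalize before combining.
#'
#' @param dn_scores,rf_scores numeric vectors in `[0, 1]` of equal length.
#' @return numeric vector of summed scores.
#' @examples
#' meta_sum(0.6, 0.8)  # 1.4
#' @export
meta_sum <- function(dn_scores, rf_scores) {
  if (length(dn_scores) != length(rf_scores)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!ok(dn_scores) || !ok(rf_scores)) {
    stop("scores must lie in [0, 1]; normalize before combining", call. = FALSE)
  }
  dn_scores + rf_scores
}
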