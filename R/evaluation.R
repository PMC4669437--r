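# Lindahl-style benchmark protocol: query-grouped cross-validation with
# template removal, per-level Top-k success rates, specificity-sensitivity
# curves, and rank-based AUC.

#' Rank-based area under the ROC curve
#'
#' The Wilcoxon-Mann-Whitney statistic: the probability that a random
#' positive is scored above a random negative, with ties contributing one
#' half.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Specificity-sensitivity curve
#'
#' One point per distinct score threshold, thresholds descending. Follows
#' the benchmark's conventions: *specificity* is the fraction of predicted
#' positives that are true positives (precision), *sensitivity* the
#' fraction of true positives predicted positive (recall). Sensitivity is
#' non-decreasing as the threshold falls; at the lowest threshold it is 1
#' and specificity equals the prevalence of positives.
#'
#' @param scores numeric score vector (NA scores dropped).
#' @param labels 0/1 labels.
#' @return data.frame with columns `threshold`, `specificity`,
#'   `sensitivity`; attribute `degenerate` is TRUE when only one class is
#'   present (with a warning).
#' @export
specificity_sensitivity_curve <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  degenerate <- length(unique(labels)) < 2L
  if (degenerate) warning("curve is degenerate: all labels belong to one class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- cumsum(table(factor(-s, levels = unique(-s))))  # last index per threshold
  idx <- as.integer(last)
  n_pos <- sum(y == 1)
  out <- data.frame(threshold = s[idx],
                    specificity = tp[idx] / (tp[idx] + fp[idx]),
                    sensitivity = if (n_pos > 0) tp[idx] / n_pos else NA_real_)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Query-grouped cross-validation partition with template removal
#'
#' Every pair sharing a query domain goes into the fold of that query
#' (queries are shuffled with the given seed and dealt into `k` near-equal
#' groups). The template-removal rule then discards from each test fold
#' any pair whose template serves as a query in that round's training set;
#' equivalently, a pair (Q, T) survives as a test pair only when T is not
#' a query of another fold. Removed pairs are recorded, carry no score,
#' and are excluded from downstream metrics.
#'
#' @param dataset a [pair_dataset()] (or its `pairs` data.frame).
#' @param k number of folds (default 10).
#' @param seed integer seed for the query shuffle.
#' @return object of class `cv_partition`: `fold_of_query` (named integer
#'   vector), `removed` (logical per pair), `removed_pairs` (data.frame),
#'   `k`, `seed`.
#' @export
make_cv_partition <- function(dataset, k = 10, seed = 1L) {
  pairs <- if (inherits(dataset, "pair_dataset")) dataset$pairs else dataset
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  queries <- unique(pairs$query_sid)
  if (length(queries) < k) {
    stop(sprintf("fewer queries (%d) than folds (%d)", length(queries), k),
         call. = FALSE)
  }
  fold_of_query <- with_seed(seed, {
    shuffled <- sample(queries)
    stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  })
  fq <- fold_of_query[pairs$query_sid]
  ft <- fold_of_query[pairs$template_sid]  # NA if template never a query
  removed <- unname(!is.na(ft) & ft != fq)
  removed_pairs <- data.frame(query_sid = pairs$query_sid[removed],
                              template_sid = pairs$template_sid[removed],
                              fold = unname(fq[removed]),
                              stringsAsFactors = FALSE)
  structure(list(fold_of_query = fold_of_query, removed = removed,
                 removed_pairs = removed_pairs, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cv_partition")
}

#' @export
print.cv_partition <- function(x, ...) {
  sizes <- table(x$fold_of_query)
  cat(sprintf("cv_partition: %d queries in %d folds (sizes %s), %d pairs removed by the template rule\n",
              length(x$fold_of_query), x$k,
              paste(as.integer(sizes), collapse = "/"), sum(x$removed)))
  invisible(x)
}

#' Out-of-fold predictions under the query-grouped protocol
#'
#' For each cross-validation round, fits the classifier on all pairs whose
#' query lies outside the test fold and scores the fold's surviving test
#' pairs, so every non-removed pair is scored exactly once by a model that
#' never trained on it. Removed pairs get `NA`.
#'
#' @param dataset a [pair_dataset()] with features.
#' @param partition a [make_cv_partition()] result (default: 10 folds
#'   seeded from `control$seed`).
#' @param arch architecture passed to [dnfold_fit()].
#' @param control a [dnfold_control()]; each round trains with seed
#'   `control$seed + round`.
#' @param fit_fun fitting function `(x, y, arch, control) -> model` with a
#'   `predict` method; defaults to [dnfold_fit()].
#' @return numeric vector of out-of-fold scores aligned with
#'   `dataset$pairs` (NA for removed pairs), with the partition attached
#'   as attribute `"partition"`.
#' @export
cv_predict <- function(dataset, partition = NULL, arch = NULL,
                       control = dnfold_control(), fit_fun = dnfold_fit) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (is.null(dataset$features)) stop("dataset has no features", call. = FALSE)
  if (is.null(partition)) partition <- make_cv_partition(dataset, seed = control$seed)
  pairs <- dataset$pairs
  fq <- partition$fold_of_query[pairs$query_sid]
  scores <- rep(NA_real_, nrow(pairs))
  for (r in seq_len(partition$k)) {
    train_idx <- which(fq != r)
    test_idx <- which(fq == r & !partition$removed)
    if (length(test_idx) == 0L) next
    ctl <- control
    ctl$seed <- control$seed + r
    fit <- fit_fun(dataset$features[train_idx, , drop = FALSE],
                   pairs$binary_label[train_idx], arch = arch, control = ctl)
    scores[test_idx] <- predict(fit, dataset$features[test_idx, , drop = FALSE])
  }
  unscored <- which(is.na(scores) & !partition$removed)
  if (length(unscored)) {
    stop(sprintf("internal consistency error: %d non-removed pairs unscored",
                 length(unscored)), call. = FALSE)
  }
  attr(scores, "partition") <- partition
  scores
}

#' Out-of-fold predictions for a whole architecture pool
#'
#' Runs [cv_predict()] once per architecture on a shared partition and
#' assembles the results into a [model_pool()] ranked by pooled
#' out-of-fold AUC. The full-pool simple average of the member predictions
#' is the ensemble fold-recognition score.
#'
#' @param dataset a [pair_dataset()] with features.
#' @param archs list of [architecture_spec()]; default
#'   [default_architecture_pool()] at the dataset's feature width.
#' @param partition shared [make_cv_partition()]; default seeded from
#'   `control$seed`.
#' @param control a [dnfold_control()].
#' @return a [model_pool()].
#' @export
cv_predict_pool <- function(dataset, archs = NULL, partition = NULL,
                            control = dnfold_control()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (is.null(archs)) archs <- default_architecture_pool(dataset$feature_count)
  if (is.null(partition)) partition <- make_cv_partition(dataset, seed = control$seed)
  preds <- vapply(seq_along(archs), function(i) {
    ctl <- control
    ctl$seed <- control$seed + 1000L * i
    cv_predict(dataset, partition, arch = archs[[i]], control = ctl)
  }, numeric(nrow(dataset$pairs)))
  model_pool(preds, dataset$pairs$binary_label, archs = archs)
}

#' Per-level Top-k template recognition success rate
#'
#' For each query, candidate templates are its scored pairs; when
#' `exclude_more_specific` is TRUE (the protocol default) pairs whose
#' relationship is *more* specific than the evaluated level are removed
#' from the list (family pairs do not compete when scoring superfamily
#' recognition), keeping the three positive sets disjoint. A query is
#' evaluable iff it retains at least one pair at exactly the evaluated
#' level; it succeeds when such a pair ranks within the top `k` by
#' descending score. Ties are broken by template sid (`ties = "template"`)
#' or pessimistically (`ties = "worst"`, every tied competitor ranked
#' ahead).
#'
#' @param scores per-pair scores aligned with `pairs` (NA = unscored,
#'   dropped).
#' @param pairs a [pair_dataset()] or data.frame with `query_sid`,
#'   `template_sid`, `relationship`.
#' @param level one of `"FAMILY"`, `"SUPERFAMILY"`, `"FOLD"`.
#' @param k rank cutoff (1 or 5 in the standard protocol).
#' @param exclude_more_specific drop pairs more specific than `level`.
#' @param ties tie-breaking policy.
#' @return percentage of evaluable queries with a hit in the top `k`,
#'   with attribute `n_queries` (the denominator); `NA` (undefined, not
#'   0) when no query is evaluable.
#' @export
topk_success_rate <- function(scores, pairs, level = c("FAMILY", "SUPERFAMILY", "FOLD"),
                              k = 1, exclude_more_specific = TRUE,
                              ties = c("template", "worst")) {
  level <- match.arg(level)
  ties <- match.arg(ties)
  if (inherits(pairs, "pair_dataset")) pairs <- pairs$pairs
  if (length(scores) != nrow(pairs)) {
    stop("scores must align with pairs", call. = FALSE)
  }
  keep <- !is.na(scores)
  if (exclude_more_specific) {
    keep <- keep & relationship_rank(pairs$relationship) <= relationship_rank(level)
  }
  df <- data.frame(query = pairs$query_sid[keep],
                   template = pairs$template_sid[keep],
                   hit = pairs$relationship[keep] == level,
                   score = scores[keep], stringsAsFactors = FALSE)
  evaluable <- unique(df$query[df$hit])
  if (length(evaluable) == 0L) {
    warning("no evaluable queries at level ", level, "; success rate undefined")
    return(structure(NA_real_, n_queries = 0L))
  }
  success <- vapply(evaluable, function(q) {
    cand <- df[df$query == q, , drop = FALSE]
    if (ties == "template") {
      ord <- order(-cand$score, cand$template)
      any(cand$hit[ord][seq_len(min(k, nrow(cand)))])
    } else {
      hits <- which(cand$hit)
      worst_rank <- vapply(hits, function(i) {
        sum(cand$score > cand$score[i]) + sum(cand$score == cand$score[i])
      }, 1)
      any(worst_rank <= k)
    }
  }, logical(1L))
  structure(100 * mean(success), n_queries = length(evaluable))
}

#' Benchmark report: per-level Top-1/Top-5 rates, curves and AUC
#'
#' Assembles the full Lindahl-style evaluation of one score vector:
#' Top-1/Top-5 success rates at the family, superfamily and fold levels,
#' the pooled specificity-sensitivity curve, per-level curves (positives =
#' pairs at exactly that level, among candidates not more specific), and
#' the pooled AUC over all scored pairs.
#'
#' @param scores per-pair scores aligned with the dataset (NA = removed).
#' @param dataset a [pair_dataset()].
#' @param method label stored in the report.
#' @param ... passed to [topk_success_rate()].
#' @return object of class `fold_eval_report`.
#' @export
evaluate_scores <- function(scores, dataset, method = "DN-Fold", ...) {
  pairs <- if (inherits(dataset, "pair_dataset")) dataset$pairs else dataset
  levels3 <- c("FAMILY", "SUPERFAMILY", "FOLD")
  rates <- lapply(levels3, function(L) {
    t1 <- suppressWarnings(topk_success_rate(scores, pairs, L, k = 1, ...))
    t5 <- suppressWarnings(topk_success_rate(scores, pairs, L, k = 5, ...))
    list(top1 = as.numeric(t1), top5 = as.numeric(t5),
         n_queries = attr(t1, "n_queries"))
  })
  names(rates) <- levels3
  keep <- !is.na(scores)
  curves <- list(pooled = specificity_sensitivity_curve(scores[keep],
                                                        pairs$binary_label[keep]))
  for (L in levels3) {
    sel <- keep & relationship_rank(pairs$relationship) <= relationship_rank(L)
    lab <- as.integer(pairs$relationship[sel] == L)
    curves[[L]] <- if (length(unique(lab)) == 2L) {
      specificity_sensitivity_curve(scores[sel], lab)
    } else NULL
  }
  auc <- auc_score(scores[keep], pairs$binary_label[keep])
  structure(list(method = method, rates = rates, curves = curves, auc = auc,
                 n_scored = sum(keep), n_removed = sum(!keep)),
            class = "fold_eval_report")
}

#' @export
print.fold_eval_report <- function(x, ...) {
  cat(sprintf("Fold recognition report for %s (%d scored pairs, %d removed; pooled AUC %.4f)\n",
              x$method, x$n_scored, x$n_removed, x$auc))
  cat(sprintf("  %-12s %8s %8s %10s\n", "level", "Top 1", "Top 5", "queries"))
  for (L in names(x$rates)) {
    r <- x$rates[[L]]
    cat(sprintf("  %-12s %8s %8s %10d\n", L,
                ifelse(is.na(r$top1), "NA", sprintf("%.1f", r$top1)),
                ifelse(is.na(r$top5), "NA", sprintf("%.1f", r$top5)),
                r$n_queries))
  }
  invisible(x)
}

#' Write a report's curve points to TSV files
#'
#' One file per available curve (`pooled`, `FAMILY`, `SUPERFAMILY`,
#' `FOLD`), columns `threshold`, `specificity`, `sensitivity` — suitable
#' for plotting specificity-sensitivity figures.
#'
#' @param report a [evaluate_scores()] result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisible character vector of written paths.
#' @export
write_curves <- function(report, dir, prefix = "curve") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$curves)) {
    cv <- report$curves[[nm]]
    if (is.null(cv)) next
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, tolower(nm)))
    write.table(cv, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
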