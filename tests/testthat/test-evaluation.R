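test_that("AUC handles perfect ordering, ties and brute-force equivalence", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(41)
  for (i in 1:5) {
    s <- sample(seq(0, 1, 0.1), 8, replace = TRUE)  # ties likely
    y <- rbinom(8, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(1, 0, y[-(1:2)])
    expect_equal(auc_score(s, y), brute_force_auc(s, y))
  }
  expect_error(auc_score(runif(4), rep(1, 4)), "positive and one negative")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(42)
  s <- runif(50)
  y <- rbinom(50, 1, 0.5)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                              direction = "<", quiet = TRUE))))
})

test_that("specificity-sensitivity curve matches an exhaustive confusion sweep", {
  # 6-pair hand-labeled fixture with a score tie across classes
  s <- c(0.9, 0.8, 0.8, 0.5, 0.3, 0.1)
  y <- c(1, 1, 0, 0, 1, 0)
  got <- specificity_sensitivity_curve(s, y)
  expect_equal(got, brute_force_curve(s, y), ignore_attr = TRUE)
  expect_false(attr(got, "degenerate"))
  # sensitivity is non-decreasing as the threshold falls
  expect_true(all(diff(got$sensitivity) >= 0))
  # lowest threshold: everything predicted positive
  expect_equal(got$sensitivity[nrow(got)], 1)
  expect_equal(got$specificity[nrow(got)], mean(y))
  # perfectly separated scores contain the (1, 1) point
  perf <- specificity_sensitivity_curve(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_true(any(perf$specificity == 1 & perf$sensitivity == 1))
  expect_warning(specificity_sensitivity_curve(runif(4), rep(1, 4)), "degenerate")
})

hand_ranked_fixture <- function() {
  # Q1 hit at rank 1 of 5; Q2 hit at rank 3 of 7; Q3 hit at rank 7 of 7.
  mk <- function(q, n, hit_rank) {
    data.frame(query_sid = q,
               template_sid = sprintf("%s_t%02d", q, seq_len(n)),
               relationship = ifelse(seq_len(n) == hit_rank, "FAMILY", "NONE"),
               score = seq(1, 0.1, length.out = n),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(mk("Q1", 5, 1), mk("Q2", 7, 3), mk("Q3", 7, 7)))
}

test_that("Top-k success rates reproduce the hand-ranked fixture", {
  fx <- hand_ranked_fixture()
  pairs <- fx[c("query_sid", "template_sid", "relationship")]
  pairs$binary_label <- as.integer(pairs$relationship != "NONE")
  t1 <- topk_success_rate(fx$score, pairs, "FAMILY", k = 1)
  t5 <- topk_success_rate(fx$score, pairs, "FAMILY", k = 5)
  expect_equal(as.numeric(t1), 100 / 3)
  expect_equal(as.numeric(t5), 200 / 3)
  expect_equal(attr(t1, "n_queries"), 3L)
  # k beyond the candidate count saturates at 100% of evaluable queries
  expect_equal(as.numeric(topk_success_rate(fx$score, pairs, "FAMILY", k = 10)), 100)
  # invariant under strictly monotone score transforms
  expect_equal(as.numeric(topk_success_rate(qlogis(fx$score / 1.01), pairs, "FAMILY", k = 1)),
               as.numeric(t1))
  expect_equal(as.numeric(topk_success_rate(fx$score^3, pairs, "FAMILY", k = 5)),
               as.numeric(t5))
})

test_that("more-specific pairs are excluded from less specific levels", {
  pairs <- data.frame(
    query_sid = "Q",
    template_sid = c("tFam", "tSup", "tNone1", "tNone2"),
    relationship = c("FAMILY", "SUPERFAMILY", "NONE", "NONE"),
    binary_label = c(1L, 1L, 0L, 0L), stringsAsFactors = FALSE)
  scores <- c(0.9, 0.6, 0.7, 0.2)
  # with exclusion the family pair vanishes and the superfamily hit is rank 2
  expect_equal(as.numeric(topk_success_rate(scores, pairs, "SUPERFAMILY", k = 1)), 0)
  expect_equal(as.numeric(topk_success_rate(scores, pairs, "SUPERFAMILY", k = 2)), 100)
  # without exclusion the family pair pushes the hit to rank 3
  expect_equal(as.numeric(topk_success_rate(scores, pairs, "SUPERFAMILY", k = 2,
                                            exclude_more_specific = FALSE)), 0)
  # no fold-level pair anywhere: undefined, not zero
  expect_warning(r <- topk_success_rate(scores, pairs, "FOLD", k = 1), "undefined")
  expect_true(is.na(r))
})

test_that("score ties resolve by template sid or pessimistically", {
  pairs <- data.frame(query_sid = "Q",
                      template_sid = c("ta", "tb", "tc"),
                      relationship = c("FAMILY", "NONE", "NONE"),
                      binary_label = c(1L, 0L, 0L), stringsAsFactors = FALSE)
  tied <- c(0.5, 0.5, 0.5)
  expect_equal(as.numeric(topk_success_rate(tied, pairs, "FAMILY", k = 1)), 100)
  expect_equal(as.numeric(topk_success_rate(tied, pairs, "FAMILY", k = 1,
                                            ties = "worst")), 0)
  expect_equal(as.numeric(topk_success_rate(tied, pairs, "FAMILY", k = 3,
                                            ties = "worst")), 100)
})

test_that("query-grouped partitions are balanced and keep queries together", {
  d <- domain_records(sprintf("d%02d", 1:20),
                      sprintf("a.%d.1.1", rep(1:4, each = 5)))
  ds <- enumerate_pairs(d)
  part <- make_cv_partition(ds, k = 10, seed = 3)
  sizes <- table(part$fold_of_query)
  expect_equal(as.integer(sizes), rep(2L, 10))
  expect_setequal(names(part$fold_of_query), d$sid)
  # partition law: every pair's fold is its query's fold
  fq <- part$fold_of_query[ds$pairs$query_sid]
  expect_true(all(!is.na(fq)))
  expect_identical(make_cv_partition(ds, k = 10, seed = 3)$fold_of_query,
                   part$fold_of_query)
  expect_error(make_cv_partition(ds, k = 30, seed = 1), "fewer queries")
})

test_that("the template rule removes exactly the cross-fold template pairs", {
  d <- domain_records(sprintf("d%02d", 1:8),
                      sprintf("a.%d.1.1", rep(1:2, each = 4)))
  ds <- enumerate_pairs(d)
  part <- make_cv_partition(ds, k = 2, seed = 5)
  f <- part$fold_of_query
  # constructed offending pair: query Q' in one fold, template Q training
  # in the other fold -> removed
  qp <- names(f)[f == 1][1]
  qt <- names(f)[f == 2][1]
  expect_true(any(part$removed_pairs$query_sid == qp &
                    part$removed_pairs$template_sid == qt))
  # same-fold templates are never removed
  qs <- names(f)[f == 1][2]
  expect_false(any(part$removed_pairs$query_sid == qp &
                     part$removed_pairs$template_sid == qs))
  # independent recomputation of the rule over all pairs
  expected <- !is.na(f[ds$pairs$template_sid]) &
    f[ds$pairs$template_sid] != f[ds$pairs$query_sid]
  expect_equal(part$removed, unname(expected))
  # never removes a pair whose template is absent from the training queries
  with_train <- f[part$removed_pairs$template_sid]
  expect_true(all(with_train != part$removed_pairs$fold))
})

test_that("out-of-fold scores cover exactly the non-removed pairs deterministically", {
  sim <- simulate_fold_data(fold_sim_config(feature_count = 6, seed = 2))
  ctl <- dnfold_control(batch_size = 32, pretrain_epochs = 2,
                        finetune_epochs = 3, seed = 2)
  part <- make_cv_partition(sim, k = 5, seed = 2)
  s1 <- cv_predict(sim, part, arch = c(6, 8, 1), control = ctl)
  s2 <- cv_predict(sim, part, arch = c(6, 8, 1), control = ctl)
  expect_identical(s1, s2)
  expect_equal(is.na(s1), part$removed)
  expect_true(all(s1[!is.na(s1)] >= 0 & s1[!is.na(s1)] <= 1))
})

test_that("Top-5 never falls below Top-1 in full evaluation reports", {
  sim <- simulate_fold_data(fold_sim_config(n_folds = 2, domains_per_family = 3,
                                            feature_count = 4, seed = 13))
  set.seed(77)
  for (i in 1:5) {
    scores <- runif(nrow(sim$pairs))
    rep_i <- evaluate_scores(scores, sim, method = "random")
    for (L in names(rep_i$rates)) {
      r <- rep_i$rates[[L]]
      if (!is.na(r$top1)) expect_gte(r$top5, r$top1)
      expect_true(is.na(r$top1) || (r$top1 >= 0 && r$top5 <= 100))
    }
    expect_gte(rep_i$auc, 0)
    expect_lte(rep_i$auc, 1)
  }
  expect_output(print(evaluate_scores(runif(nrow(sim$pairs)), sim)), "Top 1")
})

test_that("curve files are written for plotting", {
  sim <- simulate_fold_data(fold_sim_config(feature_count = 4, seed = 4))
  rep1 <- evaluate_scores(runif(nrow(sim$pairs)), sim)
  dir <- withr::local_tempdir()
  paths <- write_curves(rep1, dir)
  expect_true(length(paths) >= 1 && all(file.exists(paths)))
  back <- read.delim(paths[1])
  expect_named(back, c("threshold", "specificity", "sensitivity"))
})
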