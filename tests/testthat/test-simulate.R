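test_that("the hierarchy enumerates the configured number of domains", {
  cfg <- fold_sim_config(2, 2, 2, 2, feature_count = 4, seed = 1)
  d <- simulate_domains(cfg)
  expect_equal(nrow(d), 16L)
  expect_equal(nrow(enumerate_pairs(d)$pairs), 240L)
  parse_sccs(d$sccs)  # all codes valid
  expect_false(anyDuplicated(d$sid) > 0)
  expect_true(all(d$length >= 50 & d$length <= 300))
  # one family only -> every pair FAMILY
  one <- simulate_domains(fold_sim_config(1, 1, 1, 4, feature_count = 4))
  expect_true(all(enumerate_pairs(one)$pairs$relationship == "FAMILY"))
})

test_that("generation is deterministic under a seed and varies across seeds", {
  cfg <- fold_sim_config(feature_count = 6, seed = 5)
  s1 <- simulate_fold_data(cfg)
  s2 <- simulate_fold_data(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_fold_data(fold_sim_config(feature_count = 6, seed = 6))
  expect_false(identical(s1$features, s3$features))
  expect_false(identical(s1$pairs$tm_score, s3$pairs$tm_score))
})

test_that("informative feature means track the class-conditional signal", {
  cfg <- fold_sim_config(n_folds = 2, superfamilies_per_fold = 2,
                         families_per_superfamily = 3, domains_per_family = 4,
                         feature_count = 10, seed = 8)
  sim <- simulate_fold_data(cfg)  # 48 domains, 2256 pairs
  n_inf <- round(10 * cfg$informative_fraction)
  fam <- sim$pairs$relationship == "FAMILY"
  vals <- sim$features[fam, seq_len(n_inf)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1.5), 3 * se)
  none <- sim$features[sim$pairs$relationship == "NONE", seq_len(n_inf)]
  se0 <- sd(none) / sqrt(length(none))
  expect_lt(abs(mean(none) - 0), 3 * se0)
  # non-informative features carry no signal
  noise <- sim$features[fam, (n_inf + 1):10]
  expect_lt(abs(mean(noise)), 3 * sd(noise) / sqrt(length(noise)))
})

test_that("a null configuration leaves classes statistically indistinguishable", {
  cfg <- fold_sim_config(n_folds = 2, superfamilies_per_fold = 2,
                         families_per_superfamily = 3, domains_per_family = 4,
                         feature_count = 10,
                         signal_means = c(FAMILY = 0, SUPERFAMILY = 0,
                                          FOLD = 0, NONE = 0), seed = 15)
  sim <- simulate_fold_data(cfg)
  x1 <- rowMeans(sim$features[sim$pairs$binary_label == 1, 1:5])
  x0 <- rowMeans(sim$features[sim$pairs$binary_label == 0, 1:5])
  expect_gt(t.test(x1, x0)$p.value, 0.01)
})

test_that("TM-score-like values stay in [0,1] and overlap in the 0.30-0.50 band", {
  cfg <- fold_sim_config(n_folds = 2, superfamilies_per_fold = 2,
                         families_per_superfamily = 3, domains_per_family = 4,
                         feature_count = 4, seed = 20)
  sim <- simulate_fold_data(cfg)
  tm <- sim$pairs$tm_score
  expect_true(all(tm >= 0 & tm <= 1))
  same <- sim$pairs$binary_label == 1
  expect_gt(sum(tm[same] >= 0.30 & tm[same] <= 0.50), 0)
  expect_gt(sum(tm[!same] >= 0.30 & tm[!same] <= 0.50), 0)
  # location ordering preserved in expectation
  m <- tapply(tm, sim$pairs$relationship, mean)
  expect_true(m[["FAMILY"]] > m[["SUPERFAMILY"]])
  expect_true(m[["SUPERFAMILY"]] > m[["FOLD"]])
  expect_true(m[["FOLD"]] > m[["NONE"]])
})

test_that("degenerate spread returns each pair's configured location exactly", {
  cfg <- fold_sim_config(feature_count = 4, tm_concentration = Inf, seed = 2)
  sim <- simulate_fold_data(cfg)
  expect_equal(sim$pairs$tm_score,
               unname(cfg$tm_location[sim$pairs$relationship]))
})

test_that("configuration invariants are enforced", {
  expect_error(fold_sim_config(tm_location = c(FAMILY = 0.4, SUPERFAMILY = 0.5,
                                               FOLD = 0.3, NONE = 0.2)),
               "decrease")
  expect_error(fold_sim_config(informative_fraction = 0), "informative_fraction")
  expect_error(fold_sim_config(signal_means = c(FAMILY = 1)), "signal_means")
})
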