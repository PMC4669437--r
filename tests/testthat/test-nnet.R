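test_that("backprop gradients match central finite differences", {
  expect_lt(gradient_check("sigmoid", "sigmoid", seed = 42), 1e-5)
  expect_lt(gradient_check("relu", "linear", seed = 43), 1e-5)
})

test_that("a hand-built one-hidden-unit net matches the manual forward pass", {
  layers <- list(list(W = matrix(2, 1, 1), b = -0.5),
                 list(W = matrix(-1.5, 1, 1), b = 0.25))
  x <- matrix(c(0, 0.5, 1), 3, 1)
  h <- 1 / (1 + exp(-(2 * x - 0.5)))
  manual <- 1 / (1 + exp(-(-1.5 * h + 0.25)))
  fwd <- dnfold:::nnet_forward(layers, x, "sigmoid", "sigmoid")
  expect_equal(fwd$output, as.numeric(manual))
})

test_that("classifier separates a linearly separable fixture perfectly", {
  fix <- make_separable_data(n = 200, seed = 5)
  fit <- dnfold_fit(fix$x, fix$y, arch = c(2, 8, 4, 1),
                    control = dnfold_control(batch_size = 20, seed = 1))
  expect_equal(mean((fitted(fit) >= 0.5) == (fix$y == 1)), 1)
  # end-of-training loss never exceeds the initial loss
  expect_lte(fit$final_loss, fit$loss_history[1])
  # predictions stay in [0, 1] and identical rows get identical outputs
  p <- predict(fit, fix$x[c(1, 1, 2), ])
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p[1], p[2])
})

test_that("degenerate all-negative labels drive predictions below 0.5", {
  set.seed(8)
  x <- matrix(runif(120), 40, 3)
  fit <- dnfold_fit(x, rep(0, 40), arch = c(3, 4, 1),
                    control = dnfold_control(batch_size = 10,
                                             pretrain_epochs = 2, seed = 2))
  expect_true(all(predict(fit, x) < 0.5))
})

test_that("classifier training is reproducible given data, config and seed", {
  fix <- make_separable_data(n = 60, seed = 6)
  ctl <- dnfold_control(batch_size = 10, pretrain_epochs = 3,
                        finetune_epochs = 5, seed = 4)
  f1 <- dnfold_fit(fix$x, fix$y, arch = c(2, 5, 1), control = ctl)
  f2 <- dnfold_fit(fix$x, fix$y, arch = c(2, 5, 1), control = ctl)
  expect_identical(f1$layers, f2$layers)
  expect_identical(fitted(f1), fitted(f2))
})

test_that("regressor converges to constant targets", {
  set.seed(10)
  x <- matrix(runif(1000 * 4), 1000, 4)
  fit <- dnfoldr_fit(x, rep(0.37, 1000), arch = c(4, 16, 8, 1),
                     control = dnfoldr_control(batch_size = 16, seed = 1))
  expect_lt(mean((predict(fit, x) - 0.37)^2), 1e-3)
  expect_lte(fit$final_loss, fit$loss_history[1])
})

test_that("regressor recovers a noiseless linear similarity map out of sample", {
  set.seed(11)
  n <- 2000; F <- 8
  x <- matrix(runif(n * F), n, F)
  w <- seq(0.05, 0.2, length.out = F)
  tm <- as.numeric(x %*% w / sum(w))
  tr <- 1:1500; te <- 1501:2000
  fit <- dnfoldr_fit(x[tr, ], tm[tr], arch = c(F, 32, 16, 1),
                     control = dnfoldr_control(batch_size = 32, seed = 1))
  expect_lt(mean_absolute_deviation(predict(fit, x[te, ]), tm[te]), 0.05)
})

test_that("regressor validates targets and clamps reported predictions", {
  x <- matrix(runif(40), 10, 4)
  expect_error(dnfoldr_fit(x, runif(10) + 1), "\\[0, 1\\]")
  set.seed(3)
  fit <- dnfoldr_fit(x, runif(10), arch = c(4, 3, 3, 1),
                     control = dnfoldr_control(batch_size = 5, epochs = 2, seed = 5))
  p <- predict(fit, x)
  expect_true(all(p >= 0 & p <= 1))
  raw <- predict(fit, x, type = "raw")
  expect_equal(p, pmin(pmax(raw, 0), 1))
})

test_that("mean absolute deviation matches elementwise recomputation", {
  expect_equal(mean_absolute_deviation(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_absolute_deviation(0.5, 0.4), 0.1)
  set.seed(14)
  a <- runif(100); b <- runif(100)
  expect_equal(mean_absolute_deviation(a, b), sum(abs(a - b)) / 100)
  expect_error(mean_absolute_deviation(1:3, 1:2), "equal length")
})

test_that("saved models reload and predict bit-identically", {
  fix <- make_separable_data(n = 50, seed = 7)
  fit <- dnfold_fit(fix$x, fix$y, arch = c(2, 4, 1),
                    control = dnfold_control(batch_size = 10,
                                             pretrain_epochs = 2,
                                             finetune_epochs = 3, seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  save_deepnet(fit, path)
  back <- load_deepnet(path)
  expect_identical(predict(back, fix$x), predict(fit, fix$x))

  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), junk)
  expect_error(load_deepnet(junk), "not a dnfold")
})

test_that("feature-width mismatches are caught at prediction time", {
  fix <- make_separable_data(n = 40, seed = 8)
  fit <- dnfold_fit(fix$x, fix$y, arch = c(2, 3, 1),
                    control = dnfold_control(batch_size = 10,
                                             pretrain_epochs = 1,
                                             finetune_epochs = 2, seed = 3))
  expect_error(predict(fit, matrix(runif(9), 3, 3)), "features")
})
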