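# small synthetic learning problems for the engine
make_toy <- function(n, f, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(stats::rnorm(n * f), n, f) + outer(y, rep(1, f)) * 0.8
  list(x = x, y = y)
}

test_that("identical seeds give identical training histories and models", {
  toy <- make_toy(16, 16)
  spec <- model_spec("conv1d_energy", "test")
  cfg <- train_config(epochs = 5, seed = 99)
  f1 <- train_model(spec, toy$x, toy$y, cfg)
  f2 <- train_model(spec, toy$x, toy$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$layers, f2$network$layers)
  p1 <- classify(f1, toy$x)
  p2 <- classify(f2, toy$x)
  expect_identical(p1$probability, p2$probability)
})

test_that("zero epochs returns the untouched initialization", {
  toy <- make_toy(8, 16)
  spec <- model_spec("conv1d_energy", "test")
  fit <- train_model(spec, toy$x, toy$y, train_config(epochs = 0, seed = 3))
  expect_identical(nrow(fit$history), 0L)
  # the returned network equals a fresh build under the same seed
  old <- mvmdm:::.Random.seed_guard(3L)
  ref <- mvmdm:::build_network(spec)
  old()
  expect_identical(fit$network$layers, ref$layers)
})

test_that("a small network memorizes a tiny training set", {
  toy <- make_toy(8, 16, seed = 7)
  spec <- model_spec("conv1d_energy", "test")
  fit <- train_model(spec, toy$x, toy$y,
                     train_config(epochs = 200, seed = 7))
  expect_equal(utils::tail(fit$history$accuracy, 1), 1)
  pred <- classify(fit, toy$x)
  expect_identical(pred$label, as.integer(toy$y))
})

test_that("loss is non-increasing on the convex single-layer probe", {
  # dense(1, sigmoid) alone is logistic regression: full-batch descent at
  # lr 0.001 must not increase the loss over the first epochs
  toy <- make_toy(32, 8, seed = 11)
  spec <- structure(
    list(name = "conv1d_energy", profile = "test", input_shape = 8L,
         layers = list(mvmdm:::layer_spec("dense", units = 1L,
                                          activation = "sigmoid"))),
    class = "mvmdm_model_spec"
  )
  fit <- train_model(spec, toy$x, toy$y,
                     train_config(epochs = 10, batch_size = 32, seed = 2))
  expect_true(all(diff(fit$history$loss) <= 1e-8))
})

test_that("training rejects malformed problems", {
  toy <- make_toy(8, 16)
  spec <- model_spec("conv1d_energy", "test")
  expect_error(train_model(spec, toy$x, rep(1, 8), train_config()),
               "single class")
  expect_error(train_model(spec, toy$x[, 1:5], toy$y, train_config()),
               "does not match")
  expect_error(train_model(spec, toy$x, toy$y[-1], train_config()), "sizes")
  expect_error(train_model(spec, toy$x, c(rep(0, 4), rep(2, 4)),
                           train_config()), "binary")
})

test_that("classification thresholds behave at the decision boundary", {
  toy <- make_toy(12, 16, seed = 5)
  spec <- model_spec("conv1d_energy", "test")
  fit <- train_model(spec, toy$x, toy$y, train_config(epochs = 3, seed = 5))
  pred <- classify(fit, toy$x)
  # label = 1 iff probability >= threshold
  expect_identical(pred$label, as.integer(pred$probability >= 0.5))
  # the near-threshold regime: 0.5149 >= 0.5 classifies as disease
  expect_identical(as.integer(0.5149 >= 0.5), 1L)
  expect_error(classify(fit, toy$x, threshold = 1), "strictly inside")
  expect_error(classify(fit, toy$x[, 1:4]), "does not match")
})

test_that("feature matrices preserve shapes and reject ragged input", {
  m <- features_to_matrix(list(matrix(1:6, 2, 3), matrix(7:12, 2, 3)))
  expect_identical(dim(m), c(2L, 6L))
  expect_identical(attr(m, "input_shape"), c(2L, 3L, 1L))
  expect_error(
    features_to_matrix(list(matrix(1, 2, 3), matrix(1, 3, 2))),
    "inconsistent"
  )
})

test_that("k-fold evaluation is stratified, deterministic and summarized", {
  f <- fixture_features(0.6)$features
  spec <- model_spec("conv1d_energy", "test")
  cfg <- train_config(epochs = 20, k_folds = 5)
  kf <- kfold_evaluate(f$d1, f$y, spec, cfg, seeds = c(41, 42))
  expect_identical(nrow(kf), 10L)
  expect_identical(sort(unique(kf$fold)), 1:5)
  by_seed <- glance(kf)
  expect_identical(nrow(by_seed), 2L)
  expect_true(all(by_seed$mean_accuracy >= 0 & by_seed$mean_accuracy <= 1))

  kf2 <- kfold_evaluate(f$d1, f$y, spec, cfg, seeds = c(41, 42))
  expect_identical(as.data.frame(kf), as.data.frame(kf2))

  idx <- c(1:3, 11:13)  # three subjects per class, fewer than k = 5
  expect_error(kfold_evaluate(f$d1[idx, ], f$y[idx], spec, cfg, seeds = 1),
               "folds")
  expect_error(kfold_evaluate(f$d1[1:6, ], f$y[1:6], spec, cfg, seeds = 1),
               "both classes")
})

test_that("tidiers expose history and summaries", {
  toy <- make_toy(8, 16)
  spec <- model_spec("conv1d_energy", "test")
  fit <- train_model(spec, toy$x, toy$y, train_config(epochs = 4, seed = 1))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_identical(g$epochs, 4L)
  expect_identical(g$route, "conv1d_energy")
  expect_s3_class(autoplot(fit), "ggplot")
})
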