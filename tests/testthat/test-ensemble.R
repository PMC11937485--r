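test_that("max vote equals brute-force majority on all 8 triples", {
  grid <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (i in seq_len(nrow(grid))) {
    v <- as.integer(grid[i, ])
    expect_identical(max_vote(v), oracle_majority(v))
    # order invariance
    expect_identical(max_vote(rev(v)), max_vote(v))
  }
})

test_that("the worked prediction rows fuse as majority votes", {
  # route votes (1D, 2D, 3D): disease = 1, healthy = 0
  expect_identical(max_vote(c(1, 0, 0)), 0L)  # one disease vote -> healthy
  expect_identical(max_vote(c(1, 0, 1)), 1L)  # two disease votes -> disease
  expect_identical(max_vote(c(1, 1, 1)), 1L)  # unanimity
  expect_identical(max_vote(c(0, 0, 0)), 0L)
  # the symbol-table reading of the same rows is also a majority vote
  expect_identical(max_vote(c(0, 1, 1)), 1L)
  expect_identical(max_vote(c(0, 1, 0)), 0L)
})

test_that("vote validation and the even-ensemble tie-break", {
  expect_error(max_vote(c(0, 2, 1)), "binary")
  expect_error(max_vote(integer(0)), "no votes")
  expect_error(max_vote(c(0, 1)), "tie")
  expect_identical(max_vote(c(0, 1), probabilities = c(0.2, 0.9)), 1L)
  expect_identical(max_vote(c(0, 1), probabilities = c(0.1, 0.6)), 0L)
})

test_that("confusion counts partition the sample and match a loop oracle", {
  y <- c(1, 0, 1, 1, 0)
  expect_identical(unclass(confusion_matrix(y, y))[c("FP", "FN")],
                   list(FP = 0L, FN = 0L))
  flip <- confusion_matrix(y, 1 - y)
  expect_identical(flip$TP + flip$TN, 0L)

  set.seed(701)
  yt <- sample(0:1, 20, replace = TRUE)
  yp <- sample(0:1, 20, replace = TRUE)
  cm <- confusion_matrix(yt, yp)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:20) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1L
    if (yt[i] == 0 && yp[i] == 0) tn <- tn + 1L
    if (yt[i] == 0 && yp[i] == 1) fp <- fp + 1L
    if (yt[i] == 1 && yp[i] == 0) fn <- fn + 1L
  }
  expect_identical(unclass(cm)[c("TP", "TN", "FP", "FN")],
                   list(TP = tp, TN = tn, FP = fp, FN = fn))
  expect_identical(cm$TP + cm$TN + cm$FP + cm$FN, 20L)

  expect_error(confusion_matrix(c(0, 1), c(1)), "lengths")
  expect_error(confusion_matrix(c(0, 2), c(1, 0)), "binary")
})

test_that("metrics reproduce the cross-cohort ensemble arithmetic", {
  # ensemble row: TN 73, FP 1, FN 0, TP 71
  m <- compute_metrics(list(TN = 73, FP = 1, FN = 0, TP = 71))
  expect_equal(round(m$accuracy, 2), 99.31)
  expect_equal(round(m$precision, 2), 98.61)
  expect_equal(m$sensitivity, 100)
  expect_equal(round(m$specificity, 2), 98.65)  # 73/74; prints as 98.64 when truncated
  expect_equal(round(m$f1, 2), 99.30)

  # 1D route on the diagonal-detail subband: TN 71, FP 3, FN 9, TP 62
  m <- compute_metrics(list(TN = 71, FP = 3, FN = 9, TP = 62))
  expect_equal(round(m$accuracy, 2), 91.72)
  expect_equal(round(m$precision, 2), 95.38)
  expect_equal(round(m$sensitivity, 2), 87.32)
  expect_equal(round(m$specificity, 2), 95.95)  # 71/74; prints as 95.94 when truncated
  expect_equal(round(m$f1, 2), 91.18)  # 124/136; prints as 91.17 when truncated

  # perfect classification
  m <- compute_metrics(list(TN = 10, FP = 0, FN = 0, TP = 10))
  expect_true(all(unlist(m) == 100))
})

test_that("undefined metrics are NA, never zero", {
  m <- compute_metrics(list(TN = 5, FP = 0, FN = 0, TP = 0))
  expect_identical(m$precision, NA_real_)
  expect_identical(m$sensitivity, NA_real_)
  expect_identical(m$f1, NA_real_)
  expect_equal(m$specificity, 100)
  expect_error(compute_metrics(list(TN = 0, FP = 0, FN = 0, TP = 0)),
               "empty")
})

test_that("metric identities hold across random confusion matrices", {
  set.seed(702)
  for (i in 1:25) {
    cm <- list(TN = sample(1:50, 1), FP = sample(1:50, 1),
               FN = sample(1:50, 1), TP = sample(1:50, 1))
    m <- compute_metrics(cm)
    # F1 lies between precision and sensitivity
    expect_gte(m$f1 + 1e-9, min(m$precision, m$sensitivity))
    expect_lte(m$f1 - 1e-9, max(m$precision, m$sensitivity))
    # accuracy invariant under simultaneous label swap
    sw <- compute_metrics(list(TN = cm$TP, TP = cm$TN, FP = cm$FN,
                               FN = cm$FP))
    expect_equal(sw$accuracy, m$accuracy)
    # sensitivity and specificity exchange under label inversion
    expect_equal(sw$sensitivity, m$specificity)
    expect_equal(sw$specificity, m$sensitivity)
  }
})

test_that("confusion tidiers expose counts and derived metrics", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
  td <- tidy(cm)
  expect_identical(names(td), c("TN", "FP", "FN", "TP"))
  expect_equal(glance(cm)$accuracy, 50)
})

test_that("generalization runs refuse subject leakage", {
  man <- fixture_features(0.6)$manifest
  expect_error(generalization_run(man, man, train_config()), "leakage")
  expect_error(generalization_run(man, man[5:10, ], train_config()),
               "leakage")
})
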