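ref_traces <- list(
  conv1d_energy = list(c(86L, 32L), c(43L, 32L), c(41L, 64L), c(20L, 64L),
                       1280L, 64L, 1L),
  conv2d_fused = list(c(126L, 126L, 32L), c(126L, 126L, 32L),
                      c(63L, 63L, 32L), c(61L, 61L, 64L), c(61L, 61L, 64L),
                      c(30L, 30L, 64L), c(28L, 28L, 128L),
                      c(28L, 28L, 128L), c(14L, 14L, 128L), 25088L, 128L,
                      128L, 1L),
  conv3d_volume = list(c(87L, 126L, 126L, 32L), c(87L, 63L, 63L, 32L),
                       c(86L, 61L, 61L, 64L), c(86L, 30L, 30L, 64L),
                       c(85L, 28L, 28L, 64L), c(85L, 14L, 14L, 64L),
                       c(84L, 12L, 12L, 64L), c(84L, 6L, 6L, 64L),
                       193536L, 128L, 1L)
)

test_that("shape traces reproduce the reference output-shape columns", {
  for (nm in names(ref_traces)) {
    expect_identical(shape_trace(model_spec(nm, "paper")), ref_traces[[nm]],
                     info = nm)
  }
})

test_that("parameter counts reproduce the reference totals", {
  pc1 <- parameter_count(model_spec("conv1d_energy"))
  expect_identical(pc1$total, 88385)
  expect_identical(pc1$non_trainable, 0)

  pc2 <- parameter_count(model_spec("conv2d_fused"))
  expect_identical(pc2$total, 3305089)
  expect_identical(pc2$trainable, 3304641)
  expect_identical(pc2$non_trainable, 448)

  pc3 <- parameter_count(model_spec("conv3d_volume"))
  expect_identical(pc3$total, 24957985)
  expect_identical(pc3$non_trainable, 0)
})

test_that("total parameters always split into trainable + non-trainable", {
  for (nm in names(ref_traces)) {
    for (profile in c("paper", "test")) {
      pc <- parameter_count(model_spec(nm, profile))
      expect_identical(pc$total, pc$trainable + pc$non_trainable)
      expect_true(all(pc$by_layer$trainable >= 0))
    }
  }
})

test_that("architecture structure matches the reference layer lists", {
  s1 <- model_spec("conv1d_energy")
  expect_identical(s1$input_shape, c(88L, 1L))
  expect_length(s1$layers, 7)

  s2 <- model_spec("conv2d_fused")
  kinds2 <- vapply(s2$layers, `[[`, "", "kind")
  expect_identical(sum(kinds2 == "batchnorm"), 3L)
  drop_i <- which(kinds2 == "dropout")
  expect_equal(s2$layers[[drop_i]]$rate, 0.2)

  s3 <- model_spec("conv3d_volume")
  kinds3 <- vapply(s3$layers, `[[`, "", "kind")
  expect_identical(sum(kinds3 == "conv3d"), 4L)
  expect_identical(sum(kinds3 == "maxpool3d"), 4L)

  # every route ends in a single sigmoid unit
  for (s in list(s1, s2, s3)) {
    last <- s$layers[[length(s$layers)]]
    expect_identical(last$kind, "dense")
    expect_identical(last$units, 1L)
    expect_identical(last$activation, "sigmoid")
  }

  expect_error(model_spec("conv4d"), "arg")
})

test_that("shape tracing rejects collapsing architectures", {
  expect_error(model_spec("conv1d_energy", input_shape = c(4L, 1L)),
               "collapses")
})

test_that("the architecture self-check passes", {
  chk <- check_architecture()
  expect_true(attr(chk, "ok"))
  expect_true(all(chk$matches))
})

test_that("training configuration validates its bounds", {
  expect_error(train_config(threshold = 1), "threshold")
  expect_error(train_config(threshold = 0), "threshold")
  expect_error(train_config(epochs = -1), "epochs")
  expect_error(train_config(k_folds = 1), "k_folds")
  cfg <- train_config()
  expect_identical(cfg$epochs, 20L)
  expect_identical(cfg$batch_size, 32L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_identical(cfg$k_folds, 5L)
})

test_that("the architecture dump serializes traces and counts", {
  p <- withr::local_tempfile(fileext = ".json")
  architecture_dump("paper", p)
  dumped <- jsonlite::read_json(p)
  expect_length(dumped, 3)
  totals <- vapply(dumped, `[[`, numeric(1), "total_parameters")
  expect_setequal(totals, c(88385, 3305089, 24957985))
})
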