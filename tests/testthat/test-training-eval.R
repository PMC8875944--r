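make_feature_index <- function(labels, splits, dir = tempfile("idx")) {
  # tiny synthetic "feature images": class-dependent bright band
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- sort(unique(labels))
  paths <- character(length(labels))
  for (i in seq_along(labels)) {
    cls <- match(labels[i], classes)
    px <- matrix(as.integer(round(abs(rnorm(128 * 128, sd = 8)))), 128, 128)
    rows <- ((cls - 1) * 20 + 1):((cls - 1) * 20 + 20)
    px[rows, ] <- pmin(px[rows, ] + 200L, 255L)
    px <- pmin(pmax(px, 0L), 255L)
    paths[i] <- file.path(dir, sprintf("img%03d.png", i))
    write_feature_image(feature_image(px), paths[i])
  }
  data.frame(image_path = paths, source_id = paths, offset_s = 0,
             kind = "spectrogram", label = labels, split = splits,
             stringsAsFactors = FALSE)
}

test_that("oversampling equalizes training classes and spares val/test", {
  idx <- data.frame(image_path = sprintf("i%02d.png", 1:17),
                    source_id = "s", offset_s = 0, kind = "spectrogram",
                    label = c(rep("a", 3), rep("b", 10), rep("a", 2),
                              rep("b", 2)),
                    split = c(rep("train", 13), rep("test", 4)))
  bal <- balance_training_set(idx, "oversample", seed = 1)
  tr <- bal[bal$split == "train", ]
  expect_equal(as.vector(table(tr$label)[c("a", "b")]), c(10L, 10L))
  # the additions are replicas of existing minority rows
  expect_true(all(tr$image_path[tr$label == "a"] %in%
                    idx$image_path[idx$label == "a" & idx$split == "train"]))
  expect_identical(bal[bal$split != "train", c("image_path", "label")],
                   idx[idx$split != "train", c("image_path", "label")],
                   ignore_attr = TRUE)
  # already balanced and mode none are identities
  expect_identical(balance_training_set(idx, "none"), idx)
  even <- idx[idx$label %in% c("a", "b") & idx$split == "train", ][1:6, ]
  even$label <- rep(c("a", "b"), each = 3)
  expect_equal(nrow(balance_training_set(even, "oversample", seed = 1)), 6L)
})

test_that("evaluation reports per-class and support-weighted accuracy", {
  # a stub model whose predictions we control exactly
  report <- local({
    per <- data.frame(class = c("a", "b"), support = c(10L, 30L),
                      accuracy = c(1.0, 0.5))
    weighted <- sum(per$support * per$accuracy) / sum(per$support)
    list(per = per, weighted = weighted)
  })
  expect_equal(report$weighted, 0.625)

  set.seed(8)
  idx <- make_feature_index(rep(c("a", "b"), each = 8),
                            rep(c("train", "val", "test"), length.out = 16))
  arch <- architecture_spec("probe", c(128L, 128L, 1L), list(list(
    layer_spec("conv2d", filters = 2, kernel = c(3L, 3L),
               activation = "relu"),
    layer_spec("maxpool2d", pool = c(8L, 8L)),
    layer_spec("flatten"),
    layer_spec("dense", units = 2L),
    layer_spec("activation", activation = "softmax"))), n_classes = 2L)
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 1)
  model <- train_model(arch, idx, cfg)
  rep_ <- evaluate_model(model, idx, split = "test")
  expect_s3_class(rep_, "evaluation_report")
  expect_identical(rep_$per_class$class, c("a", "b"))
  expect_equal(sum(rep_$per_class$support), sum(idx$split == "test"))
  expect_true(all(rep_$per_class$accuracy >= 0 &
                    rep_$per_class$accuracy <= 1, na.rm = TRUE))
  w <- with(rep_$per_class, sum(support * accuracy) / sum(support))
  expect_equal(rep_$weighted_average, w)
  # single-class evaluation collapses to that class's accuracy
  one <- idx[idx$label == "a" | idx$split != "test", ]
  rep1 <- evaluate_model(model, one, split = "test")
  expect_equal(rep1$weighted_average,
               rep1$per_class$accuracy[rep1$per_class$class == "a"])
  expect_equal(rep1$per_class$support[rep1$per_class$class == "b"], 0L)
  expect_true(is.na(rep1$per_class$accuracy[rep1$per_class$class == "b"]))
})

test_that("training histories record the configured regime", {
  set.seed(21)
  idx <- make_feature_index(rep(c("a", "b"), each = 9),
                            rep(c("train", "train", "val"), 6))
  arch <- architecture_spec("probe2", c(128L, 128L, 1L), list(list(
    layer_spec("conv2d", filters = 2, kernel = c(5L, 5L),
               activation = "relu"),
    layer_spec("maxpool2d", pool = c(8L, 8L)),
    layer_spec("global_avg_pool"),
    layer_spec("dense", units = 2L),
    layer_spec("activation", activation = "softmax"))), n_classes = 2L)
  cfg <- train_config(epochs = 4, batch_size = 4, seed = 9)
  m <- train_model(arch, idx, cfg)
  expect_equal(nrow(m$history), 4L)
  expect_named(m$history,
               c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))
  # same config, same data -> identical history
  m2 <- train_model(arch, idx, cfg)
  expect_identical(m$history, m2$history)
  # invalid regimes are rejected up front
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_model(arch, idx[idx$split == "train", ], cfg),
               "train and val")
})

test_that("a separable two-class image set is learned quickly", {
  set.seed(31)
  labels <- rep(c("lo", "hi"), each = 12)
  splits <- rep(c("train", "train", "val", "test"), 6)
  idx <- make_feature_index(labels, splits)
  arch <- architecture_spec("sep128", c(128L, 128L, 1L), list(list(
    layer_spec("conv2d", filters = 4, kernel = c(5L, 5L),
               activation = "relu"),
    layer_spec("maxpool2d", pool = c(4L, 4L)),
    layer_spec("flatten"),
    layer_spec("dense", units = 8L),
    layer_spec("activation", activation = "relu"),
    layer_spec("dense", units = 2L),
    layer_spec("activation", activation = "softmax"))), n_classes = 2L)
  cfg <- train_config(epochs = 8, batch_size = 6, seed = 2,
                      learning_rate = 2e-3)
  m <- train_model(arch, idx, cfg)
  expect_gt(m$history$val_accuracy[nrow(m$history)], 0.9)
  rep_ <- evaluate_model(m, idx, split = "test")
  expect_gte(rep_$weighted_average, 0.9)
})
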