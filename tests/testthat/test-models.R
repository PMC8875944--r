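test_that("FDC-1 reproduces its printed shapes and parameter totals", {
  spec <- build_fdc1(6)
  pc <- count_parameters(spec)
  expect_equal(pc$trainable, 241174)
  expect_equal(pc$non_trainable, 0)
  shapes <- infer_shapes(spec)$branches[[1]]
  expect_equal(shapes[[1]]$shape, c(124, 124, 24))   # conv-1
  expect_equal(shapes[[2]]$shape, c(31, 62, 24))     # pool 4x2
  expect_equal(shapes[[9]]$shape, 2400)              # flatten width
  # first conv holds 24 * (5*5*1 + 1) = 624 weights
  expect_equal(unname(fdcnet:::layer_param_count(spec$branches[[1]][[1]],
                                                 c(128, 128, 1))["trainable"]),
               624)
})

test_that("FDC-2 reproduces its printed shapes and parameter totals", {
  spec <- build_fdc2(6)
  pc <- count_parameters(spec)
  expect_equal(pc$trainable, 879430)
  sh <- infer_shapes(spec)$branches[[1]]
  expect_equal(sh[[1]]$shape, c(126, 126, 32))
  expect_equal(sh[[3]]$shape, c(31, 63, 32))         # floor pooling
  expect_equal(sh[[4]]$shape, c(29, 61, 64))
  expect_equal(sh[[6]]$shape, c(7, 30, 64))
  expect_equal(sh[[7]]$shape, 13440)
  # dense(64) on 13,440 inputs and the second conv
  lp <- vapply(seq_along(spec$branches[[1]]), function(i) {
    shape <- if (i == 1) c(128, 128, 1) else sh[[i - 1]]$shape
    unname(fdcnet:::layer_param_count(spec$branches[[1]][[i]],
                                      shape)["trainable"])
  }, 0)
  expect_equal(lp[4], 18496)
  expect_equal(lp[9], 860224)
})

test_that("FDC-3 reproduces batch-norm accounting and ceil pooling", {
  spec <- build_fdc3(6)
  pc <- count_parameters(spec)
  expect_equal(pc$trainable, 362214)
  expect_equal(pc$non_trainable, 1152)
  expect_equal(pc$total, 363366)
  # batch-norm parameters total 4 per channel, exactly half non-trainable
  bn_channels <- c(32, 32, 64, 64, 64, 64, 128, 128)
  expect_equal(4 * sum(bn_channels), 2304)
  expect_equal(pc$non_trainable, 2 * sum(bn_channels))
  sh <- infer_shapes(spec)$branches[[1]]
  shapes <- lapply(sh, `[[`, "shape")
  has_shape <- function(s) any(vapply(shapes, function(x)
    length(x) == length(s) && all(x == s), TRUE))
  # ceiling pooling: 61 -> 31, 29 -> 15, 13 -> 7
  expect_true(has_shape(c(31, 31, 64)))
  expect_true(has_shape(c(15, 15, 64)))
  expect_true(has_shape(c(7, 7, 128)))
  expect_equal(shapes[[length(shapes) - 2]], 128)    # global average pool
})

test_that("FDC-FS fuses 64 + 64 + 128 features and matches its totals", {
  spec <- build_fdcfs(6)
  pc <- count_parameters(spec)
  expect_equal(pc$total, 1483958)
  expect_equal(pc$trainable, 1482806)
  sh <- infer_shapes(spec)
  widths <- vapply(sh$branches, function(b) b[[length(b)]]$shape[1], 0)
  expect_equal(widths, c(64, 64, 128))
  expect_equal(sh$head[[1]]$shape, 256)
  # fusion dense: 256 * 6 + 6
  expect_equal(unname(fdcnet:::layer_param_count(spec$fusion_head[[2]],
                                                 256)["trainable"]), 1542)
  # accounting identity: branch totals minus their final dense layers
  expect_equal(240784 + 879040 + 362592 + 1542, 1483958)
  b_totals <- vapply(c("fdc1", "fdc2", "fdc3"), function(m)
    count_parameters(build_architecture(m, 6))$total, 0)
  final_dense <- c(64 * 6 + 6, 64 * 6 + 6, 128 * 6 + 6)
  expect_equal(unname(sum(b_totals - final_dense) + 1542), pc$total)
})

test_that("changing n_classes only moves the final dense layer", {
  for (m in c("fdc1", "fdc2", "fdc3", "fdcfs")) {
    width <- switch(m, fdc1 = 64, fdc2 = 64, fdc3 = 128, fdcfs = 256)
    p6 <- count_parameters(build_architecture(m, 6))
    p10 <- count_parameters(build_architecture(m, 10))
    expect_equal(p10$trainable - p6$trainable, (width + 1) * 4,
                 label = m)
    expect_equal(p10$non_trainable, p6$non_trainable)
  }
  expect_equal(count_parameters(build_fdc1(10))$trainable, 241434)
})

test_that("every built spec ends in a softmax dense of n_classes", {
  for (m in c("fdc1", "fdc2", "fdc3", "fdcfs")) {
    spec <- build_architecture(m, 6)
    tail_layers <- if (is.null(spec$fusion_head))
      spec$branches[[length(spec$branches)]] else spec$fusion_head
    k <- length(tail_layers)
    expect_identical(tail_layers[[k]]$activation, "softmax")
    expect_identical(tail_layers[[k - 1]]$kind, "dense")
    expect_equal(tail_layers[[k - 1]]$units, 6L)
  }
  expect_error(build_fdc1(1), ">= 2")
  expect_error(architecture_spec("bad", c(8, 8, 1),
                                 list(list(layer_spec("flatten"),
                                           layer_spec("dense", units = 3))),
                                 n_classes = 3),
               "softmax")
})

test_that("parameter accounting matches the tensor-enumeration oracle", {
  for (m in c("fdc1", "fdc2", "fdc3", "fdcfs")) {
    spec <- build_architecture(m, 6)
    pc <- count_parameters(spec)
    oc <- oracle_count_params(spec)
    expect_equal(pc$trainable, oc$trainable, label = m)
    expect_equal(pc$non_trainable, oc$non_trainable, label = m)
    expect_equal(pc$total, pc$trainable + pc$non_trainable)
  }
  set.seed(2024)
  for (i in 1:100) {
    spec <- random_small_arch()
    pc <- count_parameters(spec)
    oc <- oracle_count_params(spec)
    expect_identical(unclass(pc)[c("total", "trainable", "non_trainable")],
                     oc[c("total", "trainable", "non_trainable")])
  }
})

test_that("impossible geometries raise structural errors", {
  expect_error(architecture_spec("bad", c(4, 4, 1), list(list(
    layer_spec("conv2d", filters = 2, kernel = c(7L, 7L)),
    layer_spec("flatten"),
    layer_spec("dense", units = 2),
    layer_spec("activation", activation = "softmax"))), n_classes = 2),
    "larger than its input")
})

test_that("architectures round-trip through YAML serialization", {
  for (m in c("fdc2", "fdcfs")) {
    spec <- build_architecture(m, 6)
    f <- tempfile(fileext = ".yaml")
    write_architecture(spec, f)
    back <- read_architecture(f)
    expect_equal(count_parameters(back), count_parameters(spec))
    expect_identical(format(back), format(spec))
  }
})

test_that("the rendered table shows the reference layout landmarks", {
  txt <- format(build_fdc1(6))
  expect_true(any(grepl("Conv2D +\\(None, 124, 124, 24\\) +624", txt)))
  expect_true(any(grepl("Total Parameters: 241,174", txt)))
  txt3 <- format(build_fdc3(6))
  expect_true(any(grepl("Non-Trainable Parameters: 1,152", txt3)))
})
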