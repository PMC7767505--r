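test_that("default architecture has the closed-form parameter counts", {
  m <- build_model(arch_config(), input_length = 81L)
  counts <- count_parameters(m)
  expect_equal(counts[["conv1"]], (7 * 4 + 1) * 32)    # 928
  expect_equal(counts[["conv2"]], (5 * 32 + 1) * 32)   # 5152
  # same padding: 81 -> pool 40 -> pool 20, flatten 20*32 = 640
  expect_equal(counts[["dense1"]], (640 + 1) * 16)     # 10256
  expect_equal(counts[["dense2"]], 16 + 1)
  expect_equal(
    m$layers,
    c("conv1", "relu", "batchnorm", "avgpool", "dropout",
      "conv2", "relu", "avgpool", "dropout",
      "flatten", "dense1_relu", "dense2_sigmoid"))
  # the batch-norm placement switch flips the order
  m2 <- build_model(arch_config(batchnorm_before_relu = TRUE), 81L)
  expect_equal(m2$layers[2:3], c("batchnorm", "relu"))
})

test_that("activations and loss match their definitions", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(2), 2)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0.5)), c(0, 0.5))
  expect_equal(sigmoid(0), 0.5)

  expect_lt(binary_cross_entropy(1 - 1e-9, 1), 1e-6)
  expect_equal(binary_cross_entropy(c(0.5, 0.5), c(1, 0)), log(2))
  p <- c(0.9, 0.2, 0.6, 0.4); y <- c(1, 0, 0, 1)
  ord <- c(3, 1, 4, 2)
  expect_equal(binary_cross_entropy(p, y),
               binary_cross_entropy(p[ord], y[ord]))
  expect_error(binary_cross_entropy(c(0.5, 0.5), 1), "equal length")
})

test_that("untrained model outputs probabilities in (0,1)", {
  m <- build_model(tiny_arch(), input_length = 81L, seed = 3)
  p <- predict_proba(m, random_dna(10, 81, seed = 4))
  expect_length(p, 10)
  expect_true(all(p > 0 & p < 1))
})

test_that("build and fit validate their inputs", {
  expect_error(build_model(arch_config(), input_length = 5L), "kernel")
  m <- build_model(tiny_arch(), input_length = 20L)
  x <- random_dna(6, 20, seed = 5)
  expect_error(fit(m, x, rep(1, 6), tiny_train()), "both classes")
  expect_error(fit(m, x, rep(c(0, 1), 4), tiny_train()), "sizes differ")
  expect_error(predict_proba(m, random_dna(2, 21, seed = 6)),
               "does not match")
})

test_that("training is deterministic given the seed and reduces the loss", {
  ds <- promn_dataset(n_each = 40)
  y <- as.numeric(ds$label != "NON_PROMOTER")
  m <- build_model(tiny_arch(), 81L)
  f1 <- fit(m, ds$seq, y, tiny_train(epochs = 5L, seed = 9L))
  f2 <- fit(m, ds$seq, y, tiny_train(epochs = 5L, seed = 9L))
  expect_identical(f1$params, f2$params)
  f3 <- fit(m, ds$seq, y, tiny_train(epochs = 5L, seed = 10L))
  expect_false(identical(f1$params, f3$params))
  expect_length(f1$loss_trace, 5)
  expect_lt(f1$loss_trace[5], f1$loss_trace[1])
})

test_that("inference is a pure function and batch-size invariant", {
  ds <- promn_dataset(n_each = 30)
  y <- as.numeric(ds$label != "NON_PROMOTER")
  m <- fit(build_model(tiny_arch(), 81L), ds$seq, y, tiny_train())
  seqs <- random_dna(8, 81, seed = 12)
  batched <- predict_proba(m, seqs)
  expect_identical(batched, predict_proba(m, seqs))
  singly <- vapply(seqs, function(s) predict_proba(m, s), 0,
                   USE.NAMES = FALSE)
  expect_equal(singly, batched, tolerance = 1e-12)
  # duplicate inputs get identical probabilities
  dup <- predict_proba(m, c(seqs[1], seqs[1]))
  expect_equal(dup[1], dup[2])
})

test_that("larger L2 penalties shrink the trained weight norm", {
  ds <- promn_dataset(n_each = 30)
  y <- as.numeric(ds$label != "NON_PROMOTER")
  norms <- vapply(c(1e-4, 1e-2, 1), function(lam) {
    m <- fit(build_model(tiny_arch(l2_lambda = lam), 81L), ds$seq, y,
             tiny_train(epochs = 4L, seed = 2L))
    sqrt(sum(m$params$conv1_W^2) + sum(m$params$conv2_W^2) +
           sum(m$params$dense1_W^2) + sum(m$params$dense2_W^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("model bundles round-trip exactly and reject corruption", {
  ds <- promn_dataset(n_each = 25)
  y <- as.numeric(ds$label != "NON_PROMOTER")
  m <- fit(build_model(tiny_arch(), 81L, name = "ProMN"), ds$seq, y,
           tiny_train())
  probe <- random_dna(5, 81, seed = 20)
  dir <- tempfile("bundle")
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- load_model(dir)
  expect_identical(predict_proba(m2, probe), predict_proba(m, probe))
  expect_equal(m2$name, "ProMN")
  expect_equal(unclass(m2$arch), unclass(m$arch))

  # mismatched architecture in the manifest
  mf <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  manifest$arch$conv1_filters <- 8L
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  expect_error(load_model(dir), "does not match")

  # corrupt weight blob
  save_model(m, dir)
  writeLines("garbage", file.path(dir, "weights.rds"))
  expect_error(load_model(dir), "corrupt")
  expect_error(load_model(tempfile()), "not a model bundle")
})
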