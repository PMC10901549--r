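# the toy axis (64 bins) keeps the networks small and training fast

test_that("model configuration validates shapes and reports parameter counts", {
  cfg <- model_config("fli_lenet", n_classes = 2L,
                      input_shape = c(21L, 21L, 64L))
  m <- build_model(cfg)
  # the output dense layer alone contributes (64 + 1) * 2 = 130 parameters
  expect_equal(length(m$weights$out_W) + length(m$weights$out_b), 130L)
  # hand-computed per-layer total for this configuration
  d3 <- c(21L, 21L, 64L) %/% 4L                   # after two 2x2x2 pools
  flat <- 16L * prod(d3)
  hand <- (8 * 27 + 8) + (16 * 8 * 27 + 16) +
    (64 * flat + 64) + (2 * 64 + 2)
  expect_equal(count_parameters(m), hand)
  expect_error(model_config(input_shape = c(3L, 21L, 64L)), "pooling")
})

test_that("weight initialisation is a pure function of config seed", {
  cfg <- model_config("fli_resnet", n_classes = 3L,
                      input_shape = c(21L, 21L, 64L), seed = 9L)
  expect_identical(build_model(cfg)$weights, build_model(cfg)$weights)
  cfg2 <- cfg
  cfg2$seed <- 10L
  expect_false(identical(build_model(cfg)$weights, build_model(cfg2)$weights))
})

test_that("softmax outputs are probabilities for any input", {
  cells <- toy_cells(n_per_class = 3L, seed0 = 40L)
  for (arch in c("fli_lenet", "fli_resnet")) {
    cfg <- model_config(arch, n_classes = 2L, input_shape = c(21L, 21L, 64L))
    m <- build_model(cfg)
    m$trained <- TRUE  # silence the untrained warning; forward pass only
    m$classes <- c("glycolysis", "oxphos")
    p <- predict_cnn(m, cells)
    pr <- as.matrix(p[, c("p_glycolysis", "p_oxphos")])
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-5)
  }
})

test_that("both architectures overfit a separable toy set to perfect accuracy", {
  cells <- toy_cells(n_per_class = 20L, seed0 = 60L)  # 40 cells, 2 classes
  ds <- build_dataset(cells, split = c(0.8, 0.2, 0), folds = 2L, seed = 2L)
  for (arch in c("fli_lenet", "fli_resnet")) {
    cfg <- model_config(arch, n_classes = 2L, input_shape = c(21L, 21L, 64L),
                        epochs = 40L, seed = 4L)
    m <- train_cnn(build_model(cfg), ds, use_best = FALSE)
    expect_equal(max(m$trace$train_accuracy), 1,
                 info = sprintf("architecture %s", arch))
    # predicting the training set reproduces its labels
    tr_cells <- ds$cells[ds$info$split == "train"]
    p <- predict_cnn(m, tr_cells)
    expect_gte(mean(p$predicted == p$truth), 0.95)
  }
})

test_that("training traces and final weights are reproducible under a fixed seed", {
  cells <- toy_cells(n_per_class = 8L, seed0 = 80L)
  ds <- build_dataset(cells, folds = 2L, seed = 3L)
  cfg <- model_config("fli_lenet", n_classes = 2L,
                      input_shape = c(21L, 21L, 64L), epochs = 3L, seed = 5L)
  m1 <- train_cnn(build_model(cfg), ds)
  m2 <- train_cnn(build_model(cfg), ds)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$weights, m2$weights)
})

test_that("shape mismatches are rejected with the expected geometry named", {
  cells64 <- toy_cells(n_per_class = 2L, seed0 = 95L)
  cfg <- model_config("fli_lenet", n_classes = 2L,
                      input_shape = c(21L, 21L, 128L))
  m <- build_model(cfg)
  m$trained <- TRUE
  expect_error(predict_cnn(m, cells64), "21x21x128")
})

test_that("penultimate activations have the configured width and are deterministic", {
  cells <- toy_cells(n_per_class = 3L, seed0 = 100L)
  for (arch in c("fli_lenet", "fli_resnet")) {
    cfg <- model_config(arch, n_classes = 2L, input_shape = c(21L, 21L, 64L))
    m <- build_model(cfg)
    A <- extract_activations(m, cells)
    expect_equal(dim(A), c(6L, 64L))
    # identical cells give identical rows
    A2 <- extract_activations(m, cells[c(1, 1)])
    expect_identical(A2[1, ], A2[2, ])
    # features feed tsne_embed without shape adaptation
    expect_silent(Y <- tsne_embed(A, seed = 1L, n_iter = 50L))
    expect_equal(dim(Y), c(6L, 2L))
  }
  expect_error(extract_activations(build_model(model_config()), cells,
                                   layer = "conv1"), "unknown layer")
})

test_that("cross-validation covers every cell exactly once with consistent summaries", {
  cells <- toy_cells(n_per_class = 15L, seed0 = 150L)  # 30 cells
  cfg <- model_config("fli_lenet", n_classes = 2L,
                      input_shape = c(21L, 21L, 64L), epochs = 2L, seed = 6L)
  cv <- cross_validate(cells, cfg, folds = 5L, seed = 7L)
  expect_length(cv$fold_metrics, 5L)
  expect_setequal(cv$predictions$cell_id,
                  vapply(cells, `[[`, 1L, "cell_id"))
  expect_equal(nrow(cv$predictions), 30L)
  # mean accuracy across folds equals the hand average of per-fold accuracies
  accs <- vapply(cv$fold_metrics, `[[`, numeric(1), "accuracy")
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], mean(accs))
})
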