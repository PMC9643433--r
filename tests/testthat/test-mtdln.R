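test_that("the joint loss is the convex combination of task losses", {
  expect_equal(multitask_loss(c(3.2, 1.1, 0.4), c(1, 0, 0)), 3.2)
  expect_equal(multitask_loss(c(1, 1, 1), c(0.4, 0.3, 0.3)), 1)
  expect_equal(multitask_loss(c(2, 4, 6), c(0.4, 0.3, 0.3)),
               0.4 * 2 + 0.3 * 4 + 0.3 * 6)
  expect_error(multitask_loss(c(1, 1, 1), c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(multitask_loss(c(1, 1, 1), c(1.2, -0.1, -0.1)), "nonnegative")
  expect_error(mtdln_config(5, alphas = c(0.6, 0.3, 0.3)), "sum to 1")
})

test_that("every split architecture has three heads of dims (7, N, 2)", {
  for (s in 0:7) {
    cfg <- mtdln_config(n_identities = 5, split_index = s,
                        image_size = c(16, 16))
    model <- build_mtdln(cfg, seed = 1)
    dims <- vapply(model$branches, function(b) {
      tail(b$layers, 1)[[1]]$out_shape
    }, integer(1))
    expect_equal(unname(dims), c(7L, 5L, 2L))
    if (s == 0) expect_null(model$trunk)
  }
  expect_error(mtdln_config(5, split_index = 8), "0..7")
})

test_that("trunk grows and branch-exclusive part shrinks with the split", {
  counts <- t(vapply(0:7, function(s) {
    cfg <- mtdln_config(n_identities = 5, split_index = s,
                        image_size = c(16, 16))
    mtdln_param_counts(build_mtdln(cfg, seed = 1))
  }, c(trunk = 0, branches = 0)))
  expect_true(all(diff(counts[, "trunk"]) > 0))
  expect_true(all(diff(counts[, "branches"]) < 0))
})

test_that("feature extraction has the configured dimension and softmax heads", {
  set <- tiny_set(4)
  cfg <- mtdln_config(n_identities = 4, image_size = c(16, 16), fc_width = 24)
  model <- build_mtdln(cfg, seed = 2)
  f <- extract_features(model, set$images)
  expect_equal(ncol(f$z), 24 + 7 + 2)
  expect_equal(unname(f$dims), c(24L, 7L, 2L))
  expect_equal(rowSums(feature_block(f, "expression")), rep(1, 28))
  expect_equal(rowSums(feature_block(f, "gender")), rep(1, 28))
  # eval-mode extraction is deterministic
  f2 <- extract_features(model, set$images)
  expect_identical(f$z, f2$z)
  wrong <- array(0L, c(20, 20, 2))
  expect_error(extract_features(model, wrong), "does not match")
})

test_that("the full-scale configuration yields the 521-dimensional code", {
  cfg <- mtdln_config(n_identities = 136, scale = "full",
                      image_size = c(64, 64))
  expect_equal(cfg$fc_width, 512L)
  expect_equal(cfg$fc_width + sum(cfg$head_dims[c("expression", "gender")]),
               521L)
})

test_that("training logs per-epoch validation accuracy and finds separable gender", {
  set <- generate_stimulus_set(12, 7, c(16, 16), seed = 1)
  set <- split_dataset(set, c(56, 0, 28), seed = 2, by_identity = TRUE)
  train <- subset_stimuli(set, "train")
  val <- subset_stimuli(set, "val_predict")
  cfg <- mtdln_config(n_identities = 8, split_index = 4,
                      image_size = c(16, 16), epochs = 15,
                      learning_rate = 0.02, batch_size = 16,
                      openset_pairs = c(60, 60), openset_folds = 5)
  fit <- train_mtdln(build_mtdln(cfg, seed = 3), train, val, seed = 4)
  expect_equal(nrow(fit$history$table), 15)
  expect_equal(fit$history$peak[["gender"]], 1)
  expect_equal(fit$history$peak[["expression"]],
               max(fit$history$table$expression))
  # training loss went down
  expect_lt(tail(fit$history$table$loss, 1), fit$history$table$loss[1])
  expect_error(train_mtdln(build_mtdln(cfg, seed = 3),
                           subset_stimuli(set, "val_fit"), NULL),
               "non-empty")
})

test_that("category accuracy scores argmax predictions against labels", {
  set <- tiny_set(3)
  cfg <- mtdln_config(n_identities = 3, image_size = c(16, 16))
  model <- build_mtdln(cfg, seed = 5)
  acc <- evaluate_category_accuracy(model, set, "gender")
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_error(evaluate_category_accuracy(model, set, "identity"),
               "expression")
})

test_that("open-set verification calibrates on oracle and null features", {
  ids <- rep(1:20, each = 4)
  # oracle: identical features within identity, far apart across
  oracle <- matrix(0, 80, 5)
  oracle[, 1] <- ids * 10
  expect_equal(openset_verification(oracle, ids, n_same = 300, n_diff = 300,
                                    folds = 10, seed = 1), 1)
  # identity-uninformative features: accuracy near 0.5
  set.seed(2)
  null_feats <- matrix(rnorm(80 * 5), 80, 5)
  acc <- openset_verification(null_feats, ids, n_same = 600, n_diff = 600,
                              folds = 10, seed = 3)
  expect_lt(abs(acc - 0.5), 0.07)
  expect_error(openset_verification(oracle, rep(1, 80)), "distinct")
})

test_that("checkpoints round-trip through the serialised format", {
  cfg <- mtdln_config(n_identities = 3, image_size = c(16, 16))
  model <- build_mtdln(cfg, seed = 6)
  path <- file.path(withr::local_tempdir(), "mtdln")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$branches$identity$layers, model$branches$identity$layers)
  expect_true(file.exists(paste0(path, ".json")))
})
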