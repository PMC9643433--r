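make_responses <- function(n_id = 4, voxels = 5, noise_sd = 0.5, seed = 1,
                           n_runs = 5) {
  set <- tiny_set(n_id, seed = seed)
  feats <- tiny_features(set, seed = seed + 1)
  spec <- encoding_spec(feats$dims, voxels_per_roi = voxels,
                        noise_sd = noise_sd, seed = seed + 2)
  list(set = set, feats = feats, spec = spec,
       resp = simulate_roi_responses(feats, spec, n_runs = n_runs,
                                     seed = seed + 3))
}

test_that("design assembly follows the ROI-group strategies", {
  fx <- make_responses(voxels = 5)
  prop <- roi_group_strategy("proposed")
  s1 <- roi_group_strategy("strategy1")
  s2 <- roi_group_strategy("strategy2")
  S_exp <- assemble_design(fx$resp, prop, "expression", runs = 1:3)
  expect_equal(ncol(S_exp), 4 * 5)       # V1, OFA, amygdala, pSTS
  expect_true(all(grepl("^(V1|OFA|amygdala|pSTS)_", colnames(fx$resp$responses)[
    unlist(fx$resp$roi_cols[prop$groups$expression])])))
  expect_equal(ncol(assemble_design(fx$resp, s1, "identity")), 5)
  expect_equal(ncol(assemble_design(fx$resp, s2, "gender")), 6 * 5)
  # stack vs average row bookkeeping (28 stimuli)
  expect_equal(nrow(assemble_design(fx$resp, prop, "expression", runs = 1:3,
                                    mode = "stack")), 84)
  expect_equal(nrow(assemble_design(fx$resp, prop, "expression", runs = 4:5,
                                    mode = "average")), 28)
  # constraint bookkeeping of the ablation strategies
  expect_equal(roi_group_strategy("strategy3")$constraints, "identity")
  expect_setequal(roi_group_strategy("strategy5")$constraints,
                  c("identity", "expression"))
  # missing ROI
  small <- fx$resp; small$roi_cols <- small$roi_cols["V1"]
  expect_error(assemble_design(small, prop, "expression"), "absent")
})

test_that("ordinary least squares solves the normal equations exactly", {
  # identity design collapses to W = T
  T0 <- matrix(rnorm(12), 4, 3)
  expect_equal(fit_linear_map(diag(4), T0)$W, T0, ignore_attr = TRUE)
  # construct-and-recover at full column rank
  set.seed(1)
  S <- matrix(rnorm(30 * 8), 30, 8)
  W_true <- matrix(rnorm(8 * 5), 8, 5)
  fit <- fit_linear_map(S, S %*% W_true)
  expect_false(fit$rank_deficient)
  expect_lt(max(abs(fit$W - W_true)), 1e-8)
  expect_error(fit_linear_map(S, matrix(0, 29, 5)), "rows")
})

test_that("singular designs fall back to the minimum-norm solution", {
  set.seed(2)
  S <- matrix(rnorm(6 * 10), 6, 10)         # more voxels than samples
  T0 <- matrix(rnorm(6 * 3), 6, 3)
  expect_warning(fit <- fit_linear_map(S, T0), "minimum-norm")
  expect_true(fit$rank_deficient)
  # residual matches an independent QR least-squares oracle
  oracle <- lm.fit(S, T0)
  expect_equal(norm(S %*% fit$W - T0, "F"),
               norm(as.matrix(oracle$residuals), "F"), tolerance = 1e-8)
  # minimum norm: any other exact solution has larger Frobenius norm
  expect_lte(norm(fit$W, "F"), norm(fit$W + rnorm(1) * MASS::Null(t(S))[, 1],
                                    "F") + 1e-10)
})

test_that("OLS and pseudoinverse coincide on well-posed problems", {
  set.seed(3)
  S <- matrix(rnorm(40 * 6), 40, 6)
  T0 <- matrix(rnorm(40 * 2), 40, 2)
  chol_fit <- fit_linear_map(S, T0)$W
  sv <- svd(S)
  pinv_fit <- sv$v %*% ((1 / sv$d) * crossprod(sv$u, T0))
  expect_equal(chol_fit, pinv_fit, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("prediction is the plain intercept-free matrix product", {
  set.seed(4)
  S <- matrix(rnorm(20 * 5), 20, 5)
  W_true <- matrix(rnorm(5 * 3), 5, 3)
  map <- fit_linear_map(S, S %*% W_true)
  expect_equal(predict_features(matrix(0, 2, 5), map),
               matrix(0, 2, 3), ignore_attr = TRUE)
  # interpolation: training rows reproduce training targets exactly
  expect_equal(predict_features(S, map), S %*% W_true, tolerance = 1e-8)
  map0 <- map; map0$W[] <- 0
  expect_true(all(predict_features(S, map0) == 0))
  expect_error(predict_features(matrix(0, 2, 4), map), "columns")
})

test_that("multi-dimensional feature assembly clips, zeroes and checks dims", {
  n <- 3
  z <- assemble_multidim_features(matrix(0.5, n, 7), matrix(1.5, n, 12),
                                  matrix(0.2, n, 2))
  expect_equal(ncol(z$z), 12 + 7 + 2)
  expect_warning(
    c1 <- assemble_multidim_features(matrix(1.3, n, 7), matrix(0, n, 12),
                                     matrix(0.5, n, 2)), "clipping")
  expect_equal(max(feature_block(c1, "expression")), 1)
  zz <- assemble_multidim_features(matrix(0, n, 7), matrix(0, n, 12),
                                   matrix(0, n, 2))
  expect_true(all(zz$z == 0))
  con <- assemble_multidim_features(matrix(0.5, n, 7), matrix(2, n, 4),
                                    matrix(0.5, n, 2),
                                    constraints = "identity")
  expect_true(all(feature_block(con, "expression") == 0))
  expect_true(all(feature_block(con, "gender") == 0))
  expect_false(all(feature_block(con, "identity") == 0))
  expect_error(assemble_multidim_features(matrix(0, n, 6), matrix(0, n, 4),
                                          matrix(0, n, 2)), "7 columns")
})

test_that("noiseless responses round-trip through fit and predict", {
  fx <- make_responses(voxels = 4, noise_sd = 0)
  strat <- roi_group_strategy("proposed")
  maps <- suppressWarnings(
    fit_attribute_maps(fx$resp, fx$feats, strat, runs = 1:3))
  pred <- suppressWarnings(
    predict_attribute_features(fx$resp, maps, strat, runs = 4:5,
                               condition = FALSE))
  expect_lt(max(abs(pred$z - fx$feats$z)), 1e-8)
})

test_that("prediction fidelity decays with noise and recovers selectivity", {
  cors <- vapply(c(0, 0.5, 2), function(ns) {
    mean(vapply(1:2, function(sd) {
      fx <- make_responses(n_id = 6, voxels = 8, noise_sd = ns, seed = sd * 10)
      strat <- roi_group_strategy("proposed")
      maps <- suppressWarnings(
        fit_attribute_maps(fx$resp, fx$feats, strat, runs = 1:3))
      pred <- suppressWarnings(
        predict_attribute_features(fx$resp, maps, strat, runs = 4:5,
                                   condition = FALSE))
      cor(as.vector(pred$z), as.vector(fx$feats$z))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
  # proposed expression group at least as informative as V1 alone
  fx <- make_responses(n_id = 6, voxels = 8, noise_sd = 1.5, seed = 77)
  cor_of <- function(strat_name) {
    strat <- roi_group_strategy(strat_name)
    maps <- suppressWarnings(
      fit_attribute_maps(fx$resp, fx$feats, strat, runs = 1:3))
    pred <- suppressWarnings(
      predict_attribute_features(fx$resp, maps, strat, runs = 4:5,
                                 condition = FALSE))
    cor(as.vector(feature_block(pred, "expression")),
        as.vector(feature_block(fx$feats, "expression")))
  }
  expect_gte(cor_of("proposed"), cor_of("strategy1") - 0.02)
})

test_that("linear maps round-trip through the matrix + JSON format", {
  set.seed(5)
  map <- fit_linear_map(matrix(rnorm(40), 10, 4), matrix(rnorm(30), 10, 3),
                        meta = list(attribute = "expression"))
  path <- file.path(withr::local_tempdir(), "map")
  write_linear_map(map, path)
  back <- read_linear_map(path)
  expect_equal(back$W, map$W, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$meta$attribute, "expression")
})
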