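test_that("eigen-spaces recover low-rank structure", {
  set.seed(1)
  # rank-5 data in 20 voxels
  S <- matrix(rnorm(60 * 5), 60, 5) %*% matrix(rnorm(5 * 20), 5, 20)
  es <- fit_eigenspace(S, k = 5)
  back <- eigen_backproject(es, eigen_project(es, S))
  expect_lt(max(abs(back - S)), 1e-8)
  expect_equal(crossprod(es$basis), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # k = 1 on data with a dominant axis aligns with that axis
  axis <- rnorm(20); axis <- axis / sqrt(sum(axis^2))
  S1 <- outer(rnorm(100, sd = 5), axis) + matrix(rnorm(2000, sd = 0.1), 100)
  e1 <- fit_eigenspace(S1, k = 1)
  expect_gt(abs(sum(e1$basis[, 1] * axis)), 0.99)
  # reconstruction error non-increasing in k
  errs <- vapply(1:4, function(k) {
    es <- fit_eigenspace(S1, k = k)
    norm(eigen_backproject(es, eigen_project(es, S1)) - S1, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(fit_eigenspace(S, k = 21), "k")
})

test_that("the cross-subject transform recovers known relations", {
  set.seed(2)
  A <- matrix(rnorm(80 * 6), 80, 6)
  expect_lt(max(abs(fit_cross_subject_map(A, A)$M - diag(6))), 1e-8)
  R <- matrix(rnorm(36), 6, 6)
  B <- A %*% R
  m <- fit_cross_subject_map(A, B)
  expect_lt(max(abs(m$M - solve(R))), 1e-6)
  expect_error(fit_cross_subject_map(A, B[1:40, ]), "aligned")
  # fewer shared stimuli than coordinates: warning + least-squares oracle
  A4 <- A[1:4, ]; B4 <- B[1:4, ]
  expect_warning(m4 <- fit_cross_subject_map(A4, B4), "minimum-norm")
  oracle <- lm.fit(B4, A4)
  expect_equal(norm(B4 %*% m4$M - A4, "F"),
               norm(as.matrix(oracle$residuals), "F"), tolerance = 1e-8)
  # procrustes returns an orthogonal matrix
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  mp <- fit_cross_subject_map(A, A %*% Q, method = "procrustes")
  expect_equal(crossprod(mp$M), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(mp$M - t(Q))), 1e-8)
})

test_that("with B identical to A the cross-subject route equals intra", {
  set <- tiny_set(6, 16, seed = 3)
  feats <- tiny_features(set, seed = 4)
  spec <- encoding_spec(feats$dims, voxels_per_roi = 10, noise_sd = 0.5,
                        seed = 5)
  resp <- simulate_roi_responses(feats, spec, n_runs = 5, seed = 6)
  avg <- function(runs) apply(resp$responses[, , runs], c(1, 2), mean)
  S_train <- avg(1:3); S_test <- avg(4:5)
  k <- 12
  es <- fit_eigenspace(S_train, k = k)
  coords <- eigen_project(es, S_train)
  maps <- lapply(c(expression = "expression", identity = "identity",
                   gender = "gender"), function(a)
    fit_linear_map(coords, feature_block(feats, a)))
  # intra route: project test responses in A's own eigen-space
  intra <- attribute_features(
    predict_features(eigen_project(es, S_test), maps$identity),
    predict_features(eigen_project(es, S_test), maps$expression),
    predict_features(eigen_project(es, S_test), maps$gender))
  inter <- cross_subject_reconstruct(S_test, es,
                                     fit_cross_subject_map(coords, coords),
                                     es, maps)
  expect_equal(inter$features$z, intra$z, tolerance = 1e-8)
})

test_that("shared-encoding subjects transfer and unrelated subjects do not", {
  suppressWarnings({
    shared <- run_inter_subject(
      experiment_config("inter_seen", seed = 21, n_identities = 16,
                        n_val_identities = 10, image_size = 16,
                        n_repeats = 10, generator = "none",
                        subject_b = "shared"))
    null <- run_inter_subject(
      experiment_config("inter_seen", seed = 21, n_identities = 16,
                        n_val_identities = 10, image_size = 16,
                        n_repeats = 10, generator = "none",
                        subject_b = "independent"))
  })
  st <- shared$tables$accuracy
  expect_gt(st$mean[st$condition == "feature_identity"], 80)
  expect_gt(st$mean[st$condition == "feature_expression"], 80)
  nt <- null$tables$accuracy
  expect_lt(abs(nt$mean[nt$condition == "feature_expression"] - 50), 12)
  expect_lt(abs(nt$mean[nt$condition == "feature_identity"] - 50), 12)
})

test_that("cross-subject recovery degrades with voxel noise", {
  acc_at <- function(ns) {
    mean(vapply(1:2, function(s) {
      suppressWarnings(man <- run_inter_subject(
        experiment_config("inter_seen", seed = 30 + s, n_identities = 12,
                          n_val_identities = 8, image_size = 16,
                          n_repeats = 5, generator = "none",
                          subject_b = "shared", noise_sd = ns)))
      tab <- man$tables$accuracy
      mean(tab$mean[tab$condition %in% c("feature_expression",
                                         "feature_identity")])
    }, numeric(1)))
  }
  accs <- vapply(c(0.5, 4, 16), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 1e-8))
})

test_that("alignment objects serialise with metadata", {
  set.seed(7)
  es <- fit_eigenspace(matrix(rnorm(200), 20, 10), k = 3)
  dir <- withr::local_tempdir()
  write_alignment(es, file.path(dir, "es"))
  expect_true(file.exists(file.path(dir, "es_basis.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "es.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$k, 3)
})
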