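test_that("MSE matches hand computations", {
  x <- matrix(c(0, 0, 0, 0), 2, 2)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x, x + 1), 1)
  expect_equal(mse(x, matrix(2, 2, 2)), 4)
  expect_error(mse(x, matrix(0, 2, 3)), "shapes")
})

test_that("PSNR follows its closed form and handles identical images", {
  x <- matrix(0, 4, 4)
  expect_equal(psnr(x, matrix(255, 4, 4)), 0)              # MSE = 255^2
  y <- x; y[1, 1] <- 4                                     # MSE = 1
  expect_equal(psnr(x, y), 10 * log10(65025), tolerance = 1e-12)
  expect_warning(p <- psnr(x, x), "infinite")
  expect_identical(p, Inf)
})

test_that("PSNR and MSE are mutually consistent", {
  set.seed(1)
  for (i in 1:5) {
    a <- matrix(sample(0:255, 64, TRUE), 8, 8)
    b <- matrix(sample(0:255, 64, TRUE), 8, 8)
    expect_equal(psnr(a, b), 10 * log10(255^2) - 10 * log10(mse(a, b)),
                 tolerance = 1e-10)
  }
})

test_that("SSIM matches the printed global-statistics formula", {
  set.seed(2)
  x <- matrix(sample(0:255, 100, TRUE), 10, 10)
  y <- matrix(sample(0:255, 100, TRUE), 10, 10)
  # independent evaluation of the formula from raw moments
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ref <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(ssim(x, y), ref, tolerance = 1e-12)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_equal(ssim(matrix(7, 5, 5), matrix(7, 5, 5)), 1)
  # bounded on arbitrary pairs
  expect_true(abs(ssim(x, 255 - x)) <= 1)
  # windowed variant agrees with global SSIM when the window is the image
  expect_equal(ssim_windowed(x, y, window = 10), ssim(x, y))
})

test_that("one-sample tests and BH adjustment behave canonically", {
  expect_equal(test_against_null(rep(0.5, 10), 0.5)[c("t", "p_raw")],
               list(t = 0, p_raw = 1))
  set.seed(3)
  shifted <- 0.5 + 0.2 + rnorm(40, sd = 0.01)
  expect_lt(test_against_null(shifted, 0.5)$p_raw, 0.001)
  expect_error(test_against_null(1, 0.5), "at least 2")
  fake <- lapply(c(0.001, 0.04, 0.2, 0.9), function(p) list(p_raw = p))
  adj <- adjust_fdr(fake)
  p_adj <- vapply(adj, `[[`, numeric(1), "p_fdr")
  p_raw <- vapply(adj, `[[`, numeric(1), "p_raw")
  expect_true(all(p_adj >= p_raw))
  expect_true(all(diff(p_adj[order(p_raw)]) >= 0))
  expect_equal(p_adj, p.adjust(p_raw, "BH"))
})

test_that("SSIM accuracy is maximal for perfect reconstructions", {
  set <- tiny_set(4, 32, seed = 4)
  res <- ssim_accuracy(set$images, set$images, n_repeats = 8, seed = 5)
  expect_equal(res$accuracies, rep(1, 8))
  expect_equal(res$mean, 1)
  expect_equal(res$n_repeats, 8)
  one <- set$images[, , 1, drop = FALSE]
  expect_error(ssim_accuracy(one, one, distractor_pool = one), "at least 2")
})

test_that("SSIM accuracy is at chance for unrelated reconstructions", {
  truths <- generate_stimulus_set(20, 7, c(32, 32), seed = 6)$images
  # independent reconstructions: fresh glyph parameters, and the stimulus
  # order permuted so no label structure stays aligned with the truths
  recons <- generate_stimulus_set(20, 7, c(32, 32), seed = 7)$images
  recons <- recons[, , withr::with_seed(8, sample(140))]
  res <- ssim_accuracy(recons, truths, n_repeats = 40, seed = 8)
  # per-image chance ranks are uniform; 3x the image-sampling SE at n=140
  expect_lt(abs(res$mean - 0.5), 3 * 0.025 + 0.01)
  expect_length(res$accuracies, 40)
})

test_that("feature-space reconstruction accuracy calibrates at its extremes", {
  set.seed(9)
  truth <- matrix(rnorm(60 * 5), 60, 5)
  perfect <- roi_reconstruction_accuracy(truth, truth, n_repeats = 6,
                                         seed = 10)
  expect_equal(perfect$mean, 100)
  indep <- roi_reconstruction_accuracy(matrix(rnorm(60 * 5), 60, 5), truth,
                                       n_repeats = 40, seed = 11)
  expect_lt(abs(indep$mean - 50), 3 * 100 / sqrt(12 * 60) + 2)
  expect_error(roi_reconstruction_accuracy(truth[1, , drop = FALSE],
                                           truth[1, , drop = FALSE]),
               "at least 2")
  # duplicate-feature images are excluded as foils, not counted as ties
  dup_truth <- truth[rep(1:2, each = 2), ]
  res <- roi_reconstruction_accuracy(dup_truth + 1e-6, dup_truth,
                                     n_repeats = 4, seed = 12)
  expect_equal(res$mean, 100)
})

test_that("evaluation reports serialise per-image metrics and summaries", {
  set <- tiny_set(2, 32, seed = 13)
  m <- image_metrics(set$images, set$images[, , c(2:14, 1)])
  expect_equal(nrow(m), 14)
  expect_true(all(m$mse >= 0))
  res <- list(ssim = ssim_accuracy(set$images, set$images, n_repeats = 3,
                                   seed = 1))
  dir <- withr::local_tempdir()
  write_evaluation_report(m, res, dir)
  expect_true(file.exists(file.path(dir, "per_image_metrics.tsv")))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$ssim$mean, 1)
})
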