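test_that("generation yields the full identity x expression factorial", {
  set <- generate_stimulus_set(136, 7, c(16, 16), seed = 1)
  expect_equal(dim(set$images), c(16, 16, 952))
  expect_equal(nrow(set$labels), 952)
  expect_equal(length(unique(set$labels$identity_id)), 136)
  expect_setequal(unique(set$labels$expression_id), 0:6)
  expect_true(all(set$labels$gender_id %in% 0:1))
  expect_true(all(set$images >= 0 & set$images <= 255))
  # identity x expression pairs unique
  expect_false(any(duplicated(set$labels[c("identity_id", "expression_id")])))
})

test_that("minimal one-identity one-expression case", {
  set <- generate_stimulus_set(1, 1, c(16, 16), seed = 5)
  expect_equal(dim(set$images)[3], 1)
  expect_equal(set$labels$identity_id, 0L)
  expect_equal(set$labels$expression_id, 0L)
  expect_true(set$labels$gender_id %in% 0:1)
})

test_that("all factorial cells render distinct images at 32 px", {
  for (seed in c(1, 9)) {
    set <- generate_stimulus_set(10, 7, c(32, 32), seed = seed)
    M <- matrix(set$images, ncol = dim(set$images)[3])
    expect_false(any(duplicated(t(M))))
  }
})

test_that("generation is a pure function of arguments and seed", {
  a <- generate_stimulus_set(4, 7, c(24, 20), seed = 42)
  b <- generate_stimulus_set(4, 7, c(24, 20), seed = 42)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  c <- generate_stimulus_set(4, 7, c(24, 20), seed = 43)
  expect_false(identical(a$images, c$images))
})

test_that("stimulus attributes shape distinct image regions", {
  set <- generate_stimulus_set(2, 7, c(32, 32), seed = 7,
                               gender = c(0L, 1L))
  l <- set$labels
  # same identity, different expression -> different images
  i1 <- which(l$identity_id == 0 & l$expression_id == 0)
  i2 <- which(l$identity_id == 0 & l$expression_id == 6)
  expect_false(identical(set$images[, , i1], set$images[, , i2]))
  # gender flips the dark hair band in the top rows
  m0 <- which(l$identity_id == 0 & l$expression_id == 4)
  m1 <- which(l$identity_id == 1 & l$expression_id == 4)
  top_dark <- function(img) mean(img[1:8, ] < 30)
  expect_gt(top_dark(set$images[, , m1]), top_dark(set$images[, , m0]))
})

test_that("invalid generation arguments fail", {
  expect_error(generate_stimulus_set(0, 7, c(16, 16)), "positive")
  expect_error(generate_stimulus_set(3, 7, c(8, 8)), ">= 16")
  expect_error(generate_stimulus_set(3, 9, c(16, 16)), "1..7")
  expect_error(generate_stimulus_set(3, 7, c(16, 16), gender = c(1L, 0L)),
               "length")
})

test_that("splits have exact counts and partition the set", {
  set <- generate_stimulus_set(127, 7, c(16, 16), seed = 2)
  set <- split_dataset(set, c(749, 70, 70), seed = 3)
  tab <- table(set$labels$split)
  expect_equal(unname(tab[c("train", "val_fit", "val_predict")]),
               c(749L, 70L, 70L), ignore_attr = TRUE)
  # partition: every stimulus in exactly one split
  expect_false(anyNA(set$labels$split))
  expect_equal(sum(tab), 889)
})

test_that("degenerate and invalid splits are handled", {
  set <- generate_stimulus_set(4, 7, c(16, 16), seed = 1)
  expect_warning(s <- split_dataset(set, c(28, 0, 0)), "empty validation")
  expect_true(all(s$labels$split == "train"))
  expect_error(split_dataset(set, c(20, 4, 5)), "sum")
})

test_that("identity-level splitting keeps validation identities open-set", {
  set <- generate_stimulus_set(10, 7, c(16, 16), seed = 4)
  set <- split_dataset(set, c(42, 14, 14), seed = 5, by_identity = TRUE)
  ids <- split(set$labels$identity_id, set$labels$split)
  expect_length(intersect(ids$train, ids$val_predict), 0)
  expect_length(intersect(ids$train, ids$val_fit), 0)
  expect_error(split_dataset(set, c(41, 15, 14), seed = 5,
                             by_identity = TRUE), "divisible")
})

test_that("stimulus sets round-trip through PNG plus label table", {
  set <- generate_stimulus_set(3, 7, c(16, 16), seed = 6)
  set <- split_dataset(set, c(14, 0, 7), seed = 1, by_identity = TRUE)
  dir <- withr::local_tempdir()
  write_stimulus_set(set, dir)
  back <- read_stimulus_set(dir)
  expect_identical(back$images, set$images)
  expect_equal(back$labels$identity_id, set$labels$identity_id)
  expect_equal(back$labels$split, set$labels$split)
})
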