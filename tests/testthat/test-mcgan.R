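dims3 <- c(identity = 8L, expression = 7L, gender = 2L)

test_that("configuration validates geometry and weights", {
  expect_error(mcgan_config(dims3, image_size = 20), "power of two")
  expect_error(mcgan_config(dims3, image_size = 8), "power of two")
  expect_error(mcgan_config(dims3, lambda_D = -1), ">= 0")
  expect_error(mcgan_config(c(identity = 8)), "named")
  cfg <- mcgan_config(dims3, image_size = 32)
  expect_equal(cfg$z_dim, 17L)
  expect_equal(cfg$n_stages, 3L)
})

test_that("the generator maps z through an FC layer to the configured size", {
  cfg <- mcgan_config(c(identity = 512L, expression = 7L, gender = 2L),
                      image_size = 64, g_channels = 8)
  G <- build_generator(cfg, seed = 1)
  expect_equal(G$input_shape, 521L)
  expect_equal(G$layers[[1]]$type, "dense")   # added FC before the deconvs
  z <- matrix(rnorm(2 * 521), 2, 521)
  out <- nn_forward(G, z)$out
  expect_equal(dim(out), c(64L, 64L, 1L, 2L))
  expect_true(all(out >= -1 & out <= 1))
  # fixed weights + fixed z -> identical output
  expect_identical(out, nn_forward(G, z)$out)
})

test_that("the discriminator has four conv stages and mode-dependent heads", {
  cfg <- mcgan_config(dims3, image_size = 16)
  D <- build_discriminator(cfg, seed = 2)
  expect_equal(sum(vapply(D$trunk$layers, function(l) l$type == "conv",
                          logical(1))), 4L)
  expect_setequal(names(D$heads), c("real", "expression", "identity",
                                    "gender"))
  cfg_c <- mcgan_config(dims3, image_size = 16, mode = "cgan")
  expect_equal(names(build_discriminator(cfg_c, seed = 2)$heads), "real")
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  fw <- discriminator_forward(D, x)
  expect_equal(ncol(fw$logits$identity), 8L)
  expect_true(all(fw$real > 0 & fw$real < 1))
  expect_error(discriminator_forward(D, array(0, c(8, 8, 1, 2))),
               "does not match")
})

test_that("the discriminator objective matches a hand evaluation", {
  # scalar toy: one image each, single-unit heads, one-hot targets
  d_real <- 0.8; d_fake <- 0.3; sm <- 0.9
  heads_real <- list(identity = 0.6, expression = 0.7, gender = 0.2)
  heads_fake <- list(identity = 0.4, expression = 0.5, gender = 0.9)
  targets <- list(identity = 1, expression = 1, gender = 0)
  bce <- function(t, p) -(t * log(p) + (1 - t) * log(1 - p))
  by_hand <- (sm * log(d_real) + (1 - sm) * log(1 - d_real)) +
    log(1 - d_fake) -
    20 * (bce(1, 0.6) + bce(1, 0.4) + bce(1, 0.7) + bce(1, 0.5) +
            bce(0, 0.2) + bce(0, 0.9))
  expect_equal(discriminator_loss(d_real, d_fake, heads_real, heads_fake,
                                  targets, lambda_D = 20, smooth = sm),
               by_hand, tolerance = 1e-12)
  # lambda_D = 0 reduces to the plain adversarial objective
  expect_equal(discriminator_loss(d_real, d_fake, lambda_D = 0, smooth = 1),
               log(d_real) + log(1 - d_fake), tolerance = 1e-12)
  # heads equal to binary targets zero all six BCE terms
  exact <- list(identity = 1, expression = 1, gender = 0)
  expect_equal(discriminator_loss(d_real, d_fake, exact, exact, targets,
                                  lambda_D = 20, smooth = sm),
               sm * log(d_real) + (1 - sm) * log(1 - d_real) +
                 log(1 - d_fake), tolerance = 1e-9)
  expect_error(discriminator_loss(d_real, d_fake, heads_real, heads_fake,
                                  list(identity = 2, expression = 1,
                                       gender = 0)), "\\[0, 1\\]")
})

test_that("label smoothing touches only the real-image adversarial term", {
  base <- discriminator_loss(0.7, 0.4, lambda_D = 0, smooth = 1)
  smoothed <- discriminator_loss(0.7, 0.4, lambda_D = 0, smooth = 0.9)
  # the fake term log(1 - d_fake) is identical in both
  expect_equal(base - log(0.7), smoothed -
                 (0.9 * log(0.7) + 0.1 * log(1 - 0.7)), tolerance = 1e-12)
})

test_that("the generator objective matches a hand evaluation", {
  g <- array(c(0, 100, 50, 200), c(2, 2, 1))
  x <- array(c(10, 90, 80, 180), c(2, 2, 1))
  d_fake <- 0.25
  by_hand <- log(1 - 0.25) + 20 * mean(c(10, 10, 30, 20))
  expect_equal(generator_loss(d_fake, g, x, lambda_G = 20), by_hand,
               tolerance = 1e-12)
  expect_equal(generator_loss(d_fake, g, x, lambda_G = 0), log(0.75),
               tolerance = 1e-12)
  expect_equal(generator_loss(d_fake, x, x, lambda_G = 20), log(0.75),
               tolerance = 1e-12)
  expect_error(generator_loss(d_fake, g, array(0, c(2, 3, 1))), "shape")
})

test_that("training is seeded and validates its inputs", {
  set <- tiny_set(4, 16, seed = 9)
  feats <- tiny_features(set, seed = 10)
  cfg <- mcgan_config(feats$dims, image_size = 16, epochs = 2,
                      g_channels = 8, d_channels = c(4L, 4L, 8L, 8L))
  m1 <- train_mcgan(set$images, feats, cfg, seed = 11)
  m2 <- train_mcgan(set$images, feats, cfg, seed = 11)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$generator$layers, m2$generator$layers)
  expect_equal(nrow(m1$log), 2)
  bad <- tiny_features(tiny_set(3, 16), seed = 1)
  expect_error(train_mcgan(set$images, bad, cfg), "one feature vector")
})

test_that("reconstruction rescales to 8-bit and is deterministic", {
  env <- get_toy_gan()
  rec <- reconstruct(env$model, env$feats)
  expect_true(all(rec >= 0 & rec <= 255))
  expect_equal(dim(rec), dim(env$set$images))
  expect_identical(rec, reconstruct(env$model, env$feats))
  expect_error(reconstruct(env$model, matrix(0, 2, 5)), "dimension")
})

test_that("the trained generator uses its conditioning blocks", {
  # flipping the expression block moves the mouth region more than
  # flipping the gender block does
  env <- get_toy_gan()
  z0 <- env$feats$z[1, , drop = FALSE]
  z_exp <- z0
  z_exp[, env$feats$blocks$expression] <-
    rev(z_exp[, env$feats$blocks$expression])
  z_gen <- z0
  z_gen[, env$feats$blocks$gender] <- rev(z_gen[, env$feats$blocks$gender])
  base <- reconstruct(env$model, z0)
  mouth_r <- 18:29; mouth_c <- 12:21   # mouth-arc box of the 32 px glyph
  d_exp <- mean(abs(reconstruct(env$model, z_exp)[mouth_r, mouth_c, 1] -
                      base[mouth_r, mouth_c, 1]))
  d_gen <- mean(abs(reconstruct(env$model, z_gen)[mouth_r, mouth_c, 1] -
                      base[mouth_r, mouth_c, 1]))
  expect_gt(d_exp, d_gen)
})
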