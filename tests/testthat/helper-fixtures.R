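# shared fixtures and numerical utilities for the suite

# central finite-difference gradient of f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# max abs error between analytic and numeric gradients of a network,
# checking the input and every parameter tensor
nn_gradcheck_err <- function(net, x, seed = 99) {
  set.seed(seed)
  fw <- nn_forward(net, x)
  dout <- fw$out
  dout[] <- rnorm(length(dout))
  loss_of <- function(out) sum(out * dout)
  bw <- nn_backward(net, fw$cache, dout)
  f_x <- function(v) { xx <- x; xx[] <- v; loss_of(nn_forward(net, xx)$out) }
  err <- max(abs(num_grad(f_x, as.vector(x)) - as.vector(bw$dx)))
  for (i in seq_along(net$layers)) {
    if (is.null(net$layers[[i]]$W)) next
    for (p in c("W", "b")) {
      f_p <- function(v) {
        n2 <- net; n2$layers[[i]][[p]][] <- v
        loss_of(nn_forward(n2, x)$out)
      }
      err <- max(err, max(abs(num_grad(f_p, as.vector(net$layers[[i]][[p]])) -
                                as.vector(bw$grads[[i]][[p]]))))
    }
  }
  err
}

# small labelled stimulus set shared across tests
tiny_set <- function(n_id = 6, size = 16, seed = 1) {
  generate_stimulus_set(n_id, 7L, c(size, size), seed = seed)
}

# features with per-image-unique identity embeddings are not needed for
# most tests; label features are the encoding ground truth
tiny_features <- function(set, d_id = 8, seed = 2) {
  label_features(set, d_id = d_id, seed = seed)
}

# one cached toy GAN (32x32) reused by the tests that need a trained model
toy_gan_env <- new.env(parent = emptyenv())
get_toy_gan <- function() {
  if (is.null(toy_gan_env$model)) {
    set <- tiny_set(8, 32, seed = 3)
    feats <- tiny_features(set, d_id = 8, seed = 4)
    cfg <- mcgan_config(feats$dims, image_size = 32L, epochs = 40L,
                        g_channels = 16L, d_channels = c(8L, 8L, 16L, 16L),
                        lr = 1e-3)
    toy_gan_env$model <- train_mcgan(set$images, feats, cfg, seed = 5)
    toy_gan_env$set <- set
    toy_gan_env$feats <- feats
  }
  toy_gan_env
}
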