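# Minimal convolutional network engine ---------------------------------------
#
# Small, explicit forward/backward implementations of the layers the two
# networks need: 2-D convolution (arbitrary stride/padding), its adjoint
# (transposed convolution), 2x2 max pooling, dense layers, the usual
# activations and dropout. Convolution uses a precompiled im2col gather
# index; its backward pass (and the transposed-convolution forward pass)
# uses the adjoint scatter as a sparse matrix product. Batches are arrays
# with dimensions (height, width, channels, batch); dense layers operate on
# (batch x features) matrices. Correctness is pinned down by
# finite-difference gradient checks in the test suite.
#
# This engine exists because the package targets plain CPU R; it is sized
# for the small images (16-64 px) and narrow layers used throughout.

# ---- layer constructors (shape-free specs, compiled by nn_sequential) ------

#' Layer constructors for [nn_sequential()]
#'
#' Shape-free layer specifications; [nn_sequential()] compiles them against
#' an input shape, initialising weights and convolution index structures.
#'
#' @param filters,units Output channels / units.
#' @param kernel,stride,pad Convolution geometry. `pad = "same"` keeps the
#'   spatial size (stride 1).
#' @param l2 L2 weight-decay rate applied to this dense layer's weights
#'   during optimisation (0 = none).
#' @param p Dropout probability.
#' @param alpha Negative slope of the leaky ReLU.
#' @param shape Target `(H, W, C)` for `layer_reshape`.
#' @return A layer specification list.
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
layer_conv <- function(filters, kernel = 3L, stride = 1L, pad = "same")
  list(type = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), pad = pad)

#' @rdname nn_layers
#' @export
layer_convt <- function(filters, kernel = 4L, stride = 2L, pad = 1L)
  list(type = "convt", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad))

#' @rdname nn_layers
#' @export
layer_maxpool <- function() list(type = "maxpool")

#' @rdname nn_layers
#' @export
layer_flatten <- function() list(type = "flatten")

#' @rdname nn_layers
#' @export
layer_reshape <- function(shape) list(type = "reshape", shape = as.integer(shape))

#' @rdname nn_layers
#' @export
layer_dense <- function(units, l2 = 0) list(type = "dense",
                                            units = as.integer(units), l2 = l2)

#' @rdname nn_layers
#' @export
layer_relu <- function() list(type = "relu")

#' @rdname nn_layers
#' @export
layer_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)

#' @rdname nn_layers
#' @export
layer_tanh <- function() list(type = "tanh")

#' @rdname nn_layers
#' @export
layer_sigmoid <- function() list(type = "sigmoid")

#' @rdname nn_layers
#' @export
layer_dropout <- function(p = 0.5) list(type = "dropout", p = p)

# ---- geometry --------------------------------------------------------------

# Gather/scatter geometry of a convolution over in_shape = c(H, W, C).
conv_geom <- function(in_shape, kernel, stride, pad) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  k <- kernel; s <- stride
  if (identical(pad, "same")) {
    if (s != 1L) stop_arg("pad = \"same\" requires stride 1")
    pad <- (k - 1L) %/% 2L
  }
  p <- as.integer(pad)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  if ((Hp - k) %% s != 0L || (Wp - k) %% s != 0L)
    stop_arg("incompatible convolution geometry")
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  P <- Ho * Wo
  ho <- rep(seq_len(Ho), times = Wo); wo <- rep(seq_len(Wo), each = Ho)
  base_p <- (ho - 1L) * s + ((wo - 1L) * s) * Hp          # 0-based (h) + w*Hp
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  off_k <- kh + (kw - 1L) * Hp + (cc - 1L) * Hp * Wp      # 1-based within pad
  idx <- outer(base_p, off_k, `+`)                        # P x K
  K <- k * k * C
  scat <- Matrix::sparseMatrix(i = seq_len(P * K), j = as.vector(idx), x = 1,
                               dims = c(P * K, Hp * Wp * C))
  list(H = H, W = W, C = C, k = k, s = s, p = p, Hp = Hp, Wp = Wp,
       Ho = Ho, Wo = Wo, P = P, K = K, idx = idx, scat = scat)
}

pad_array <- function(x, g) {
  if (g$p == 0L) return(x)
  N <- dim(x)[4]
  xp <- array(0, dim = c(g$Hp, g$Wp, g$C, N))
  xp[g$p + seq_len(g$H), g$p + seq_len(g$W), , ] <- x
  xp
}

unpad_array <- function(xp, g, channels = g$C) {
  if (g$p == 0L) return(xp)
  xp[g$p + seq_len(g$H), g$p + seq_len(g$W), , , drop = FALSE]
}

# gather: padded array -> (N*P) x K matrix of receptive-field rows
conv_gather <- function(xp, g) {
  N <- dim(xp)[4]
  Xflat <- t(matrix(xp, g$Hp * g$Wp * g$C, N))
  Xcol <- Xflat[, as.vector(g$idx), drop = FALSE]         # N x (P*K)
  matrix(array(Xcol, c(N, g$P, g$K)), N * g$P, g$K)
}

# scatter (adjoint of gather): (N*P) x K -> padded array
conv_scatter <- function(m2, g, N) {
  m <- matrix(array(m2, c(N, g$P, g$K)), N, g$P * g$K)
  Xflat <- as.matrix(m %*% g$scat)                        # N x (Hp*Wp*C)
  array(t(Xflat), c(g$Hp, g$Wp, g$C, N))
}

# (Ho,Wo,Cout,N) <-> (N*P) x Cout
out_to_mat <- function(y, g, Cout) {
  N <- dim(y)[4]
  matrix(aperm(array(y, c(g$P, Cout, N)), c(3, 1, 2)), N * g$P, Cout)
}
mat_to_out <- function(m2, g, Cout, N) {
  array(aperm(array(m2, c(N, g$P, Cout)), c(2, 3, 1)), c(g$Ho, g$Wo, Cout, N))
}

# ---- compilation -----------------------------------------------------------

#' Build a sequential network
#'
#' Compiles a list of layer specifications (see [nn_layers]) against an
#' input shape, initialising weights (He-scaled Gaussians) from `seed`.
#'
#' @param layers List of layer specifications.
#' @param input_shape `c(H, W, C)` for image input or a single integer for
#'   vector input.
#' @param seed Integer seed for weight initialisation.
#' @return An `nn_net` object (list of compiled layers plus shapes).
#' @export
nn_sequential <- function(layers, input_shape, seed = 1L) {
  with_seed(seed, nn_compile(layers, input_shape))
}

# Compile without touching the seed (used when several subnetworks must be
# initialised under one RNG stream).
nn_compile <- function(layers, input_shape) {
  shape <- as.integer(input_shape)
  compiled <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    l$in_shape <- shape
    switch(l$type,
      conv = {
        g <- conv_geom(shape, l$kernel, l$stride, l$pad)
        l$geom <- g
        fan_in <- g$K
        l$W <- matrix(rnorm(g$K * l$filters, sd = sqrt(2 / fan_in)),
                      g$K, l$filters)
        l$b <- rep(0, l$filters)
        shape <- c(g$Ho, g$Wo, l$filters)
      },
      convt = {
        # geometry of the adjoint convolution: large (output) side first
        Hs <- shape[1]; Ws <- shape[2]; Cs <- shape[3]
        Hl <- (Hs - 1L) * l$stride - 2L * l$pad + l$kernel
        Wl <- (Ws - 1L) * l$stride - 2L * l$pad + l$kernel
        g <- conv_geom(c(Hl, Wl, l$filters), l$kernel, l$stride, l$pad)
        if (g$Ho != Hs || g$Wo != Ws) stop_arg("incompatible convt geometry")
        l$geom <- g
        l$W <- matrix(rnorm(g$K * Cs, sd = sqrt(2 / (l$kernel^2 * Cs))),
                      g$K, Cs)
        l$b <- rep(0, l$filters)
        shape <- c(Hl, Wl, l$filters)
      },
      maxpool = {
        l$identity <- all(shape[1:2] == 1L)
        if (!l$identity && any(shape[1:2] %% 2L != 0L))
          stop_arg("maxpool needs even spatial dims (got ",
                   paste(shape[1:2], collapse = "x"), ")")
        if (!l$identity) shape <- c(shape[1:2] %/% 2L, shape[3])
      },
      flatten = { shape <- prod(shape) },
      reshape = {
        if (prod(shape) != prod(l$shape)) stop_arg("reshape size mismatch")
        shape <- l$shape
      },
      dense = {
        if (length(shape) != 1L) stop_arg("dense layer needs flattened input")
        l$W <- matrix(rnorm(shape * l$units, sd = sqrt(2 / shape)),
                      shape, l$units)
        l$b <- rep(0, l$units)
        shape <- l$units
      },
      relu = , lrelu = , tanh = , sigmoid = , dropout = NULL,
      stop_arg("unknown layer type: ", l$type)
    )
    l$out_shape <- shape
    compiled[[i]] <- l
  }
  structure(list(layers = compiled, input_shape = as.integer(input_shape),
                 output_shape = shape),
            class = "nn_net")
}

#' @export
print.nn_net <- function(x, ...) {
  cat(sprintf("<nn_net> %s -> %s, %d layers, %d parameters\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$output_shape, collapse = "x"),
              length(x$layers), nn_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters in a network
#' @param net An `nn_net`.
#' @return Integer parameter count.
#' @export
nn_n_params <- function(net) {
  sum(vapply(net$layers, function(l)
    length(l$W %||% numeric(0)) + length(l$b %||% numeric(0)), numeric(1)))
}

# ---- forward / backward ----------------------------------------------------

#' Forward pass through a network
#'
#' @param net An `nn_net`.
#' @param x Input batch: array `(H, W, C, N)` or matrix `(N, D)`.
#' @param train Training mode (enables dropout; draws from the current RNG).
#' @return List with `out` and `cache` (for [nn_backward()]).
#' @export
nn_forward <- function(net, x, train = FALSE) {
  cache <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    res <- switch(l$type,
      conv = {
        g <- l$geom
        N <- dim(x)[4]
        Z <- conv_gather(pad_array(x, g), g)
        y2 <- Z %*% l$W
        y2 <- sweep(y2, 2, l$b, `+`)
        list(out = mat_to_out(y2, g, l$filters, N), cache = list(Z = Z, N = N))
      },
      convt = {
        g <- l$geom
        N <- dim(x)[4]
        U2 <- out_to_mat(x, g, dim(x)[3])
        V2 <- tcrossprod(U2, l$W)                     # (N*P) x K
        vp <- conv_scatter(V2, g, N)
        v <- unpad_array(vp, g)
        v <- v + array(rep(rep(l$b, each = g$H * g$W), N), dim = dim(v))
        list(out = v, cache = list(U2 = U2, N = N))
      },
      maxpool = {
        if (l$identity) list(out = x, cache = NULL)
        else maxpool_forward(x)
      },
      flatten = {
        d <- dim(x); N <- d[4]
        list(out = t(matrix(x, prod(d[1:3]), N)), cache = list(dims = d))
      },
      reshape = {
        N <- nrow(x)
        list(out = array(t(x), c(l$shape, N)), cache = list(N = N))
      },
      dense = {
        y <- x %*% l$W
        y <- sweep(y, 2, l$b, `+`)
        list(out = y, cache = list(x = x))
      },
      relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
      lrelu = {
        mask <- x > 0
        list(out = ifelse(mask, x, l$alpha * x), cache = list(mask = mask))
      },
      tanh = { y <- tanh(x); list(out = y, cache = list(y = y)) },
      sigmoid = { y <- 1 / (1 + exp(-x)); list(out = y, cache = list(y = y)) },
      dropout = {
        if (train) {
          mask <- (runif(length(x)) >= l$p) / (1 - l$p)
          dim(mask) <- dim(x)
          list(out = x * mask, cache = list(mask = mask))
        } else list(out = x, cache = NULL)
      }
    )
    x <- res$out
    cache[[i]] <- res$cache
  }
  list(out = x, cache = cache)
}

POOL_OFFSETS <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))

maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  s1 <- seq(1L, H, 2L); s2 <- seq(1L, W, 2L)
  cur <- x[s1, s2, , , drop = FALSE]
  arg <- array(1L, dim = dim(cur))
  for (k in 2:4) {
    o <- POOL_OFFSETS[[k]]
    cand <- x[s1 + o[1], s2 + o[2], , , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- k
  }
  list(out = cur, cache = list(arg = arg, dims = d))
}

#' Backward pass through a network
#'
#' @param net An `nn_net`.
#' @param cache Cache from [nn_forward()].
#' @param dout Gradient of the loss w.r.t. the network output.
#' @return List with `dx` (gradient w.r.t. the input) and `grads` (per-layer
#'   list of `W`/`b` gradients, `NULL` for parameter-free layers).
#' @export
nn_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- cache[[i]]
    switch(l$type,
      conv = {
        g <- l$geom
        dY2 <- out_to_mat(dout, g, l$filters)
        grads[[i]] <- list(W = crossprod(cc$Z, dY2), b = colSums(dY2))
        dZ <- tcrossprod(dY2, l$W)                    # (N*P) x K
        dxp <- conv_scatter(dZ, g, cc$N)
        dout <- unpad_array(dxp, g)
      },
      convt = {
        g <- l$geom
        Dcol <- conv_gather(pad_array(dout, g), g)    # (N*P) x K
        grads[[i]] <- list(W = crossprod(Dcol, cc$U2),
                           b = apply(dout, 3, sum))
        dU2 <- Dcol %*% l$W                           # (N*P) x Cs
        dout <- mat_to_out(dU2, g, ncol(l$W), cc$N)
      },
      maxpool = {
        if (!l$identity) {
          d <- cc$dims
          s1 <- seq(1L, d[1], 2L); s2 <- seq(1L, d[2], 2L)
          dx <- array(0, dim = d)
          for (k in 1:4) {
            o <- POOL_OFFSETS[[k]]
            dx[s1 + o[1], s2 + o[2], , ] <- dout * (cc$arg == k)
          }
          dout <- dx
        }
      },
      flatten = { dout <- array(t(dout), cc$dims) },
      reshape = {
        D <- prod(l$shape)
        dout <- t(matrix(dout, D, cc$N))
      },
      dense = {
        grads[[i]] <- list(W = crossprod(cc$x, dout), b = colSums(dout))
        dout <- tcrossprod(dout, l$W)
      },
      relu = { dout <- dout * cc$mask },
      lrelu = { dout <- ifelse(cc$mask, dout, l$alpha * dout) },
      tanh = { dout <- dout * (1 - cc$y^2) },
      sigmoid = { dout <- dout * cc$y * (1 - cc$y) },
      dropout = { if (!is.null(cc)) dout <- dout * cc$mask }
    )
  }
  list(dx = dout, grads = grads)
}

# ---- losses ----------------------------------------------------------------

softmax_rows <- function(logits) {
  m <- logits - apply(logits, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# mean cross-entropy over the batch; labels are 1-based integers.
# Returns loss and gradient w.r.t. logits.
softmax_ce <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  ll <- -mean(log(pmax(p[cbind(seq_len(n), labels)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  list(loss = ll, grad = g / n)
}

# soft-target binary cross-entropy on logits; mean over all elements.
bce_logits <- function(logits, targets) {
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-12
  loss <- -mean(targets * log(pmax(p, eps)) +
                (1 - targets) * log(pmax(1 - p, eps)))
  list(loss = loss, grad = (p - targets) / length(p), p = p)
}

# BCE on probabilities (used by the printed-form loss evaluators)
bce_prob <- function(targets, p) {
  eps <- 1e-12
  -mean(targets * log(pmax(p, eps)) + (1 - targets) * log(pmax(1 - p, eps)))
}

# ---- optimisers ------------------------------------------------------------

#' Create an optimiser for a set of networks
#'
#' @param nets Named list of `nn_net` objects updated together.
#' @param method `"sgd"` (with momentum) or `"adam"`.
#' @param lr Learning rate.
#' @param momentum SGD momentum (default 0.9).
#' @param beta1,beta2,eps Adam moment parameters.
#' @return An optimiser state object.
#' @export
nn_optimizer <- function(nets, method = c("sgd", "adam"), lr = 0.001,
                         momentum = 0.9, beta1 = 0.5, beta2 = 0.999,
                         eps = 1e-8) {
  method <- match.arg(method)
  state <- lapply(nets, function(net)
    lapply(net$layers, function(l) {
      if (is.null(l$W)) return(NULL)
      s <- list(vW = l$W * 0, vb = l$b * 0)
      if (method == "adam") { s$mW <- l$W * 0; s$mb <- l$b * 0 }
      s
    }))
  structure(list(method = method, lr = lr, momentum = momentum,
                 beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
                 state = state),
            class = "nn_optimizer")
}

#' Apply one optimiser step
#'
#' Adds each dense layer's configured L2 weight decay to its gradient, then
#' updates all parameters in place.
#'
#' @param opt An [nn_optimizer()] state.
#' @param nets Named list of networks (same names as at creation).
#' @param grads Named list of per-network gradient lists from
#'   [nn_backward()].
#' @return List with updated `nets` and `opt`.
#' @export
nn_step <- function(opt, nets, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    net <- nets[[nm]]
    for (i in seq_along(net$layers)) {
      gi <- grads[[nm]][[i]]
      if (is.null(gi)) next
      l <- net$layers[[i]]
      gW <- gi$W
      if (!is.null(l$l2) && l$l2 > 0) gW <- gW + l$l2 * l$W
      s <- opt$state[[nm]][[i]]
      if (opt$method == "sgd") {
        s$vW <- opt$momentum * s$vW - opt$lr * gW
        s$vb <- opt$momentum * s$vb - opt$lr * gi$b
        l$W <- l$W + s$vW
        l$b <- l$b + s$vb
      } else {
        s$mW <- opt$beta1 * s$mW + (1 - opt$beta1) * gW
        s$vW <- opt$beta2 * s$vW + (1 - opt$beta2) * gW^2
        s$mb <- opt$beta1 * s$mb + (1 - opt$beta1) * gi$b
        s$vb <- opt$beta2 * s$vb + (1 - opt$beta2) * gi$b^2
        bc1 <- 1 - opt$beta1^opt$t; bc2 <- 1 - opt$beta2^opt$t
        l$W <- l$W - opt$lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + opt$eps)
        l$b <- l$b - opt$lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + opt$eps)
      }
      opt$state[[nm]][[i]] <- s
      net$layers[[i]] <- l
    }
    nets[[nm]] <- net
  }
  list(nets = nets, opt = opt)
}
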