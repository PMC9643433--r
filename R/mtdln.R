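# Multi-task attribute network ----------------------------------------------
#
# A shared-trunk / three-branch convolutional classifier over face images:
# one expression head (7 classes), one identity head (N training
# identities) and one gender head (2 classes). The architecture family is
# indexed by a split point: how many of the 7 units (5 conv blocks + 2 FC
# layers) are shared before the network branches. Each conv block is a
# conv-conv-maxpool unit (the VGG block pattern at reduced width); the two
# FC layers are `fc_width` wide, the first carrying L2 weight decay and the
# second followed by dropout. The joint loss is the convex combination
# alpha1 * CE_expression + alpha2 * CE_identity + alpha3 * CE_gender.

TASKS <- c("expression", "identity", "gender")

#' Configuration of the multi-task attribute network
#'
#' @param n_identities Number of training identities N (identity head size).
#' @param split_index How many of the 7 units (5 conv blocks, 2 FC layers)
#'   are shared before branching, 0-7. 0 means three independent networks;
#'   4 (the default) shares the first four conv blocks.
#' @param alphas Task weights `(alpha1, alpha2, alpha3)` for
#'   (expression, identity, gender); nonnegative, summing to 1.
#'   Default `c(0.4, 0.3, 0.3)`.
#' @param image_size Input image size `c(H, W)`.
#' @param scale `"desk"` (narrow layers, the default) or `"full"`
#'   (VGG-width trunk, 512-wide FC layers).
#' @param conv_widths Widths of the 5 conv blocks (overrides `scale`).
#' @param fc_width Width of the two FC layers (overrides `scale`;
#'   512 at full scale).
#' @param learning_rate,momentum,batch_size,epochs SGD settings
#'   (defaults 0.001, 0.9, 32, 500; use far fewer epochs at desk scale).
#' @param l2_rate L2 decay on the first FC layer of each branch (0.001).
#' @param dropout Dropout after the second FC layer of each branch (0.5).
#' @param freeze_trunk Keep shared-trunk parameters fixed during training
#'   (the transfer-learning regime where the trunk comes pre-trained).
#' @param openset_pairs `c(n_same, n_diff)` pairs used for the per-epoch
#'   open-set identity validation accuracy (desk-scale default 100/100;
#'   the final evaluation protocol uses 900/900).
#' @param openset_folds Folds for the per-epoch open-set accuracy.
#' @return An `mtdln_config` object.
#' @export
mtdln_config <- function(n_identities, split_index = 4L,
                         alphas = c(0.4, 0.3, 0.3),
                         image_size = c(64L, 64L),
                         scale = c("desk", "full"),
                         conv_widths = NULL, fc_width = NULL,
                         learning_rate = 0.001, momentum = 0.9,
                         batch_size = 32L, epochs = 500L,
                         l2_rate = 0.001, dropout = 0.5,
                         freeze_trunk = FALSE,
                         openset_pairs = c(100L, 100L),
                         openset_folds = 5L) {
  scale <- match.arg(scale)
  if (!(split_index %in% 0:7))
    stop_arg("`split_index` must be an integer in 0..7")
  check_alphas(alphas)
  if (is.null(conv_widths))
    conv_widths <- if (scale == "full") c(64L, 128L, 256L, 512L, 512L)
                   else c(4L, 8L, 8L, 16L, 16L)
  if (is.null(fc_width)) fc_width <- if (scale == "full") 512L else 32L
  if (length(conv_widths) != 5) stop_arg("`conv_widths` must have length 5")
  structure(list(n_identities = as.integer(n_identities),
                 split_index = as.integer(split_index), alphas = alphas,
                 image_size = as.integer(image_size), scale = scale,
                 conv_widths = as.integer(conv_widths),
                 fc_width = as.integer(fc_width),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2_rate = l2_rate,
                 dropout = dropout, freeze_trunk = freeze_trunk,
                 openset_pairs = as.integer(openset_pairs),
                 openset_folds = as.integer(openset_folds),
                 head_dims = c(expression = 7L,
                               identity = as.integer(n_identities),
                               gender = 2L)),
            class = "mtdln_config")
}

check_alphas <- function(alphas) {
  if (length(alphas) != 3 || any(alphas < 0))
    stop_arg("`alphas` must be three nonnegative weights")
  if (abs(sum(alphas) - 1) > 1e-8)
    stop_arg("`alphas` must sum to 1 (got ", format(sum(alphas)), ")")
  invisible(alphas)
}

#' Weighted multi-task loss
#'
#' The convex combination `alpha1*loss1 + alpha2*loss2 + alpha3*loss3` of
#' the per-task cross-entropies (expression, identity, gender). With a
#' one-hot `alphas` it reduces to the corresponding single-task loss.
#'
#' @param losses Numeric vector of the three per-task losses.
#' @param alphas Three nonnegative weights summing to 1 (tolerance 1e-8).
#' @return The scalar combined loss.
#' @export
multitask_loss <- function(losses, alphas) {
  if (length(losses) != 3) stop_arg("`losses` must have length 3")
  check_alphas(alphas)
  sum(alphas * losses)
}

# the 7 architecture units as layer-spec lists
mtdln_units <- function(config) {
  blocks <- lapply(config$conv_widths, function(w)
    list(layer_conv(w, 3L, 1L, "same"), layer_relu(),
         layer_conv(w, 3L, 1L, "same"), layer_relu(), layer_maxpool()))
  fc1 <- list(layer_flatten(), layer_dense(config$fc_width, l2 = config$l2_rate),
              layer_relu())
  fc2 <- list(layer_dense(config$fc_width), layer_relu(),
              layer_dropout(config$dropout))
  c(blocks, list(fc1, fc2))
}

#' Build the multi-task network
#'
#' Assembles the shared trunk (the first `split_index` units) and three
#' branches (the remaining units plus a classification head of 7, N and 2
#' units respectively).
#'
#' @param config An [mtdln_config()].
#' @param seed Weight-initialisation seed.
#' @return An `mtdln_model` object: list with `trunk` (an `nn_net`, or
#'   `NULL` when `split_index = 0`), `branches` (named list of `nn_net`),
#'   and `config`.
#' @export
build_mtdln <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mtdln_config"))
  units <- mtdln_units(config)
  s <- config$split_index
  trunk_spec <- if (s > 0) do.call(c, units[seq_len(s)]) else list()
  in_shape <- c(config$image_size, 1L)
  with_seed(seed, {
    trunk <- if (length(trunk_spec)) nn_compile(trunk_spec, in_shape) else NULL
    mid_shape <- if (is.null(trunk)) in_shape else trunk$output_shape
    branches <- lapply(TASKS, function(task) {
      spec <- if (s < 7) do.call(c, units[(s + 1):7]) else list()
      spec <- c(spec, list(layer_dense(config$head_dims[[task]])))
      nn_compile(spec, mid_shape)
    })
    names(branches) <- TASKS
    structure(list(trunk = trunk, branches = branches, config = config),
              class = "mtdln_model")
  })
}

#' @export
print.mtdln_model <- function(x, ...) {
  pc <- mtdln_param_counts(x)
  cat(sprintf(paste0("<mtdln_model> split %d, %dx%d input, fc %d; ",
                     "%d shared + %d branch parameters\n"),
              x$config$split_index, x$config$image_size[1],
              x$config$image_size[2], x$config$fc_width,
              pc["trunk"], pc["branches"]))
  invisible(x)
}

#' Trainable-parameter counts of the shared trunk and the three branches
#'
#' @param model An `mtdln_model`.
#' @return Named vector `c(trunk = , branches = )`.
#' @export
mtdln_param_counts <- function(model) {
  trunk <- if (is.null(model$trunk)) 0 else nn_n_params(model$trunk)
  c(trunk = trunk,
    branches = sum(vapply(model$branches, nn_n_params, numeric(1))))
}

# images (H,W,n) 0-255 -> network input (H,W,1,n) in [-1, 1]
prep_images <- function(images) {
  d <- dim(images)
  array(images / 127.5 - 1, dim = c(d[1], d[2], 1L, d[3]))
}

# forward all heads; returns logits, the penultimate identity activations
# and (optionally) caches for the backward pass
mtdln_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  if (!is.null(model$trunk)) {
    ft <- nn_forward(model$trunk, x, train = train)
    mid <- ft$out
  } else { ft <- NULL; mid <- x }
  br <- lapply(model$branches, nn_forward, x = mid, train = train)
  head_idx <- length(model$branches$identity$layers)
  t_id <- br$identity$cache[[head_idx]]$x   # input of the identity head
  out <- list(logits = lapply(br, `[[`, "out"), t_id = t_id)
  if (keep_cache) { out$trunk_cache <- ft; out$branch_fw <- br; out$mid <- mid }
  out
}

#' Extract multi-dimensional attribute features from a trained network
#'
#' `t_id` is the penultimate identity-branch activation vector (`fc_width`
#' units); `t_exp` and `t_gen` are the softmax outputs of the expression and
#' gender heads (each summing to 1); `z` is their concatenation, of
#' dimension `fc_width + 7 + 2` (521 at full scale).
#'
#' @param model A trained `mtdln_model`.
#' @param images Array `H x W x n` (or `H x W`) of 8-bit grayscale images
#'   matching the model's input size.
#' @return An [attribute_features()] object with `n` rows.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "mtdln_model"))
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1L)
  if (!all(dim(images)[1:2] == model$config$image_size))
    stop_arg("image size ", paste(dim(images)[1:2], collapse = "x"),
             " does not match the model input ",
             paste(model$config$image_size, collapse = "x"))
  fw <- mtdln_forward(model, prep_images(images), train = FALSE)
  attribute_features(fw$t_id, softmax_rows(fw$logits$expression),
                     softmax_rows(fw$logits$gender))
}

# map raw identity_id labels to 1..N head indices (training identities)
identity_index <- function(ids, universe) {
  idx <- match(ids, universe)
  if (anyNA(idx)) stop_arg("identity label outside the training identities")
  idx
}

#' Train the multi-task network
#'
#' Minibatch SGD (momentum) on the weighted joint loss, logging per-epoch
#' validation accuracies for all three tasks: category accuracy for
#' expression and gender, the open-set verification accuracy for identity
#' (validation identities need not — and for the open-set protocol must
#' not — overlap the training identities).
#'
#' @param model An `mtdln_model` from [build_mtdln()].
#' @param train_set,val_set `face_stimulus_set`s. `val_set` may be `NULL`
#'   (history then records `NA` accuracies).
#' @param config Optional [mtdln_config()] override (defaults to the
#'   model's).
#' @param seed Seed for shuffling, dropout and validation-pair sampling.
#' @return List with `model` (trained), `history` (class
#'   `mtdln_history`: per-epoch accuracy data.frame plus `peak`), and
#'   `config`.
#' @export
train_mtdln <- function(model, train_set, val_set = NULL, config = model$config,
                        seed = 1L) {
  stopifnot(inherits(model, "mtdln_model"))
  if (!inherits(train_set, "face_stimulus_set") || nrow(train_set$labels) == 0)
    stop_arg("`train_set` must be a non-empty face_stimulus_set")
  if (!is.null(val_set) && nrow(val_set$labels) == 0)
    stop_arg("`val_set` is empty; pass NULL to skip validation")

  x_all <- prep_images(train_set$images)
  id_universe <- sort(unique(train_set$labels$identity_id))
  if (length(id_universe) > config$n_identities)
    stop_arg("more training identities than the identity head size N")
  y <- list(expression = train_set$labels$expression_id + 1L,
            identity = identity_index(train_set$labels$identity_id, id_universe),
            gender = train_set$labels$gender_id + 1L)

  n <- dim(x_all)[4]
  nets <- c(list(trunk = model$trunk), model$branches)
  nets <- nets[!vapply(nets, is.null, logical(1))]
  opt <- nn_optimizer(nets, "sgd", lr = config$learning_rate,
                      momentum = config$momentum)
  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     expression = NA_real_, identity = NA_real_,
                     gender = NA_real_)
  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        xb <- x_all[, , , b, drop = FALSE]
        fw <- mtdln_forward(model, xb, train = TRUE, keep_cache = TRUE)
        task_losses <- numeric(3); names(task_losses) <- TASKS
        branch_grads <- list()
        dmid <- NULL
        for (task in TASKS) {
          ce <- softmax_ce(fw$logits[[task]], y[[task]][b])
          task_losses[task] <- ce$loss
          bw <- nn_backward(model$branches[[task]], fw$branch_fw[[task]]$cache,
                            config$alphas[match(task, TASKS)] * ce$grad)
          branch_grads[[task]] <- bw$grads
          dmid <- if (is.null(dmid)) bw$dx else dmid + bw$dx
        }
        grads <- branch_grads
        if (!is.null(model$trunk) && !config$freeze_trunk) {
          tb <- nn_backward(model$trunk, fw$trunk_cache$cache, dmid)
          grads$trunk <- tb$grads
        }
        ep_loss <- ep_loss + multitask_loss(task_losses, config$alphas) * length(b)
        nets <- c(list(trunk = model$trunk), model$branches)
        step <- nn_step(opt, nets[names(grads)], grads)
        opt <- step$opt
        for (nm in names(step$nets)) {
          if (nm == "trunk") model$trunk <- step$nets$trunk
          else model$branches[[nm]] <- step$nets[[nm]]
        }
      }
      hist$loss[epoch] <- ep_loss / n
      if (!is.null(val_set)) {
        hist$expression[epoch] <-
          evaluate_category_accuracy(model, val_set, "expression")
        hist$gender[epoch] <-
          evaluate_category_accuracy(model, val_set, "gender")
        hist$identity[epoch] <- tryCatch(
          evaluate_identity_openset(model, val_set,
                                    n_same = config$openset_pairs[1],
                                    n_diff = config$openset_pairs[2],
                                    folds = config$openset_folds,
                                    seed = child_seed(seed, epoch)),
          error = function(e) NA_real_)
      }
    }
  })
  history <- structure(list(table = hist,
                            peak = c(expression = suppressWarnings(max(hist$expression, na.rm = TRUE)),
                                     identity = suppressWarnings(max(hist$identity, na.rm = TRUE)),
                                     gender = suppressWarnings(max(hist$gender, na.rm = TRUE)))),
                       class = "mtdln_history")
  list(model = model, history = history, config = config)
}

#' @export
print.mtdln_history <- function(x, ...) {
  cat(sprintf("<mtdln_history> %d epochs; peak val accuracy: exp %.3f, id %.3f, gen %.3f\n",
              nrow(x$table), x$peak["expression"], x$peak["identity"],
              x$peak["gender"]))
  invisible(x)
}

#' Classification accuracy on a labelled validation set
#'
#' Fraction of stimuli whose arg-max predicted category equals the label.
#' Identity is evaluated with the open-set protocol instead
#' ([evaluate_identity_openset()]).
#'
#' @param model A trained `mtdln_model`.
#' @param set A labelled `face_stimulus_set`.
#' @param task `"expression"` or `"gender"`.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_category_accuracy <- function(model, set, task) {
  if (!task %in% c("expression", "gender"))
    stop_arg("`task` must be \"expression\" or \"gender\"")
  fw <- mtdln_forward(model, prep_images(set$images), train = FALSE)
  pred <- max.col(fw$logits[[task]], ties.method = "first")
  truth <- set$labels[[paste0(task, "_id")]] + 1L
  mean(pred == truth)
}

#' Open-set identity verification accuracy
#'
#' The distance-threshold protocol for identities never seen in training:
#' sample `n_same` same-identity and `n_diff` different-identity image
#' pairs, compute Euclidean distances between their penultimate
#' identity-branch feature vectors, split the pairs into `folds` groups,
#' and for each group apply the accuracy-maximising threshold fitted on the
#' remaining groups (smallest such threshold on ties). Returns the mean
#' cross-validated accuracy.
#'
#' @param model A trained `mtdln_model`.
#' @param val_set A labelled `face_stimulus_set` of open-set identities.
#' @param n_same,n_diff Number of same/different-identity pairs (900/900 at
#'   full scale). Pairs are sampled with replacement.
#' @param folds Cross-validation groups (default 10).
#' @param seed Pair-sampling seed.
#' @return Mean cross-validated verification accuracy in `[0, 1]`.
#' @export
evaluate_identity_openset <- function(model, val_set, n_same = 900L,
                                      n_diff = 900L, folds = 10L, seed = 1L) {
  fw <- mtdln_forward(model, prep_images(val_set$images), train = FALSE)
  openset_verification(fw$t_id, val_set$labels$identity_id,
                       n_same = n_same, n_diff = n_diff, folds = folds,
                       seed = seed)
}

#' @rdname evaluate_identity_openset
#' @param features Matrix `n x d` of identity features (one row per image).
#' @param identities Identity label per row.
#' @export
openset_verification <- function(features, identities, n_same = 900L,
                                 n_diff = 900L, folds = 10L, seed = 1L) {
  features <- as.matrix(features)
  ids <- as.vector(identities)
  tab <- table(ids)
  if (length(tab) < 2)
    stop_arg("need at least two distinct identities for different-identity pairs")
  if (!any(tab >= 2))
    stop_arg("need at least one identity with two images for same-identity pairs")
  multi <- names(tab)[tab >= 2]
  with_seed(seed, {
    pick_same <- function() {
      id <- sample(multi, 1L)
      sample(which(ids == id), 2L)
    }
    pick_diff <- function() {
      two <- sample(names(tab), 2L)
      c(sample(which(ids == two[1]), 1L), sample(which(ids == two[2]), 1L))
    }
    pairs <- rbind(
      t(vapply(seq_len(n_same), function(i) pick_same(), integer(2))),
      t(vapply(seq_len(n_diff), function(i) pick_diff(), integer(2))))
    same <- rep(c(1L, 0L), c(n_same, n_diff))
    d <- sqrt(rowSums((features[pairs[, 1], , drop = FALSE] -
                       features[pairs[, 2], , drop = FALSE])^2))
    fold <- sample(rep_len(seq_len(folds), length(d)))
    acc <- vapply(seq_len(folds), function(f) {
      thr <- best_threshold(d[fold != f], same[fold != f])
      mean((d[fold == f] < thr) == (same[fold == f] == 1L))
    }, numeric(1))
    mean(acc)
  })
}

# smallest threshold maximising accuracy of rule "same iff distance < thr"
best_threshold <- function(d, same) {
  ud <- sort(unique(d))
  cand <- c(ud[1] - 1, (ud[-1] + ud[-length(ud)]) / 2, ud[length(ud)] + 1)
  acc <- vapply(cand, function(th) mean((d < th) == (same == 1L)), numeric(1))
  cand[which.max(acc)]   # which.max returns the first (smallest) maximiser
}

#' Save / load a model checkpoint
#'
#' Serialises the model to `<path>.rds` with a JSON manifest `<path>.json`
#' recording the configuration.
#'
#' @param model An `mtdln_model` or `mcgan_model`.
#' @param path Path prefix (no extension).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  cfg <- model$config
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  jsonlite::write_json(list(class = class(model)[1], config = cfg),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(paste0(path, ".rds"))
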