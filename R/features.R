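# Attribute feature container ------------------------------------------------
#
# The framework's latent code z is the concatenation (t_id, t_exp, t_gen):
# an identity feature block (the penultimate identity-branch activations of
# the multi-task network, or any stand-in embedding), a 7-dim expression
# block and a 2-dim gender block. All stages downstream of feature
# extraction operate on this container.

#' Construct an attribute-feature container
#'
#' @param t_id Matrix `n x d_id` of identity features.
#' @param t_exp Matrix `n x 7` of expression features.
#' @param t_gen Matrix `n x 2` of gender features.
#' @return An `attribute_features` object: list with `z`
#'   (`n x (d_id + 7 + 2)`, columns ordered id, exp, gen), `blocks`
#'   (named list of column indices) and `dims`.
#' @export
attribute_features <- function(t_id, t_exp, t_gen) {
  t_id <- as.matrix(t_id); t_exp <- as.matrix(t_exp); t_gen <- as.matrix(t_gen)
  n <- nrow(t_id)
  if (nrow(t_exp) != n || nrow(t_gen) != n)
    stop_arg("feature blocks must have the same number of rows")
  d <- c(identity = ncol(t_id), expression = ncol(t_exp), gender = ncol(t_gen))
  z <- cbind(t_id, t_exp, t_gen)
  colnames(z) <- c(sprintf("t_id_%d", seq_len(d[1]) - 1L),
                   sprintf("t_exp_%d", seq_len(d[2]) - 1L),
                   sprintf("t_gen_%d", seq_len(d[3]) - 1L))
  blocks <- list(identity = seq_len(d[1]),
                 expression = d[1] + seq_len(d[2]),
                 gender = d[1] + d[2] + seq_len(d[3]))
  structure(list(z = z, blocks = blocks, dims = d),
            class = "attribute_features")
}

#' @export
print.attribute_features <- function(x, ...) {
  cat(sprintf("<attribute_features> %d stimuli, z dim %d (id %d + exp %d + gen %d)\n",
              nrow(x$z), ncol(x$z), x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Extract one attribute block from an attribute-feature container
#'
#' @param features An `attribute_features` object.
#' @param attribute One of `"identity"`, `"expression"`, `"gender"`.
#' @return The block as a matrix.
#' @export
feature_block <- function(features, attribute) {
  stopifnot(inherits(features, "attribute_features"))
  attribute <- match.arg(attribute, c("identity", "expression", "gender"))
  features$z[, features$blocks[[attribute]], drop = FALSE]
}

#' Ground-truth attribute features from stimulus labels
#'
#' Builds label-derived features: a fixed random Gaussian embedding per
#' identity (`d_id` dimensions, seeded), a one-hot 7-vector per expression
#' and a one-hot 2-vector per gender. These are the encoding features the
#' response simulator uses as ground truth, and a fast stand-in for trained
#' network features when exercising the downstream stages.
#'
#' @param set A `face_stimulus_set` (or its `labels` data.frame).
#' @param d_id Identity embedding dimension (default 16).
#' @param seed Seed for the identity embedding.
#' @return An `attribute_features` object with one row per stimulus.
#' @export
label_features <- function(set, d_id = 16L, seed = 1L) {
  labels <- if (inherits(set, "face_stimulus_set")) set$labels else set
  ids <- labels$identity_id
  uid <- sort(unique(ids))
  emb <- with_seed(seed, matrix(rnorm(length(uid) * d_id), length(uid), d_id))
  rownames(emb) <- as.character(uid)
  t_id <- emb[as.character(ids), , drop = FALSE]
  rownames(t_id) <- NULL
  onehot <- function(v, k) {
    m <- matrix(0, length(v), k)
    m[cbind(seq_along(v), v + 1L)] <- 1
    m
  }
  attribute_features(t_id, onehot(labels$expression_id, 7L),
                     onehot(labels$gender_id, 2L))
}

#' Write / read an attribute-feature table
#'
#' Tab-separated file, one row per stimulus, columns named
#' `t_id_0, ..., t_exp_0, ..., t_gen_0, ...`.
#'
#' @param features An `attribute_features` object.
#' @param path File path.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "attribute_features"))
  write.table(features$z, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  z <- as.matrix(read.delim(path, check.names = FALSE))
  d_exp <- sum(startsWith(colnames(z), "t_exp_"))
  d_gen <- sum(startsWith(colnames(z), "t_gen_"))
  d_id <- ncol(z) - d_exp - d_gen
  attribute_features(z[, seq_len(d_id), drop = FALSE],
                     z[, d_id + seq_len(d_exp), drop = FALSE],
                     z[, d_id + d_exp + seq_len(d_gen), drop = FALSE])
}
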