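# Linear brain-to-feature regression -----------------------------------------
#
# Ordinary least squares, without intercept, from ROI voxel responses S to
# attribute feature blocks T: W = (S'S)^{-1} S'T, per attribute, with the
# voxel columns of S drawn from an attribute-specific ROI group. When S'S
# is singular (more voxels than samples) the minimum-norm pseudoinverse
# solution is used instead, with a warning.

#' ROI-combination strategies
#'
#' Which ROIs feed each attribute's regression, and which attribute blocks
#' are kept as conditioning constraints downstream:
#' \describe{
#'   \item{proposed}{expression from V1, OFA, amygdala, pSTS; identity and
#'     gender from V1, OFA, FFA, aIT; all three constraints kept.}
#'   \item{strategy1}{V1 only, for every attribute.}
#'   \item{strategy2}{all six ROIs, for every attribute.}
#'   \item{strategy3}{all six ROIs; identity constraint only (expression
#'     and gender blocks zeroed before conditioning).}
#'   \item{strategy4}{all six ROIs; identity + gender constraints.}
#'   \item{strategy5}{all six ROIs; identity + expression constraints.}
#' }
#'
#' @param name Strategy name.
#' @return An `roi_group_strategy`: list with `name`, `groups` (named list
#'   attribute -> ROI names) and `constraints` (attributes kept).
#' @export
roi_group_strategy <- function(name = c("proposed", "strategy1", "strategy2",
                                        "strategy3", "strategy4", "strategy5")) {
  name <- match.arg(name)
  all6 <- ROI_NAMES
  exp_group <- c("V1", "OFA", "amygdala", "pSTS")
  id_group <- c("V1", "OFA", "FFA", "aIT")
  groups <- switch(name,
    proposed = list(expression = exp_group, identity = id_group,
                    gender = id_group),
    strategy1 = list(expression = "V1", identity = "V1", gender = "V1"),
    list(expression = all6, identity = all6, gender = all6))
  constraints <- switch(name,
    strategy3 = "identity",
    strategy4 = c("identity", "gender"),
    strategy5 = c("identity", "expression"),
    c("identity", "expression", "gender"))
  structure(list(name = name, groups = groups, constraints = constraints),
            class = "roi_group_strategy")
}

#' @export
print.roi_group_strategy <- function(x, ...) {
  cat(sprintf("<roi_group_strategy> %s (constraints: %s)\n", x$name,
              paste(x$constraints, collapse = ", ")))
  for (a in names(x$groups))
    cat(sprintf("  %-10s <- %s\n", a, paste(x$groups[[a]], collapse = ", ")))
  invisible(x)
}

#' Assemble the design matrix S for one attribute's regression
#'
#' Concatenates the voxel columns of the strategy's ROI group for
#' `attribute` and the selected runs: `mode = "stack"` stacks runs as
#' independent rows (run 1's stimuli, then run 2's, ...), `mode =
#' "average"` collapses the selected runs by their mean.
#'
#' @param responses An `roi_response_set`.
#' @param strategy An [roi_group_strategy()] (or a bare list with a
#'   `groups` entry).
#' @param attribute `"expression"`, `"identity"` or `"gender"`.
#' @param runs Integer run indices (default: all runs).
#' @param mode `"stack"` or `"average"`.
#' @return Matrix `S` with attribute `"stim"` giving each row's stimulus
#'   index (rows are `stimuli x runs` when stacked).
#' @export
assemble_design <- function(responses, strategy, attribute,
                            runs = seq_len(responses$n_runs),
                            mode = c("stack", "average")) {
  mode <- match.arg(mode)
  attribute <- match.arg(attribute, c("expression", "identity", "gender"))
  rois <- strategy$groups[[attribute]]
  missing_roi <- setdiff(rois, names(responses$roi_cols))
  if (length(missing_roi))
    stop_arg("ROI(s) absent from the response set: ",
             paste(missing_roi, collapse = ", "))
  cols <- unlist(responses$roi_cols[rois], use.names = FALSE)
  n_stim <- dim(responses$responses)[1]
  if (mode == "average") {
    S <- apply(responses$responses[, cols, runs, drop = FALSE], c(1, 2), mean)
    attr(S, "stim") <- seq_len(n_stim)
  } else {
    S <- do.call(rbind, lapply(runs, function(r)
      matrix(responses$responses[, cols, r], n_stim, length(cols))))
    attr(S, "stim") <- rep(seq_len(n_stim), times = length(runs))
  }
  S
}

#' Fit the linear map W = (S'S)^-1 S'T
#'
#' All feature dimensions are fit jointly through the matrix normal
#' equations (equivalent to independent per-column regressions). On a
#' rank-deficient `S'S` the minimum-norm least-squares solution (SVD
#' pseudoinverse) is returned with a warning.
#'
#' @param S Design matrix (samples x voxels).
#' @param T_feat Target feature matrix (samples x feature dims).
#' @param meta Optional metadata list stored on the map (attribute, ROIs,
#'   runs).
#' @return A `linear_map`: list with `W` (voxels x feature dims),
#'   `rank_deficient` flag and `meta`.
#' @export
fit_linear_map <- function(S, T_feat, meta = list()) {
  S <- as.matrix(S); T_feat <- as.matrix(T_feat)
  if (nrow(S) != nrow(T_feat))
    stop_arg("S and T have different numbers of rows (", nrow(S), " vs ",
             nrow(T_feat), ")")
  StS <- crossprod(S)
  rank_deficient <- FALSE
  W <- tryCatch({
    R <- chol(StS)
    backsolve(R, forwardsolve(t(R), crossprod(S, T_feat)))
  }, error = function(e) NULL)
  if (is.null(W)) {
    rank_deficient <- TRUE
    warning("S'S is singular; using the minimum-norm pseudoinverse solution")
    sv <- svd(S)
    pos <- sv$d > max(dim(S)) * max(sv$d) * .Machine$double.eps
    W <- sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], T_feat))
  }
  dimnames(W) <- list(colnames(S), colnames(T_feat))
  structure(list(W = W, rank_deficient = rank_deficient, meta = meta),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("<linear_map> %d voxels -> %d feature dims%s\n",
              nrow(x$W), ncol(x$W),
              if (x$rank_deficient) " (minimum-norm fit)" else ""))
  invisible(x)
}

#' Predict attribute features from new responses
#'
#' The plain matrix product `S_new %*% W` — no intercept, matching the
#' training model.
#'
#' @param S_new Matrix of new responses (samples x voxels).
#' @param map A `linear_map`.
#' @return Predicted feature matrix.
#' @export
predict_features <- function(S_new, map) {
  stopifnot(inherits(map, "linear_map"))
  S_new <- as.matrix(S_new)
  if (ncol(S_new) != nrow(map$W))
    stop_arg("S_new has ", ncol(S_new), " columns but the map expects ",
             nrow(map$W))
  S_new %*% map$W
}

#' Concatenate predicted blocks into multi-dimensional features
#'
#' Builds `z = (t_id, t_exp, t_gen)`. The bounded expression and gender
#' blocks are clipped to `[0, 1]` (with a warning when clipping occurs);
#' attribute blocks not in `constraints` are zeroed, which is how the
#' constraint-ablation strategies condition the generator on fewer
#' attributes.
#'
#' @param pred_exp,pred_id,pred_gen Predicted blocks (7, d_id and 2
#'   columns).
#' @param constraints Attributes kept (default all three).
#' @return An [attribute_features()] object.
#' @export
assemble_multidim_features <- function(pred_exp, pred_id, pred_gen,
                                       constraints = c("identity", "expression",
                                                       "gender")) {
  pred_exp <- as.matrix(pred_exp); pred_id <- as.matrix(pred_id)
  pred_gen <- as.matrix(pred_gen)
  if (ncol(pred_exp) != 7L) stop_arg("expression block must have 7 columns")
  if (ncol(pred_gen) != 2L) stop_arg("gender block must have 2 columns")
  clip_block <- function(b, nm) {
    if (any(b < 0 | b > 1)) {
      warning("clipping ", nm, " features to [0, 1]")
      b <- clip(b, 0, 1)
    }
    b
  }
  pred_exp <- clip_block(pred_exp, "expression")
  pred_gen <- clip_block(pred_gen, "gender")
  if (!"identity" %in% constraints) pred_id[] <- 0
  if (!"expression" %in% constraints) pred_exp[] <- 0
  if (!"gender" %in% constraints) pred_gen[] <- 0
  attribute_features(pred_id, pred_exp, pred_gen)
}

#' Fit the three attribute regressions of a strategy
#'
#' Convenience wrapper: assembles each attribute's design from its ROI
#' group and the training runs (stacked as independent rows by default)
#' and fits [fit_linear_map()] against the matching feature block.
#'
#' @param responses An `roi_response_set`.
#' @param features An `attribute_features` object (one row per stimulus).
#' @param strategy An [roi_group_strategy()].
#' @param runs Training run indices (default runs 1-3).
#' @param mode `"stack"` or `"average"` run handling.
#' @param center Optionally mean-center S and T columns before fitting
#'   (default `FALSE`, matching the intercept-free model).
#' @return Named list of `linear_map`s (expression, identity, gender) with
#'   centering vectors attached when `center = TRUE`.
#' @export
fit_attribute_maps <- function(responses, features, strategy,
                               runs = 1:3, mode = "stack", center = FALSE) {
  maps <- list()
  for (a in c("expression", "identity", "gender")) {
    S <- assemble_design(responses, strategy, a, runs = runs, mode = mode)
    T_feat <- feature_block(features, a)[attr(S, "stim"), , drop = FALSE]
    meta <- list(attribute = a, rois = strategy$groups[[a]], runs = runs,
                 mode = mode)
    if (center) {
      meta$S_center <- colMeans(S)
      meta$T_center <- colMeans(T_feat)
      S <- sweep(S, 2, meta$S_center)
      T_feat <- sweep(T_feat, 2, meta$T_center)
    }
    maps[[a]] <- fit_linear_map(S, T_feat, meta = meta)
  }
  maps
}

#' Predict multi-dimensional features from held-out runs
#'
#' Assembles each attribute's design from the prediction runs (averaged by
#' default), applies the fitted maps, and concatenates the blocks with the
#' strategy's constraints.
#'
#' @param responses An `roi_response_set`.
#' @param maps Output of [fit_attribute_maps()].
#' @param strategy The same [roi_group_strategy()] used at fit time.
#' @param runs Prediction run indices (default runs 4-5).
#' @param mode `"average"` (default) or `"stack"`.
#' @param condition Return generator-ready features: bounded blocks
#'   clipped to `[0, 1]` and non-constraint blocks zeroed. With `FALSE`
#'   the raw regression outputs are concatenated unchanged — the form the
#'   feature-space evaluation statistics operate on.
#' @return An [attribute_features()] object of predicted features.
#' @export
predict_attribute_features <- function(responses, maps, strategy,
                                       runs = 4:5, mode = "average",
                                       condition = TRUE) {
  pred <- list()
  for (a in c("expression", "identity", "gender")) {
    S <- assemble_design(responses, strategy, a, runs = runs, mode = mode)
    m <- maps[[a]]
    if (!is.null(m$meta$S_center)) S <- sweep(S, 2, m$meta$S_center)
    p <- predict_features(S, m)
    if (!is.null(m$meta$T_center)) p <- sweep(p, 2, m$meta$T_center, `+`)
    pred[[a]] <- p
  }
  if (!condition)
    return(attribute_features(pred$identity, pred$expression, pred$gender))
  suppressWarnings(
    assemble_multidim_features(pred$expression, pred$identity, pred$gender,
                               constraints = strategy$constraints))
}

#' Write / read a linear map as a matrix file plus JSON metadata
#'
#' @param map A `linear_map`.
#' @param path Path prefix; writes `<path>.tsv` and `<path>.json`.
#' @export
write_linear_map <- function(map, path) {
  stopifnot(inherits(map, "linear_map"))
  write.table(map$W, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(map$meta, list(rank_deficient = map$rank_deficient)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linear_map
#' @export
read_linear_map <- function(path) {
  W <- as.matrix(read.delim(paste0(path, ".tsv"), check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rd <- isTRUE(meta$rank_deficient)
  meta$rank_deficient <- NULL
  structure(list(W = W, rank_deficient = rd, meta = meta),
            class = "linear_map")
}
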