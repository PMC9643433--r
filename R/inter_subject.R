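# Cross-subject eigen-space alignment ----------------------------------------
#
# Voxel responses differ across subjects even for identical stimuli; the
# cross-subject route projects each subject's responses into a per-subject
# PCA eigen-space (default 56 components), estimates a linear transform
# between the two coordinate systems from responses to shared stimuli, and
# then pushes a test subject's coordinates through the training subject's
# regression-plus-generator stack.

#' Fit a PCA eigen-space of voxel responses
#'
#' Mean-centred PCA; coordinates are projections onto the top `k`
#' components.
#'
#' @param S Response matrix (stimuli x voxels).
#' @param k Number of components (default 56); must satisfy
#'   `k <= min(nrow - 1, ncol)`.
#' @return An `eigen_space`: list with `mean`, `basis` (voxels x k,
#'   orthonormal columns), `sdev` and `k`.
#' @export
fit_eigenspace <- function(S, k = 56L) {
  S <- as.matrix(S)
  k <- as.integer(k)
  if (k < 1 || k > min(nrow(S) - 1L, ncol(S)))
    stop_arg("`k` must be in 1..min(nrow - 1, ncol) = ",
             min(nrow(S) - 1L, ncol(S)))
  pc <- prcomp(S, center = TRUE, scale. = FALSE)
  structure(list(mean = pc$center, basis = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev[seq_len(k)], k = k),
            class = "eigen_space")
}

#' @export
print.eigen_space <- function(x, ...) {
  cat(sprintf("<eigen_space> %d voxels -> %d components\n",
              nrow(x$basis), x$k))
  invisible(x)
}

#' Project responses into (or back out of) an eigen-space
#'
#' @param space An `eigen_space`.
#' @param S Response matrix (stimuli x voxels) or, for
#'   `eigen_backproject`, a coordinate matrix (stimuli x k).
#' @return Coordinates (stimuli x k), or reconstructed responses.
#' @export
eigen_project <- function(space, S) {
  S <- as.matrix(S)
  if (ncol(S) != nrow(space$basis))
    stop_arg("voxel count does not match the eigen-space")
  sweep(S, 2, space$mean) %*% space$basis
}

#' @rdname eigen_project
#' @export
eigen_backproject <- function(space, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != space$k)
    stop_arg("coordinate dimension does not match the eigen-space")
  sweep(tcrossprod(coords, space$basis), 2, space$mean, `+`)
}

#' Fit the cross-subject coordinate transform
#'
#' Least-squares linear map `M` minimising
#' `||coords_B %*% M - coords_A||`, estimated from responses of both
#' subjects to the same stimuli (rows aligned by stimulus). When fewer
#' shared stimuli than coordinates are available the minimum-norm solution
#' is used with a warning. `method = "procrustes"` constrains `M` to an
#' orthogonal rotation (SVD solution of the orthogonal Procrustes
#' problem).
#'
#' @param coords_A,coords_B Coordinate matrices (shared stimuli x k),
#'   subject A = framework-training subject, subject B = test subject.
#' @param method `"lstsq"` (default) or `"procrustes"`.
#' @return A `cross_subject_map`: list with `M` (k_B x k_A), `method`,
#'   `residual` (Frobenius norm of the fit residual) and `n_shared`.
#' @export
fit_cross_subject_map <- function(coords_A, coords_B,
                                  method = c("lstsq", "procrustes")) {
  method <- match.arg(method)
  coords_A <- as.matrix(coords_A); coords_B <- as.matrix(coords_B)
  if (nrow(coords_A) != nrow(coords_B))
    stop_arg("coordinate matrices must be row-aligned by shared stimulus")
  if (method == "procrustes") {
    if (ncol(coords_A) != ncol(coords_B))
      stop_arg("procrustes alignment needs equal dimensions")
    sv <- svd(crossprod(coords_B, coords_A))
    M <- tcrossprod(sv$u, sv$v)
  } else {
    if (nrow(coords_B) < ncol(coords_B))
      warning("fewer shared stimuli than coordinates; minimum-norm fit")
    fit <- fit_linear_map(coords_B, coords_A)
    M <- fit$W
  }
  res <- norm(coords_B %*% M - coords_A, "F")
  structure(list(M = M, method = method, residual = res,
                 n_shared = nrow(coords_A)),
            class = "cross_subject_map")
}

#' @export
print.cross_subject_map <- function(x, ...) {
  cat(sprintf("<cross_subject_map> %dx%d (%s), %d shared stimuli, residual %.3g\n",
              nrow(x$M), ncol(x$M), x$method, x$n_shared, x$residual))
  invisible(x)
}

#' Reconstruct images from another subject's responses
#'
#' Projects the test subject's responses into their own eigen-space, maps
#' the coordinates into the training subject's eigen-space, predicts
#' attribute features with the training subject's regressions and renders
#' images with the trained generator. With `from = "eigen"` (default) the
#' regressions must have been fitted on the training subject's
#' eigen-coordinates; `from = "voxel"` back-projects into the training
#' subject's voxel space first and expects voxel-space regressions.
#'
#' @param responses_B Test-subject response matrix (stimuli x voxels).
#' @param eigen_B,eigen_A The two [fit_eigenspace()] objects.
#' @param map The [fit_cross_subject_map()] from B to A coordinates.
#' @param maps_A The training subject's attribute maps (named list of
#'   `linear_map`s over all three attributes, fitted on eigen-coordinates
#'   or voxels according to `from`).
#' @param generator A trained generator (or `NULL` to return features
#'   only).
#' @param constraints Attribute blocks kept when conditioning.
#' @param from `"eigen"` or `"voxel"` regression input space.
#' @return List with `features` (raw predicted [attribute_features()]),
#'   `features_conditioned` (clipped/constrained generator input) and
#'   `images` (reconstructions, or `NULL` without a generator).
#' @export
cross_subject_reconstruct <- function(responses_B, eigen_B, map, eigen_A,
                                      maps_A, generator = NULL,
                                      constraints = c("identity", "expression",
                                                      "gender"),
                                      from = c("eigen", "voxel")) {
  from <- match.arg(from)
  coords <- eigen_project(eigen_B, responses_B) %*% map$M
  X <- if (from == "eigen") coords else eigen_backproject(eigen_A, coords)
  pred <- lapply(c(expression = "expression", identity = "identity",
                   gender = "gender"),
                 function(a) predict_features(X, maps_A[[a]]))
  feats <- attribute_features(pred$identity, pred$expression, pred$gender)
  cond <- suppressWarnings(
    assemble_multidim_features(pred$expression, pred$identity, pred$gender,
                               constraints = constraints))
  images <- if (!is.null(generator)) reconstruct(generator, cond) else NULL
  list(features = feats, features_conditioned = cond, images = images)
}

#' Serialise an eigen-space or cross-subject map
#'
#' Matrix payloads as tab-separated files plus a JSON metadata sidecar.
#'
#' @param x An `eigen_space` or `cross_subject_map`.
#' @param path Path prefix.
#' @export
write_alignment <- function(x, path) {
  if (inherits(x, "eigen_space")) {
    write.table(x$basis, paste0(path, "_basis.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(class = "eigen_space", mean = x$mean,
                              sdev = x$sdev, k = x$k),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "cross_subject_map")) {
    write.table(x$M, paste0(path, "_M.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(class = "cross_subject_map", method = x$method,
                              residual = x$residual, n_shared = x$n_shared),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop_arg("unsupported object")
  invisible(path)
}
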