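# Simulated ROI voxel responses ---------------------------------------------
#
# Responses emulate per-stimulus GLM amplitude estimates in six face-network
# ROIs. Each ROI encodes a known subset of the attribute feature blocks
# through a fixed ground-truth weight matrix; repeated runs add i.i.d.
# Gaussian noise. ROI selectivity is realised purely by which feature-block
# rows of the true weights are nonzero, so downstream decoding selectivity
# is a recoverable ground truth.

ROI_NAMES <- c("V1", "OFA", "FFA", "aIT", "pSTS", "amygdala")

#' Default ROI attribute selectivity
#'
#' V1 and OFA respond to all attribute blocks (low-level / holistic
#' signals), FFA and aIT to identity and gender, pSTS and amygdala to
#' expression only.
#'
#' @return Named list mapping ROI name to a character vector of attribute
#'   blocks with nonzero encoding weights.
#' @export
default_roi_selectivity <- function() {
  list(V1 = c("identity", "expression", "gender"),
       OFA = c("identity", "expression", "gender"),
       FFA = c("identity", "gender"),
       aIT = c("identity", "gender"),
       pSTS = "expression",
       amygdala = "expression")
}

#' Build a ground-truth linear encoding specification
#'
#' Draws, per ROI, a true weight matrix `W_true` (total feature dimension x
#' voxels) whose rows are zero outside the ROI's selective attribute blocks.
#' Nonzero entries are Normal with SD `weight_scale / sqrt(active dims)`, so
#' each voxel's signal has roughly unit variance across stimuli.
#'
#' @param feature_dims Named integer vector
#'   `c(identity = , expression = 7, gender = 2)` (e.g. `features$dims`).
#' @param roi_names ROIs to include, subset of
#'   `c("V1","OFA","FFA","aIT","pSTS","amygdala")`.
#' @param voxels_per_roi Voxels per ROI (default 56, a 6-mm sphere's worth).
#' @param noise_sd Run-noise standard deviation (>= 0), default 1.
#' @param selectivity Named list ROI -> attribute blocks;
#'   default [default_roi_selectivity()].
#' @param weight_scale Overall encoding strength, default 1.
#' @param seed Seed for the weight draw.
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(feature_dims, roi_names = ROI_NAMES,
                          voxels_per_roi = 56L, noise_sd = 1,
                          selectivity = default_roi_selectivity(),
                          weight_scale = 1, seed = 1L) {
  if (noise_sd < 0) stop_arg("`noise_sd` must be >= 0")
  if (!all(roi_names %in% ROI_NAMES))
    stop_arg("unknown ROI name(s): ",
             paste(setdiff(roi_names, ROI_NAMES), collapse = ", "))
  d <- feature_dims
  if (is.null(names(d)) ||
      !all(c("identity", "expression", "gender") %in% names(d)))
    stop_arg("`feature_dims` must be named (identity, expression, gender)")
  d_tot <- sum(d)
  blocks <- list(identity = seq_len(d[["identity"]]),
                 expression = d[["identity"]] + seq_len(d[["expression"]]),
                 gender = d[["identity"]] + d[["expression"]] + seq_len(d[["gender"]]))
  W_true <- with_seed(seed, {
    out <- list()
    for (roi in roi_names) {
      sel <- selectivity[[roi]]
      if (is.null(sel)) stop_arg("no selectivity entry for ROI ", roi)
      active <- unlist(blocks[sel], use.names = FALSE)
      W <- matrix(0, d_tot, voxels_per_roi)
      W[active, ] <- rnorm(length(active) * voxels_per_roi,
                           sd = weight_scale / sqrt(length(active)))
      out[[roi]] <- W
    }
    out
  })
  structure(list(roi_names = roi_names, voxels_per_roi = as.integer(voxels_per_roi),
                 noise_sd = noise_sd, selectivity = selectivity[roi_names],
                 W_true = W_true, feature_dims = d, blocks = blocks,
                 weight_scale = weight_scale, seed = as.integer(seed)),
            class = "encoding_spec")
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat(sprintf("<encoding_spec> %d ROIs x %d voxels, noise_sd = %g\n",
              length(x$roi_names), x$voxels_per_roi, x$noise_sd))
  for (roi in x$roi_names)
    cat(sprintf("  %-9s <- %s\n", roi, paste(x$selectivity[[roi]], collapse = ", ")))
  invisible(x)
}

#' Simulate multi-run ROI voxel responses
#'
#' `response(run, stim, roi) = features(stim) %*% W_true(roi) + noise`,
#' with noise i.i.d. `Normal(0, noise_sd^2)` per run, stimulus and voxel.
#' All runs present the same stimuli (as in a design where every face is
#' shown once per run).
#'
#' @param features An `attribute_features` object (one row per stimulus).
#' @param spec An [encoding_spec()].
#' @param n_runs Number of runs (default 5).
#' @param seed Noise seed.
#' @param rois ROIs to simulate; must be covered by `spec`
#'   (default: all of `spec$roi_names`).
#' @return An `roi_response_set`: list with `responses` (array
#'   `n_stim x total_voxels x n_runs`, voxel columns named `"ROI_j"`),
#'   `roi_cols` (named list of column indices), `rois`, `n_runs`, `spec`,
#'   `seed`.
#' @export
simulate_roi_responses <- function(features, spec, n_runs = 5L, seed = 1L,
                                   rois = spec$roi_names) {
  stopifnot(inherits(features, "attribute_features"),
            inherits(spec, "encoding_spec"))
  missing_roi <- setdiff(rois, spec$roi_names)
  if (length(missing_roi))
    stop_arg("ROI(s) not covered by the encoding spec: ",
             paste(missing_roi, collapse = ", "))
  if (n_runs < 1) stop_arg("`n_runs` must be >= 1")
  Z <- features$z
  if (ncol(Z) != sum(spec$feature_dims))
    stop_arg("feature dimension does not match the encoding spec")

  signal <- do.call(cbind, lapply(rois, function(r) Z %*% spec$W_true[[r]]))
  vox_names <- unlist(lapply(rois, function(r)
    sprintf("%s_%d", r, seq_len(spec$voxels_per_roi))))
  n_stim <- nrow(Z); n_vox <- ncol(signal)
  responses <- with_seed(seed, {
    arr <- array(0, dim = c(n_stim, n_vox, n_runs))
    for (r in seq_len(n_runs))
      arr[, , r] <- signal +
        if (spec$noise_sd > 0)
          matrix(rnorm(n_stim * n_vox, sd = spec$noise_sd), n_stim, n_vox)
        else 0
    arr
  })
  dimnames(responses) <- list(NULL, vox_names, sprintf("run%d", seq_len(n_runs)))
  roi_cols <- split(seq_len(n_vox),
                    rep(seq_along(rois), each = spec$voxels_per_roi))
  names(roi_cols) <- rois
  structure(list(responses = responses, roi_cols = roi_cols, rois = rois,
                 n_runs = as.integer(n_runs), spec = spec,
                 seed = as.integer(seed)),
            class = "roi_response_set")
}

#' @export
print.roi_response_set <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<roi_response_set> %d stimuli x %d voxels (%s) x %d runs\n",
              d[1], d[2], paste(x$rois, collapse = ", "), d[3]))
  invisible(x)
}

#' Write / read ROI responses as per-run delimited tables
#'
#' One tab-separated file per run (`responses_run1.tsv`, ...; rows =
#' stimulus order, columns = `ROI_voxel`), plus a JSON sidecar
#' (`responses.json`) recording the ROI layout, noise SD and seed.
#'
#' @param responses An `roi_response_set`.
#' @param dir Output directory.
#' @export
write_roi_responses <- function(responses, dir) {
  stopifnot(inherits(responses, "roi_response_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_len(responses$n_runs))
    write.table(responses$responses[, , r],
                file.path(dir, sprintf("responses_run%d.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(rois = responses$rois,
               voxels_per_roi = responses$spec$voxels_per_roi,
               noise_sd = responses$spec$noise_sd,
               n_runs = responses$n_runs, seed = responses$seed)
  jsonlite::write_json(meta, file.path(dir, "responses.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_roi_responses
#' @export
read_roi_responses <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "responses.json"),
                              simplifyVector = TRUE)
  runs <- lapply(seq_len(meta$n_runs), function(r)
    as.matrix(read.delim(file.path(dir, sprintf("responses_run%d.tsv", r)),
                         check.names = FALSE)))
  responses <- array(0, dim = c(nrow(runs[[1]]), ncol(runs[[1]]), meta$n_runs))
  for (r in seq_along(runs)) responses[, , r] <- runs[[r]]
  dimnames(responses) <- list(NULL, colnames(runs[[1]]),
                              sprintf("run%d", seq_len(meta$n_runs)))
  roi_cols <- split(seq_len(ncol(runs[[1]])),
                    rep(seq_along(meta$rois), each = meta$voxels_per_roi))
  names(roi_cols) <- meta$rois
  structure(list(responses = responses, roi_cols = roi_cols, rois = meta$rois,
                 n_runs = as.integer(meta$n_runs), spec = NULL,
                 seed = meta$seed),
            class = "roi_response_set")
}
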