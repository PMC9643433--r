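# Experiment orchestration ---------------------------------------------------
#
# End-to-end experiments over synthetic subjects: stimulus generation,
# feature extraction, response simulation, regression, generation and
# evaluation, all driven by one config list and one global seed that fans
# out deterministically to the stages (see child_seed). Every experiment
# returns a manifest: the config snapshot, the seeds used, and the metric
# tables — rerunning with the same config yields identical numbers.

#' Build an experiment configuration
#'
#' Defaults describe the desk-scale study: a factorial stimulus set
#' (`n_identities` x 7 expressions), identity-level train/validation
#' split, 6 simulated ROIs x 56 voxels x 5 runs (3 training + 2
#' prediction), the proposed ROI-group strategy, label-derived features,
#' and a small conditional GAN.
#'
#' @param kind One of `"intra_seen"`, `"intra_unseen"`, `"inter_seen"`,
#'   `"ablation_gan"`, `"ablation_strategy"`, `"roi_contribution"`.
#' @param seed Global seed.
#' @param n_identities Total identities (train + validation).
#' @param n_val_identities Identities held out for validation.
#' @param image_size Square stimulus size (power of two for the GAN).
#' @param d_id Identity feature dimension.
#' @param voxels_per_roi,noise_sd,n_runs Encoding simulation settings.
#' @param train_runs,predict_runs Run split for the seen experiments.
#' @param strategy ROI-combination strategy name.
#' @param feature_source `"labels"` (ground-truth embedding features) or
#'   `"mtdln"` (train the multi-task network and extract its features).
#' @param generator `"train"` (fit a small GAN), `"none"` (feature-space
#'   evaluation only) or a pre-trained `mcgan_model`.
#' @param gan_epochs,mtdln_epochs Training budgets.
#' @param folds Cross-validation folds for the unseen experiment.
#' @param n_repeats Resampling repeats of the accuracy statistics.
#' @param subject_b For inter-subject runs: `"identical"` (B is A),
#'   `"shared"` (same encoding up to an orthogonal voxel transform) or
#'   `"independent"` (unrelated encoding).
#' @param outdir Optional output directory for artifacts.
#' @param ... Additional overrides stored in the config.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(kind = "intra_seen", seed = 1L,
                              n_identities = 26L, n_val_identities = 6L,
                              image_size = 32L, d_id = 16L,
                              voxels_per_roi = 56L, noise_sd = 1,
                              n_runs = 5L, train_runs = 1:3,
                              predict_runs = 4:5, strategy = "proposed",
                              feature_source = c("labels", "mtdln"),
                              generator = "none", gan_epochs = 10L,
                              mtdln_epochs = 10L, folds = 10L,
                              n_repeats = 40L, subject_b = "shared",
                              outdir = NULL, ...) {
  kinds <- c("intra_seen", "intra_unseen", "inter_seen", "ablation_gan",
             "ablation_strategy", "roi_contribution")
  if (!kind %in% kinds)
    stop_arg("unknown experiment kind: ", kind)
  feature_source <- match.arg(feature_source)
  cfg <- c(list(kind = kind, seed = as.integer(seed),
                n_identities = as.integer(n_identities),
                n_val_identities = as.integer(n_val_identities),
                image_size = as.integer(image_size), d_id = as.integer(d_id),
                voxels_per_roi = as.integer(voxels_per_roi),
                noise_sd = noise_sd, n_runs = as.integer(n_runs),
                train_runs = train_runs, predict_runs = predict_runs,
                strategy = strategy, feature_source = feature_source,
                generator = generator, gan_epochs = as.integer(gan_epochs),
                mtdln_epochs = as.integer(mtdln_epochs),
                folds = as.integer(folds), n_repeats = as.integer(n_repeats),
                subject_b = subject_b, outdir = outdir),
           list(...))
  structure(cfg, class = "experiment_config")
}

# stage seeds fanned out from the global seed
stage_seeds <- function(seed) {
  list(stimuli = child_seed(seed, 1), split = child_seed(seed, 2),
       features = child_seed(seed, 3), encoding = child_seed(seed, 4),
       noise = child_seed(seed, 5), mtdln = child_seed(seed, 6),
       gan = child_seed(seed, 7), eval = child_seed(seed, 8),
       noise_b = child_seed(seed, 9), transform = child_seed(seed, 10))
}

# shared setup: stimuli, split, features, validation subset
experiment_setup <- function(config) {
  seeds <- stage_seeds(config$seed)
  set <- generate_stimulus_set(config$n_identities, 7L,
                               c(config$image_size, config$image_size),
                               seed = seeds$stimuli)
  n <- nrow(set$labels)
  n_val <- config$n_val_identities * 7L
  set <- split_dataset(set, c(n - n_val, 0L, n_val), seed = seeds$split,
                       by_identity = TRUE)
  train <- subset_stimuli(set, "train")
  val <- subset_stimuli(set, "val_predict")
  if (config$feature_source == "mtdln") {
    mcfg <- mtdln_config(n_identities = length(unique(train$labels$identity_id)),
                         image_size = c(config$image_size, config$image_size),
                         epochs = config$mtdln_epochs,
                         fc_width = config$d_id)
    fit <- train_mtdln(build_mtdln(mcfg, seed = seeds$mtdln), train,
                       val_set = NULL, config = mcfg, seed = seeds$mtdln)
    feats_train <- extract_features(fit$model, train$images)
    feats_val <- extract_features(fit$model, val$images)
    mtdln_fit <- fit
  } else {
    feats_all <- label_features(set, d_id = config$d_id, seed = seeds$features)
    keep_train <- set$labels$split == "train"
    keep_val <- set$labels$split == "val_predict"
    feats_train <- attribute_features(
      feature_block(feats_all, "identity")[keep_train, , drop = FALSE],
      feature_block(feats_all, "expression")[keep_train, , drop = FALSE],
      feature_block(feats_all, "gender")[keep_train, , drop = FALSE])
    feats_val <- attribute_features(
      feature_block(feats_all, "identity")[keep_val, , drop = FALSE],
      feature_block(feats_all, "expression")[keep_val, , drop = FALSE],
      feature_block(feats_all, "gender")[keep_val, , drop = FALSE])
    mtdln_fit <- NULL
  }
  list(seeds = seeds, set = set, train = train, val = val,
       feats_train = feats_train, feats_val = feats_val,
       mtdln_fit = mtdln_fit)
}

# a generator per config: trained, supplied, or NULL
experiment_generator <- function(config, setup) {
  if (inherits(config$generator, "mcgan_model")) return(config$generator)
  if (identical(config$generator, "none")) return(NULL)
  gcfg <- mcgan_config(setup$feats_train$dims,
                       image_size = config$image_size,
                       epochs = config$gan_epochs,
                       g_channels = config$g_channels %||% 16L,
                       d_channels = config$d_channels %||% c(8L, 8L, 16L, 16L))
  train_mcgan(setup$train$images, setup$feats_train, gcfg,
              seed = setup$seeds$gan)
}

subset_responses <- function(responses, idx) {
  responses$responses <- responses$responses[idx, , , drop = FALSE]
  responses
}

evaluate_reconstruction <- function(config, recons, truths, pred_feats,
                                    true_feats, seeds) {
  results <- list()
  if (!is.null(recons))
    results$ssim_accuracy <- ssim_accuracy(recons, truths,
                                           n_repeats = config$n_repeats,
                                           seed = seeds$eval)
  for (a in c("expression", "identity", "gender"))
    results[[paste0("feature_", a)]] <- roi_reconstruction_accuracy(
      feature_block(pred_feats, a), feature_block(true_feats, a),
      n_repeats = config$n_repeats, seed = child_seed(seeds$eval, match(a, TASKS)))
  adjust_fdr(results)
}

result_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(condition = nm, mean = r$mean, sd = sd(r$accuracies),
               t = r$t, p_raw = r$p_raw, p_fdr = r$p_fdr)
  }))
}

finish_manifest <- function(config, seeds, tables, results = NULL,
                            extra = list()) {
  manifest <- c(list(config = unclass(config), seeds = seeds,
                     tables = tables,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  manifest$results <- results
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    json <- manifest
    json$results <- lapply(results, function(r)
      list(mean = r$mean, t = r$t, p_raw = r$p_raw, p_fdr = r$p_fdr))
    json$timestamp <- NULL   # manifests are compared across reruns
    jsonlite::write_json(json, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns")
  }
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s (seed %d)\n", x$config$kind, x$config$seed))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], digits = 3)
  }
  invisible(x)
}

#' Run an intra-subject reconstruction experiment
#'
#' Seen mode: the attribute regressions are trained on the validation
#' stimuli's training runs (default 3, stacked) and predict the same
#' stimuli from the held-out runs (default 2, averaged). Unseen mode:
#' cross-validation over stimuli — each fold's regressions are fitted on
#' the remaining stimuli using all runs and predict the held-out stimuli
#' (126 train / 14 test per fold at full scale). Reconstructions (when a
#' generator is available) and predicted features are scored with the
#' resampling accuracy statistics.
#'
#' @param config An [experiment_config()] of kind `"intra_seen"` or
#'   `"intra_unseen"`.
#' @return A `run_manifest`.
#' @export
run_intra_subject <- function(config) {
  setup <- experiment_setup(config)
  seeds <- setup$seeds
  spec <- encoding_spec(setup$feats_val$dims,
                        voxels_per_roi = config$voxels_per_roi,
                        noise_sd = config$noise_sd,
                        weight_scale = config$weight_scale %||% 1,
                        seed = seeds$encoding)
  responses <- simulate_roi_responses(setup$feats_val, spec,
                                      n_runs = config$n_runs,
                                      seed = seeds$noise)
  strategy <- roi_group_strategy(config$strategy)
  n_val <- nrow(setup$feats_val$z)

  if (config$kind == "intra_unseen") {
    fold_id <- with_seed(seeds$split, sample(rep_len(seq_len(config$folds), n_val)))
    pred_z <- matrix(0, n_val, ncol(setup$feats_val$z))
    for (f in seq_len(config$folds)) {
      test_idx <- which(fold_id == f)
      train_idx <- which(fold_id != f)
      feats_tr <- attribute_features(
        feature_block(setup$feats_val, "identity")[train_idx, , drop = FALSE],
        feature_block(setup$feats_val, "expression")[train_idx, , drop = FALSE],
        feature_block(setup$feats_val, "gender")[train_idx, , drop = FALSE])
      maps <- fit_attribute_maps(subset_responses(responses, train_idx),
                                 feats_tr, strategy,
                                 runs = seq_len(config$n_runs), mode = "stack")
      pf <- predict_attribute_features(subset_responses(responses, test_idx),
                                       maps, strategy,
                                       runs = seq_len(config$n_runs),
                                       mode = "average", condition = FALSE)
      pred_z[test_idx, ] <- pf$z
    }
    d <- setup$feats_val$dims
    pred <- attribute_features(pred_z[, seq_len(d[1]), drop = FALSE],
                               pred_z[, d[1] + seq_len(d[2]), drop = FALSE],
                               pred_z[, d[1] + d[2] + seq_len(d[3]), drop = FALSE])
  } else {
    maps <- fit_attribute_maps(responses, setup$feats_val, strategy,
                               runs = config$train_runs, mode = "stack")
    pred <- predict_attribute_features(responses, maps, strategy,
                                       runs = config$predict_runs,
                                       mode = "average", condition = FALSE)
  }

  gen <- experiment_generator(config, setup)
  recons <- if (!is.null(gen)) {
    cond <- suppressWarnings(assemble_multidim_features(
      feature_block(pred, "expression"), feature_block(pred, "identity"),
      feature_block(pred, "gender"), constraints = strategy$constraints))
    reconstruct(gen, cond)
  } else NULL
  results <- evaluate_reconstruction(config, recons, setup$val$images, pred,
                                     setup$feats_val, seeds)
  tables <- list(accuracy = result_table(results))
  if (!is.null(recons))
    tables$per_image <- image_metrics(recons, setup$val$images)
  if (!is.null(config$outdir) && !is.null(recons)) {
    rs <- setup$val; rs$images <- recons
    write_stimulus_set(rs, file.path(config$outdir, "reconstructions"))
  }
  finish_manifest(config, seeds, tables, results,
                  extra = list(pred_features = pred))
}

#' Run the ablation sweeps
#'
#' `kind = "ablation_gan"`: trains the four GAN modes on the training
#' stimuli (same seed and data) and tabulates reconstruction MSE / SSIM /
#' PSNR, optionally adding the white-noise-input control scored by a
#' nearest-centroid attribute classifier. `kind = "ablation_strategy"`:
#' runs the full regression chain per ROI/constraint strategy and reports
#' paired t-tests (per-image SSIM when a generator is available, otherwise
#' per-image feature distance) of the proposed strategy against the
#' others.
#'
#' @param config An [experiment_config()].
#' @param white_noise Include the white-noise-latent control
#'   (`ablation_gan` only).
#' @param strategies Strategy names for the strategy sweep.
#' @return A `run_manifest`.
#' @export
run_ablation_suite <- function(config, white_noise = TRUE,
                               strategies = c("strategy1", "strategy2",
                                              "strategy3", "strategy4",
                                              "strategy5", "proposed")) {
  setup <- experiment_setup(config)
  seeds <- setup$seeds
  if (config$kind == "ablation_gan") {
    gcfg <- mcgan_config(setup$feats_train$dims,
                         image_size = config$image_size,
                         epochs = config$gan_epochs,
                         g_channels = config$g_channels %||% 16L,
                         d_channels = config$d_channels %||% c(8L, 8L, 16L, 16L))
    sweep <- sweep_gan_modes(setup$train$images, setup$feats_train, gcfg,
                             seed = seeds$gan)
    tables <- list(gan_modes = sweep$table)
    extra <- list(models = sweep$models)
    if (white_noise) {
      wn <- white_noise_features(dim(setup$train$images)[3],
                                 setup$feats_train$dims, seed = seeds$eval)
      rec_wn <- reconstruct(sweep$models$mcgan, wn)
      acc <- vapply(c("expression", "gender"), function(task)
        nearest_centroid_accuracy(setup$train$images,
                                  setup$train$labels[[paste0(task, "_id")]],
                                  rec_wn,
                                  setup$train$labels[[paste0(task, "_id")]]),
        numeric(1))
      tables$white_noise <- data.frame(task = names(acc),
                                       accuracy = unname(acc),
                                       chance = c(1 / 7, 1 / 2))
    }
    return(finish_manifest(config, seeds, tables, extra = extra))
  }

  # strategy sweep
  spec <- encoding_spec(setup$feats_val$dims,
                        voxels_per_roi = config$voxels_per_roi,
                        noise_sd = config$noise_sd,
                        weight_scale = config$weight_scale %||% 1,
                        seed = seeds$encoding)
  responses <- simulate_roi_responses(setup$feats_val, spec,
                                      n_runs = config$n_runs,
                                      seed = seeds$noise)
  gen <- experiment_generator(config, setup)
  per_image <- list()
  rows <- list()
  for (s in strategies) {
    strat <- roi_group_strategy(s)
    maps <- fit_attribute_maps(responses, setup$feats_val, strat,
                               runs = config$train_runs, mode = "stack")
    pred <- predict_attribute_features(responses, maps, strat,
                                       runs = config$predict_runs,
                                       mode = "average")
    if (!is.null(gen)) {
      rec <- reconstruct(gen, pred)
      m <- image_metrics(rec, setup$val$images)
      per_image[[s]] <- m$ssim
      rows[[s]] <- data.frame(strategy = s, metric = "ssim",
                              mean = mean(m$ssim), sd = sd(m$ssim))
    } else {
      dist <- sqrt(rowSums((pred$z - setup$feats_val$z)^2))
      per_image[[s]] <- -dist    # higher = better, like SSIM
      rows[[s]] <- data.frame(strategy = s, metric = "neg_feature_distance",
                              mean = mean(-dist), sd = sd(dist))
    }
  }
  cmp <- list()
  for (s in setdiff(names(per_image), "proposed")) {
    tt <- t.test(per_image$proposed, per_image[[s]], paired = TRUE)
    cmp[[s]] <- data.frame(comparison = paste0("proposed_vs_", s),
                           mean_diff = unname(tt$estimate),
                           t = unname(tt$statistic), p = tt$p.value)
  }
  tables <- list(strategies = do.call(rbind, c(rows, make.row.names = FALSE)),
                 paired_tests = do.call(rbind, c(cmp, make.row.names = FALSE)))
  finish_manifest(config, seeds, tables)
}

#' Nearest-centroid image classifier accuracy
#'
#' Trains per-class pixel centroids on labelled images and reports the
#' accuracy of nearest-centroid assignment on the test images — the
#' held-out attribute-recognisability check used for the white-noise
#' control.
#'
#' @param train_images,test_images Arrays `H x W x n`.
#' @param train_labels,test_labels Integer class labels.
#' @return Accuracy in `[0, 1]`.
#' @export
nearest_centroid_accuracy <- function(train_images, train_labels,
                                      test_images, test_labels) {
  X <- matrix(as.numeric(train_images), ncol = dim(train_images)[3])
  Y <- matrix(as.numeric(test_images), ncol = dim(test_images)[3])
  classes <- sort(unique(train_labels))
  cent <- vapply(classes, function(cl)
    rowMeans(X[, train_labels == cl, drop = FALSE]), numeric(nrow(X)))
  d2 <- outer(colSums(Y^2), colSums(cent^2), `+`) - 2 * crossprod(Y, cent)
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == test_labels)
}

#' Per-ROI decoding-contribution analysis
#'
#' For every ROI x attribute pair, fits the linear regression from that
#' single ROI's training-run responses to the attribute's features,
#' predicts the held-out runs, and scores the resampled reconstruction
#' accuracy (40 repeats, t-test vs 50%, BH correction across the 18
#' conditions).
#'
#' @param config An [experiment_config()] (kind `"roi_contribution"`).
#' @return A `run_manifest`; `tables$roi_contribution` has one row per
#'   ROI x attribute.
#' @export
run_roi_contribution <- function(config) {
  setup <- experiment_setup(config)
  seeds <- setup$seeds
  spec <- encoding_spec(setup$feats_val$dims,
                        voxels_per_roi = config$voxels_per_roi,
                        noise_sd = config$noise_sd,
                        weight_scale = config$weight_scale %||% 1,
                        seed = seeds$encoding)
  responses <- simulate_roi_responses(setup$feats_val, spec,
                                      n_runs = config$n_runs,
                                      seed = seeds$noise)
  results <- list()
  for (roi in responses$rois) {
    strat <- list(groups = list(expression = roi, identity = roi,
                                gender = roi))
    for (a in c("expression", "identity", "gender")) {
      S_tr <- assemble_design(responses, strat, a, runs = config$train_runs,
                              mode = "stack")
      T_tr <- feature_block(setup$feats_val, a)[attr(S_tr, "stim"), ,
                                                drop = FALSE]
      map <- fit_linear_map(S_tr, T_tr)
      S_te <- assemble_design(responses, strat, a, runs = config$predict_runs,
                              mode = "average")
      pred <- predict_features(S_te, map)
      results[[paste(roi, a, sep = ".")]] <- roi_reconstruction_accuracy(
        pred, feature_block(setup$feats_val, a),
        n_repeats = config$n_repeats,
        seed = child_seed(seeds$eval, match(roi, ROI_NAMES) * 10 +
                            match(a, TASKS)))
    }
  }
  results <- adjust_fdr(results)
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    r <- results[[nm]]
    data.frame(roi = parts[1], attribute = parts[2], mean = r$mean,
               t = r$t, p_raw = r$p_raw, p_fdr = r$p_fdr)
  }))
  finish_manifest(config, seeds, list(roi_contribution = tab), results)
}

#' Run an inter-subject reconstruction experiment
#'
#' Simulates a second subject (`config$subject_b`): `"identical"` reuses
#' subject A's responses, `"shared"` applies a fixed random orthogonal
#' voxel transform to A's signal (same encoding, different voxel basis,
#' fresh noise) and `"independent"` draws an unrelated encoding. Both
#' subjects' training-run averages span 56-dimensional PCA eigen-spaces;
#' a least-squares transform maps B's coordinates into A's; A's
#' regressions (fitted on A's eigen-coordinates) and generator then
#' reconstruct from B's held-out runs.
#'
#' @param config An [experiment_config()] of kind `"inter_seen"`.
#' @return A `run_manifest`.
#' @export
run_inter_subject <- function(config) {
  setup <- experiment_setup(config)
  seeds <- setup$seeds
  spec_A <- encoding_spec(setup$feats_val$dims,
                          voxels_per_roi = config$voxels_per_roi,
                          noise_sd = config$noise_sd,
                        weight_scale = config$weight_scale %||% 1,
                        seed = seeds$encoding)
  resp_A <- simulate_roi_responses(setup$feats_val, spec_A,
                                   n_runs = config$n_runs, seed = seeds$noise)
  n_vox <- dim(resp_A$responses)[2]
  resp_B <- switch(config$subject_b,
    identical = resp_A,
    shared = {
      Q <- with_seed(seeds$transform, qr.Q(qr(matrix(rnorm(n_vox^2), n_vox))))
      signal <- setup$feats_val$z %*% do.call(cbind, spec_A$W_true[resp_A$rois])
      r <- resp_A
      with_seed(seeds$noise_b, {
        for (k in seq_len(config$n_runs))
          r$responses[, , k] <- signal %*% Q +
            matrix(rnorm(length(signal), sd = config$noise_sd),
                   nrow(signal), ncol(signal))
      })
      r
    },
    independent = {
      # a subject whose responses carry no stimulus information at all:
      # zero encoding weights, noise only (the cross-subject null)
      spec_B <- encoding_spec(setup$feats_val$dims,
                              voxels_per_roi = config$voxels_per_roi,
                              noise_sd = max(config$noise_sd, 1),
                              weight_scale = 0, seed = seeds$transform)
      simulate_roi_responses(setup$feats_val, spec_B,
                             n_runs = config$n_runs, seed = seeds$noise_b)
    },
    stop_arg("unknown subject_b mode: ", config$subject_b))

  k <- min(56L, nrow(setup$feats_val$z) - 1L, n_vox)
  avg <- function(resp, runs) apply(resp$responses[, , runs, drop = FALSE],
                                    c(1, 2), mean)
  SA_train <- avg(resp_A, config$train_runs)
  SB_train <- avg(resp_B, config$train_runs)
  eigen_A <- fit_eigenspace(SA_train, k = k)
  eigen_B <- fit_eigenspace(SB_train, k = k)
  coords_A <- eigen_project(eigen_A, SA_train)
  coords_B <- eigen_project(eigen_B, SB_train)
  map <- fit_cross_subject_map(coords_A, coords_B)
  maps_A <- lapply(c(expression = "expression", identity = "identity",
                     gender = "gender"), function(a)
    fit_linear_map(coords_A, feature_block(setup$feats_val, a),
                   meta = list(attribute = a, space = "eigen")))
  gen <- experiment_generator(config, setup)
  out <- cross_subject_reconstruct(avg(resp_B, config$predict_runs),
                                   eigen_B, map, eigen_A, maps_A,
                                   generator = gen)
  results <- evaluate_reconstruction(config, out$images, setup$val$images,
                                     out$features, setup$feats_val, seeds)
  finish_manifest(config, seeds, list(accuracy = result_table(results)),
                  results, extra = list(pred_features = out$features,
                                        map = map))
}
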