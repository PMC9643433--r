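# Objective evaluation -------------------------------------------------------
#
# Per-image quality metrics on the 0-255 pixel scale: mean squared error,
# peak signal-to-noise ratio with MAX = 255, and the structural similarity
# index computed from global image statistics (a single window spanning
# the whole image). On top of the raw metrics sit two resampled
# two-alternative statistics with one-sample t-tests against chance:
# "SSIM accuracy" in image space and "reconstruction accuracy" in
# attribute-feature space (the per-ROI contribution statistic).

#' Mean squared pixel error
#'
#' `mean((x - y)^2)` over all pixels, on the 0-255 scale.
#'
#' @param x,y Images (matrices or arrays) of identical shape.
#' @return Nonnegative scalar.
#' @export
mse <- function(x, y) {
  check_same_shape(x, y)
  mean((as.numeric(x) - as.numeric(y))^2)
}

check_same_shape <- function(x, y) {
  dx <- dim(x) %||% length(x); dy <- dim(y) %||% length(y)
  if (!identical(dx, dy))
    stop_arg("images have different shapes (", paste(dx, collapse = "x"),
             " vs ", paste(dy, collapse = "x"), ")")
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` in dB. Identical images (MSE = 0) return
#' `Inf` with a warning.
#'
#' @param x,y Images of identical shape.
#' @param max_value Peak pixel value MAX (default 255).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, max_value = 255) {
  m <- mse(x, y)
  if (m == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(max_value^2 / m)
}

#' Structural similarity index (global statistics)
#'
#' `SSIM = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` computed from the
#' means, variances and covariance of the whole image (one global window).
#' Defaults use the standard constants `C1 = (0.01*255)^2`,
#' `C2 = (0.03*255)^2`. Equals 1 iff the images are identical. A
#' mean-windowed variant is available via `window`.
#'
#' @param x,y Images of identical shape, 0-255 scale.
#' @param C1,C2 Stabilising constants.
#' @param window `NULL` (global, the default) or an odd integer: side of a
#'   sliding square window whose per-window SSIM values are averaged.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(x, y, C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2,
                 window = NULL) {
  check_same_shape(x, y)
  if (!is.null(window))
    return(ssim_windowed(x, y, window = window, C1 = C1, C2 = C2))
  ssim_stat(as.numeric(x), as.numeric(y), C1, C2)
}

# SSIM from flat pixel vectors; population (1/n) variance convention
ssim_stat <- function(x, y, C1, C2) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' @rdname ssim
#' @param step Window stride for the windowed variant.
#' @export
ssim_windowed <- function(x, y, window = 7L, step = 1L,
                          C1 = (0.01 * 255)^2, C2 = (0.03 * 255)^2) {
  check_same_shape(x, y)
  x <- as.matrix(x); y <- as.matrix(y)
  H <- nrow(x); W <- ncol(x)
  if (window > min(H, W)) stop_arg("window larger than the image")
  rs <- seq(1L, H - window + 1L, by = step)
  cs <- seq(1L, W - window + 1L, by = step)
  vals <- vapply(rs, function(r) mean(vapply(cs, function(cc) {
    xi <- x[r:(r + window - 1L), cc:(cc + window - 1L)]
    yi <- y[r:(r + window - 1L), cc:(cc + window - 1L)]
    ssim_stat(as.numeric(xi), as.numeric(yi), C1, C2)
  }, numeric(1))), numeric(1))
  mean(vals)
}

#' Per-image metrics for aligned image stacks
#'
#' @param recons,truths Arrays `H x W x n` of reconstructed and
#'   ground-truth images (0-255).
#' @return A data.frame with columns `mse`, `psnr`, `ssim` (one row per
#'   image).
#' @export
image_metrics <- function(recons, truths) {
  check_same_shape(recons, truths)
  n <- dim(recons)[3]
  out <- data.frame(mse = numeric(n), psnr = numeric(n), ssim = numeric(n))
  for (i in seq_len(n)) {
    out$mse[i] <- mse(recons[, , i], truths[, , i])
    out$psnr[i] <- if (out$mse[i] == 0) Inf else
      10 * log10(255^2 / out$mse[i])
    out$ssim[i] <- ssim(recons[, , i], truths[, , i])
  }
  out
}

#' One-sample t-test against a chance level
#'
#' @param values Numeric vector (>= 2 values).
#' @param null_value The chance level tested against.
#' @return List with `t`, `p_raw`, `mean`, `df`. Constant values equal to
#'   the null give `t = 0, p = 1`.
#' @export
test_against_null <- function(values, null_value) {
  if (length(values) < 2) stop_arg("need at least 2 values for a t-test")
  if (sd(values) == 0) {
    t_stat <- if (values[1] == null_value) 0 else sign(values[1] - null_value) * Inf
    p <- if (t_stat == 0) 1 else 0
    return(list(t = t_stat, p_raw = p, mean = mean(values),
                df = length(values) - 1L))
  }
  tt <- t.test(values, mu = null_value)
  list(t = unname(tt$statistic), p_raw = tt$p.value, mean = mean(values),
       df = unname(tt$parameter))
}

#' Benjamini-Hochberg adjustment across a batch of resampling results
#'
#' @param results List of `resampling_result` objects (or any lists with a
#'   `p_raw` entry); each gains a `p_fdr` entry.
#' @return The list with `p_fdr` filled in.
#' @export
adjust_fdr <- function(results) {
  p <- vapply(results, `[[`, numeric(1), "p_raw")
  padj <- p.adjust(p, method = "BH")
  for (i in seq_along(results)) results[[i]]$p_fdr <- padj[i]
  results
}

new_resampling_result <- function(accuracies, null_value, scale = 1) {
  tt <- test_against_null(accuracies, null_value)
  structure(list(accuracies = accuracies, mean = mean(accuracies),
                 null_value = null_value, t = tt$t, p_raw = tt$p_raw,
                 p_fdr = NA_real_, n_repeats = length(accuracies),
                 scale = scale),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("<resampling_result> mean %.3f (chance %.3f), %d repeats, t = %.2f, p = %.3g%s\n",
              x$mean, x$null_value, x$n_repeats, x$t, x$p_raw,
              if (!is.na(x$p_fdr)) sprintf(" (FDR %.3g)", x$p_fdr) else ""))
  invisible(x)
}

#' Resampled SSIM accuracy of a reconstruction set
#'
#' For each reconstructed image, SSIM1 is its similarity to the ground
#' truth and SSIM2 its similarity to a distractor drawn uniformly from the
#' pool excluding the ground truth; the image scores 1 when
#' SSIM1 > SSIM2 (ties count as failure). One repeat's accuracy is the
#' mean over all images; the procedure is repeated `n_repeats` times with
#' fresh distractors (repeat r uses `seed + r`) and summarised by a
#' one-sample t-test against 0.5.
#'
#' @param recons,truths Aligned arrays `H x W x n` (0-255).
#' @param distractor_pool Array of candidate distractor images (default:
#'   the truths themselves). Needs >= 2 images.
#' @param n_repeats Number of resampling repeats (default 40).
#' @param seed Base seed.
#' @return A `resampling_result` with the 40 accuracy values, their mean,
#'   `t`, `p_raw` and (after [adjust_fdr()]) `p_fdr`.
#' @export
ssim_accuracy <- function(recons, truths, distractor_pool = truths,
                          n_repeats = 40L, seed = 1L) {
  check_same_shape(recons, truths)
  n <- dim(recons)[3]
  n_pool <- dim(distractor_pool)[3]
  if (is.na(n_pool) || n_pool < 2)
    stop_arg("distractor pool must contain at least 2 images")
  # match truths to pool entries so the drawn distractor is never the truth
  truth_in_pool <- match_images(truths, distractor_pool)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  npix <- prod(dim(recons)[1:2])
  R <- matrix(as.numeric(recons), npix, n)
  Tm <- matrix(as.numeric(truths), npix, n)
  P <- matrix(as.numeric(distractor_pool), npix, n_pool)
  mR <- colMeans(R); mT <- colMeans(Tm); mP <- colMeans(P)
  Rc <- sweep(R, 2, mR); Tc <- sweep(Tm, 2, mT); Pc <- sweep(P, 2, mP)
  vR <- colMeans(Rc^2); vT <- colMeans(Tc^2); vP <- colMeans(Pc^2)
  ssim1 <- ((2 * mR * mT + C1) * (2 * colMeans(Rc * Tc) + C2)) /
    ((mR^2 + mT^2 + C1) * (vR + vT + C2))
  cross <- crossprod(Rc, Pc) / npix                  # n x n_pool covariances
  ssim_pool <- ((2 * outer(mR, mP) + C1) * (2 * cross + C2)) /
    ((outer(mR^2, mP^2, `+`) + C1) * (outer(vR, vP, `+`) + C2))
  acc <- vapply(seq_len(n_repeats), function(r) {
    with_seed(child_seed(seed, r), {
      hits <- vapply(seq_len(n), function(i) {
        cand <- setdiff(seq_len(n_pool), truth_in_pool[i])
        j <- if (length(cand) == 1) cand else sample(cand, 1L)
        as.numeric(ssim1[i] > ssim_pool[i, j])
      }, numeric(1))
      mean(hits)
    })
  }, numeric(1))
  new_resampling_result(acc, 0.5)
}

# index of each truth image inside the pool (0 when absent)
match_images <- function(truths, pool) {
  n <- dim(truths)[3]
  vapply(seq_len(n), function(i) {
    for (j in seq_len(dim(pool)[3]))
      if (identical(as.vector(truths[, , i]), as.vector(pool[, , j])))
        return(j)
    0L
  }, integer(1))
}

#' Resampled reconstruction accuracy in feature space
#'
#' The per-ROI contribution statistic: each test image's predicted
#' attribute features are compared, by Euclidean distance, with its own
#' true features and with a randomly drawn distractor image's true
#' features; the image counts as recognisable when the own-distance is
#' smaller. Accuracy per repeat is the fraction of recognisable images;
#' `n_repeats` repeats with fresh distractors are summarised by a
#' one-sample t-test against 50%.
#'
#' @param predicted,truth Aligned feature matrices (rows = test images).
#' @param n_repeats Number of repeats (default 40).
#' @param seed Base seed (repeat r derives its own stream).
#' @return A `resampling_result` on the percent scale (chance 50).
#' @details Distractors are drawn uniformly among test images whose true
#'   feature vectors differ from the test image's own — the feature-space
#'   analogue of excluding the ground-truth image from the SSIM distractor
#'   pool. With categorical feature blocks several images can share one
#'   true vector; such images are no foil at all, and counting their
#'   inevitable distance ties as failures would push an uninformative
#'   predictor systematically below the 50% chance level.
#' @export
roi_reconstruction_accuracy <- function(predicted, truth, n_repeats = 40L,
                                        seed = 1L) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (nrow(predicted) != nrow(truth) || ncol(predicted) != ncol(truth))
    stop_arg("predicted and truth features must be aligned matrices")
  n <- nrow(predicted)
  if (n < 2) stop_arg("need at least 2 test images")
  # pairwise distances predicted_i -> truth_j
  pn <- rowSums(predicted^2); tn <- rowSums(truth^2)
  D2 <- outer(pn, tn, `+`) - 2 * tcrossprod(predicted, truth)
  own <- diag(D2)
  # truth-duplicate structure: D2_tt == 0 marks identical true features
  D2_tt <- outer(tn, tn, `+`) - 2 * tcrossprod(truth)
  tol <- 1e-9 * (1 + max(abs(tn)))
  candidates <- lapply(seq_len(n), function(i)
    which(D2_tt[i, ] > tol & seq_len(n) != i))
  if (any(lengths(candidates) == 0))
    stop_arg("some test images have no distinct-feature distractor")
  acc <- vapply(seq_len(n_repeats), function(r) {
    with_seed(child_seed(seed, r), {
      hits <- vapply(seq_len(n), function(i) {
        cand <- candidates[[i]]
        j <- if (length(cand) == 1) cand else sample(cand, 1L)
        as.numeric(own[i] < D2[i, j])
      }, numeric(1))
      mean(hits)
    })
  }, numeric(1))
  new_resampling_result(acc * 100, 50, scale = 100)
}

#' Write an evaluation report
#'
#' Per-image metrics as a tab-separated table and the resampling summaries
#' as JSON (mean, SD, t, p values per condition).
#'
#' @param metrics Per-image metric data.frame from [image_metrics()].
#' @param results Named list of `resampling_result`s.
#' @param dir Output directory.
#' @export
write_evaluation_report <- function(metrics, results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(metrics, file.path(dir, "per_image_metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- lapply(results, function(r)
    list(mean = r$mean, sd = sd(r$accuracies), n_repeats = r$n_repeats,
         t = r$t, p_raw = r$p_raw, p_fdr = r$p_fdr))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
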