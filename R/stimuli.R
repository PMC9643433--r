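# Synthetic face-like stimuli ------------------------------------------------
#
# The stimulus generator produces a factorial identity x expression x gender
# set of grayscale glyph "faces". Identity controls stable geometry (outline
# radii, eye spacing/height/size, nose length) drawn once per identity from a
# seeded Normal; expression controls mouth curvature and eyebrow angle in 7
# discrete, equally spaced settings; gender controls jaw width and the
# presence of a dark hair band. The factorial structure mirrors a multi-label
# face dataset (many identities, each photographed under the same 7 basic
# expressions, with a binary gender label per identity).

EXPRESSION_NAMES <- c("fear", "anger", "disgust", "happiness", "neutral",
                      "sadness", "surprise")

#' Generate a synthetic attribute-labelled face stimulus set
#'
#' Renders `n_identities * n_expressions` grayscale glyph faces with a known
#' factorial attribute structure. Pixel values are 8-bit integers in
#' \[0, 255\]; every image is a pure function of `(arguments, seed)`.
#'
#' @param n_identities Number of distinct identities (>= 1).
#' @param n_expressions Number of expression categories rendered, the first
#'   `n_expressions` of the 7 basic expressions (fear, anger, disgust,
#'   happiness, neutral, sadness, surprise). Default 7.
#' @param image_size `c(height, width)` in pixels, each >= 16. Default 64x64.
#' @param seed Integer seed controlling identity geometry (and gender
#'   assignment when `gender = NULL`).
#' @param gender Optional integer vector (0/1) of length `n_identities`
#'   overriding the default deterministic gender assignment (identity index
#'   parity).
#' @param identity_sd Standard deviation of the identity shape parameters.
#' @return An object of class `face_stimulus_set`: list with `images`
#'   (array `height x width x n`, integer 0-255), `labels` (data.frame with
#'   `stim`, `identity_id`, `expression_id`, `gender_id`, `split`),
#'   `image_size`, `seed`, and the identity parameter matrix `identity_params`.
#' @examples
#' set <- generate_stimulus_set(4, image_size = c(32, 32), seed = 1)
#' dim(set$images)   # 32 32 28
#' @export
generate_stimulus_set <- function(n_identities, n_expressions = 7L,
                                  image_size = c(64L, 64L), seed = 1L,
                                  gender = NULL, identity_sd = 1) {
  if (length(n_identities) != 1 || is.na(n_identities) || n_identities < 1)
    stop_arg("`n_identities` must be a positive integer")
  if (length(n_expressions) != 1 || n_expressions < 1 || n_expressions > 7)
    stop_arg("`n_expressions` must be in 1..7")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 16))
    stop_arg("`image_size` must be two integers >= 16")
  n_identities <- as.integer(n_identities)
  n_expressions <- as.integer(n_expressions)

  if (is.null(gender)) {
    gender <- (seq_len(n_identities) - 1L) %% 2L
  } else {
    gender <- as.integer(gender)
    if (length(gender) != n_identities || !all(gender %in% c(0L, 1L)))
      stop_arg("`gender` must be a 0/1 vector of length `n_identities`")
  }

  # 6 continuous shape parameters per identity
  P <- with_seed(seed, matrix(rnorm(n_identities * 6, sd = identity_sd),
                              nrow = n_identities))
  colnames(P) <- c("face_w", "face_h", "eye_dx", "eye_y", "eye_r", "nose_len")

  n <- n_identities * n_expressions
  H <- image_size[1]; W <- image_size[2]
  images <- array(0L, dim = c(H, W, n))
  labels <- data.frame(
    stim = seq_len(n),
    identity_id = rep(seq_len(n_identities) - 1L, each = n_expressions),
    expression_id = rep(seq_len(n_expressions) - 1L, times = n_identities),
    gender_id = rep(gender, each = n_expressions),
    split = NA_character_,
    stringsAsFactors = FALSE
  )
  k <- 1L
  for (i in seq_len(n_identities)) {
    for (e in seq_len(n_expressions) - 1L) {
      images[, , k] <- render_face_glyph(P[i, ], e, gender[i], H, W)
      k <- k + 1L
    }
  }
  structure(list(images = images, labels = labels,
                 image_size = image_size, seed = as.integer(seed),
                 identity_params = P,
                 expression_names = EXPRESSION_NAMES[seq_len(n_expressions)]),
            class = "face_stimulus_set")
}

# Render one glyph face. par: named 6-vector of identity shape parameters
# (unit Normal scale); expr: 0..6; gen: 0/1. Deterministic.
render_face_glyph <- function(par, expr, gen, H, W) {
  squash <- function(z) tanh(z / 2)          # (-1, 1), tame outliers
  xs <- seq(-1, 1, length.out = W)
  ys <- seq(-1, 1, length.out = H)
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)                      # row = y (top = -1)

  jaw <- if (gen == 1L) 0.78 else 0.95
  a <- (0.62 + 0.12 * squash(par["face_w"])) * jaw   # half-width
  b <- 0.78 + 0.10 * squash(par["face_h"])           # half-height
  edx <- 0.28 + 0.10 * squash(par["eye_dx"])         # eye half-spacing
  ey <- -0.28 + 0.10 * squash(par["eye_y"])          # eye vertical pos
  er <- 0.075 + 0.03 * squash(par["eye_r"])          # eye radius
  nlen <- 0.30 + 0.12 * squash(par["nose_len"])      # nose length

  # expression: 7 equally spaced levels in [-1, 1]; amplitudes are chosen
  # so adjacent levels stay distinguishable down to the 16 px minimum size
  lev <- if (expr %in% 0:6) -1 + expr * (2 / 6) else 0
  curv <- 0.5 * lev                                   # mouth curvature
  brow <- 0.4 * lev                                   # eyebrow slope

  img <- matrix(0.88, H, W)                           # light background

  ellipse <- (X / a)^2 + (Y / b)^2
  img[abs(ellipse - 1) < 0.12] <- 0.25                # outline
  img[ellipse > 1 + 0.12] <- 0.97                     # outside is near-white

  for (sgn in c(-1, 1)) {
    eye <- (X - sgn * edx)^2 + (Y - ey)^2 < er^2
    img[eye] <- 0.1
    # eyebrow: slanted bar above the eye; slope sign mirrors across the face
    bx <- X - sgn * edx
    brow_y <- ey - 2.2 * er + sgn * brow * bx
    bar <- abs(Y - brow_y) < 0.035 & abs(bx) < 1.7 * er & ellipse < 1
    img[bar] <- 0.15
  }

  # nose: vertical stroke from eye level downward
  nose <- abs(X) < 0.03 & Y > ey + er & Y < ey + er + nlen
  img[nose] <- 0.3

  # mouth: parabolic arc, curvature encodes expression level
  my <- 0.45
  mw <- 0.30
  arc <- abs(Y - (my - curv * ((X / mw)^2 - 0.5))) < 0.05 & abs(X) < mw
  img[arc] <- 0.12

  # gender glyph: dark hair band across the top of the face for gen == 1
  if (gen == 1L) {
    band <- ellipse < 1.1 & Y < -b + 0.28
    img[band] <- 0.05
  }

  matrix(as.integer(round(clip(img, 0, 1) * 255)), H, W)
}

#' @export
print.face_stimulus_set <- function(x, ...) {
  n <- dim(x$images)[3]
  cat(sprintf(
    "<face_stimulus_set> %d stimuli (%d identities x %d expressions), %dx%d px\n",
    n, length(unique(x$labels$identity_id)),
    length(unique(x$labels$expression_id)),
    x$image_size[1], x$image_size[2]))
  if (!all(is.na(x$labels$split)))
    print(table(x$labels$split))
  invisible(x)
}

#' Assign train / validation splits to a stimulus set
#'
#' Partitions the stimuli into `train`, `val_fit` (used to fit the linear
#' brain-to-feature regression) and `val_predict` (held out for prediction)
#' splits with exactly the requested counts. With `by_identity = TRUE`
#' whole identities are assigned to a split, so validation identities never
#' occur in training — the precondition of the open-set identity protocol.
#'
#' @param set A `face_stimulus_set`.
#' @param counts Integer vector `c(train, val_fit, val_predict)` summing to
#'   the number of stimuli.
#' @param seed Integer seed for the random assignment.
#' @param by_identity Split at the identity level (counts must then be
#'   multiples of the images-per-identity count). Default `FALSE`.
#' @return The set with its `labels$split` column filled in.
#' @export
split_dataset <- function(set, counts, seed = 1L, by_identity = FALSE) {
  stopifnot(inherits(set, "face_stimulus_set"))
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 0))
    stop_arg("`counts` must be three nonnegative integers (train, val_fit, val_predict)")
  n <- nrow(set$labels)
  if (sum(counts) != n)
    stop_arg(sprintf("`counts` must sum to the set size (%d), got %d", n, sum(counts)))
  if (sum(counts[2:3]) == 0)
    warning("empty validation splits: all stimuli assigned to training")

  splits <- c("train", "val_fit", "val_predict")
  if (by_identity) {
    ids <- unique(set$labels$identity_id)
    per_id <- n / length(ids)
    if (any(counts %% per_id != 0))
      stop_arg("`by_identity = TRUE` requires counts divisible by images per identity")
    id_counts <- counts %/% per_id
    perm <- with_seed(seed, sample(ids))
    id_split <- rep(splits, id_counts)
    names(id_split) <- perm
    set$labels$split <- unname(id_split[as.character(set$labels$identity_id)])
  } else {
    perm <- with_seed(seed, sample.int(n))
    lab <- rep(splits, counts)
    set$labels$split <- lab[order(perm)]
  }
  set
}

#' Subset a stimulus set by split tag (or arbitrary index)
#'
#' @param set A `face_stimulus_set`.
#' @param split One of `"train"`, `"val_fit"`, `"val_predict"`, or `NULL`.
#' @param index Optional integer index of stimuli (applied after `split`).
#' @return A `face_stimulus_set` containing the selected stimuli.
#' @export
subset_stimuli <- function(set, split = NULL, index = NULL) {
  stopifnot(inherits(set, "face_stimulus_set"))
  keep <- seq_len(nrow(set$labels))
  if (!is.null(split)) keep <- keep[set$labels$split[keep] %in% split]
  if (!is.null(index)) keep <- keep[index]
  set$images <- set$images[, , keep, drop = FALSE]
  set$labels <- set$labels[keep, , drop = FALSE]
  set$labels$stim <- seq_len(nrow(set$labels))
  rownames(set$labels) <- NULL
  set
}

#' Write / read a stimulus set as PNG files plus a label table
#'
#' Images are written as 8-bit grayscale PNG files `stim_0001.png`, ... and
#' the labels as a tab-separated table with columns `filename`,
#' `identity_id`, `expression_id`, `gender_id`, `split`.
#'
#' @param set A `face_stimulus_set`.
#' @param dir Output directory (created if missing).
#' @return `write_stimulus_set` returns the directory invisibly;
#'   `read_stimulus_set` returns a `face_stimulus_set`.
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "face_stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(set$images)[3]
  fn <- sprintf("stim_%04d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(set$images[, , i] / 255, file.path(dir, fn[i]))
  lab <- cbind(filename = fn, set$labels[, c("identity_id", "expression_id",
                                             "gender_id", "split")])
  write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  lab <- read.delim(file.path(dir, "labels.tsv"), stringsAsFactors = FALSE)
  n <- nrow(lab)
  first <- png::readPNG(file.path(dir, lab$filename[1]))
  H <- nrow(first); W <- ncol(first)
  images <- array(0L, dim = c(H, W, n))
  for (i in seq_len(n)) {
    im <- png::readPNG(file.path(dir, lab$filename[i]))
    if (length(dim(im)) == 3) im <- im[, , 1]
    images[, , i] <- as.integer(round(im * 255))
  }
  labels <- data.frame(stim = seq_len(n), identity_id = lab$identity_id,
                       expression_id = lab$expression_id,
                       gender_id = lab$gender_id,
                       split = as.character(lab$split),
                       stringsAsFactors = FALSE)
  structure(list(images = images, labels = labels, image_size = c(H, W),
                 seed = NA_integer_, identity_params = NULL,
                 expression_names = EXPRESSION_NAMES),
            class = "face_stimulus_set")
}
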