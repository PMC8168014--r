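## Random-forest pixel classification: foreground (labelled somata) versus
## background (autofluorescent tissue architecture).  Training uses sparse
## stroke labels; prediction yields a per-pixel foreground probability which
## is thresholded into a binary mask.  Crops whose mask comes out empty are
## flagged so downstream counting can exclude them.

#' Train a pixel classifier from stroke-labelled images
#'
#' @param labeled list of labelled images; each element is a list with
#'   `image` (numeric matrix) and either logical stroke masks `fg`/`bg` of
#'   the image size or index vectors `fg_idx`/`bg_idx` into the image.
#' @param config a [feature_bank()].
#' @param n_trees forest size (default 100).
#' @param seed integer seed (mandatory; training is deterministic given it).
#' @return A `pixel_classifier` with the fitted forest, the feature
#'   configuration, the out-of-bag accuracy and training provenance.
#' @export
train_pixel_classifier <- function(labeled, config = feature_bank(),
                                   n_trees = 100L, seed) {
  if (missing(seed)) stop("a seed is required")
  rows <- list(); labs <- list()
  for (el in labeled) {
    fg <- stroke_indices(el, "fg"); bg <- stroke_indices(el, "bg")
    if (length(fg) == 0L && length(bg) == 0L) next
    fm <- features_as_matrix(compute_features(el$image, config))
    if (length(fg)) { rows[[length(rows) + 1L]] <- fm[fg, , drop = FALSE]
                      labs[[length(labs) + 1L]] <- rep("fg", length(fg)) }
    if (length(bg)) { rows[[length(rows) + 1L]] <- fm[bg, , drop = FALSE]
                      labs[[length(labs) + 1L]] <- rep("bg", length(bg)) }
  }
  X <- do.call(rbind, rows)
  y <- factor(unlist(labs), levels = c("bg", "fg"))
  if (length(unique(y)) < 2L)
    stop("both foreground and background strokes are required")
  df <- data.frame(.class = y, X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = n_trees, probability = TRUE,
                        seed = seed, num.threads = 1L, verbose = FALSE)
  structure(list(config = config, forest = fit,
                 oob_accuracy = 1 - fit$prediction.error,
                 provenance = list(n_images = length(labeled), seed = seed,
                                   n_pixels = nrow(X))),
            class = "pixel_classifier")
}

stroke_indices <- function(el, which) {
  idx <- el[[paste0(which, "_idx")]]
  if (!is.null(idx)) return(as.integer(idx))
  m <- el[[which]]
  if (is.null(m)) return(integer(0))
  which(as.logical(m))
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "Pixel classifier: %d trees, %d feature channels, OOB accuracy %.3f\n",
    x$forest$num.trees, n_feature_channels(x$config), x$oob_accuracy))
  invisible(x)
}

#' Predict the per-pixel foreground probability
#'
#' @param object a `pixel_classifier`.
#' @param image numeric matrix.
#' @param ... unused.
#' @return Numeric matrix of foreground probabilities in \[0, 1\].
#' @export
predict.pixel_classifier <- function(object, image, ...) {
  fm <- features_as_matrix(compute_features(image, object$config))
  pr <- stats::predict(object$forest, data = as.data.frame(fm),
                       num.threads = 1L)$predictions
  matrix(pr[, "fg"], nrow(image), ncol(image))
}

#' Segment an image into a binary foreground mask
#'
#' Thresholds the classifier's probability map. The returned mask carries an
#' `empty` attribute so callers can exclude crops without any labelled
#' somata from further analysis.
#'
#' @param classifier a `pixel_classifier`.
#' @param image numeric matrix.
#' @param threshold probability cut-off (default 0.5; mask is
#'   `probability >= threshold`).
#' @return Logical matrix with attribute `empty`.
#' @export
segment <- function(classifier, image, threshold = 0.5) {
  prob <- predict(classifier, image)
  mask <- prob >= threshold
  attr(mask, "empty") <- !any(mask)
  mask
}

#' Build stroke labels from an annotated synthetic image
#'
#' Convenience for training on synthetic data: samples foreground strokes
#' from the known soma-signal mask and background strokes away from it.
#'
#' @param ai an `annotated_image` from [simulate_training_set()].
#' @param n_fg,n_bg stroke pixel budgets.
#' @param seed integer seed.
#' @return List with `image`, `fg_idx`, `bg_idx`.
#' @export
strokes_from_annotated <- function(ai, n_fg = 150L, n_bg = 300L, seed = 1L) {
  set.seed(seed)
  fg_pool <- which(ai$fg_mask)
  bg_pool <- which(!ai$fg_mask)
  list(image = ai$image,
       fg_idx = if (length(fg_pool)) sample(fg_pool, min(n_fg, length(fg_pool)))
                else integer(0),
       bg_idx = sample(bg_pool, min(n_bg, length(bg_pool))))
}
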