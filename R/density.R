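## Regression-forest density counting ("learning to count"): each annotated
## soma contributes a unit-mass Gaussian to a target density map; a random
## regression forest learns the map from the per-pixel feature stack; the
## count of a crop is the integral of the predicted density over its mask.
## Forest defaults follow the counting stage's published configuration:
## 20 trees of maximum depth 80.

#' Gaussian dot-annotation density target
#'
#' Builds the regression target: a sum of unit-integral Gaussians centred at
#' the annotated soma positions. Kernels truncated by the image border are
#' renormalised so every dot contributes exactly one unit of mass.
#'
#' @param dots n x 2 matrix of (col, row) dot positions (1-based px).
#' @param shape integer vector `c(nrow, ncol)`.
#' @param sigma_dot kernel scale in px (default 2, about one soma radius).
#' @return Numeric matrix summing to the number of dots.
#' @export
density_target <- function(dots, shape, sigma_dot = 2) {
  out <- matrix(0, shape[1], shape[2])
  if (is.null(dots) || nrow(dots) == 0L) return(out)
  if (any(dots[, 1] < 1 | dots[, 1] > shape[2] |
          dots[, 2] < 1 | dots[, 2] > shape[1]))
    stop("dot annotation outside image bounds")
  hw <- ceiling(3 * sigma_dot) + 1L
  for (i in seq_len(nrow(dots))) {
    cx <- dots[i, 1]; cy <- dots[i, 2]
    rr <- max(1L, floor(cy) - hw):min(shape[1], ceiling(cy) + hw)
    cc <- max(1L, floor(cx) - hw):min(shape[2], ceiling(cx) + hw)
    k <- outer(exp(-(rr - cy)^2 / (2 * sigma_dot^2)),
               exp(-(cc - cx)^2 / (2 * sigma_dot^2)))
    out[rr, cc] <- out[rr, cc] + k / sum(k)
  }
  out
}

#' Train the density-counting model
#'
#' Fits a random regression forest from the feature stack to the Gaussian
#' density target over a stratified pixel subsample of the training images
#' (all high-density pixels plus a background sample, capped per image), and
#' predicts at full resolution.
#'
#' @param training list of `annotated_image` objects (`image` + `dots`).
#' @param config a [feature_bank()].
#' @param n_trees number of trees (default 20).
#' @param max_depth maximum tree depth (default 80).
#' @param seed integer seed (mandatory).
#' @param sigma_dot target kernel scale in px.
#' @param max_px_per_image per-image training pixel cap.
#' @return A `density_model`.
#' @export
train_density_model <- function(training, config = feature_bank(),
                                n_trees = 20L, max_depth = 80L, seed,
                                sigma_dot = 2, max_px_per_image = 1200L) {
  if (missing(seed)) stop("a seed is required")
  if (length(training) == 0L) stop("empty training set")
  rows <- vector("list", length(training))
  targ <- vector("list", length(training))
  for (i in seq_along(training)) {
    ai <- training[[i]]
    fm <- features_as_matrix(compute_features(ai$image, config))
    y <- as.vector(density_target(ai$dots, dim(ai$image), sigma_dot))
    set.seed(seed_child(seed, i))
    pos <- which(y > 1e-4)
    n_pos <- min(length(pos), floor(max_px_per_image * 0.6))
    take_pos <- if (length(pos)) sample(pos, n_pos) else integer(0)
    neg <- which(y <= 1e-4)
    take_neg <- sample(neg, min(length(neg), max_px_per_image - n_pos))
    take <- c(take_pos, take_neg)
    rows[[i]] <- fm[take, , drop = FALSE]
    targ[[i]] <- y[take]
  }
  df <- data.frame(.density = unlist(targ), do.call(rbind, rows),
                   check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".density", data = df,
                        num.trees = n_trees, max.depth = max_depth,
                        seed = seed, num.threads = 1L, verbose = FALSE)
  structure(list(config = config, forest = fit, sigma_dot = sigma_dot,
                 provenance = list(n_images = length(training), seed = seed,
                                   n_pixels = nrow(df))),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf(
    "Density counting model: %d trees (max depth %d), %d channels, trained on %d images\n",
    x$forest$num.trees, x$forest$call$max.depth %||% NA,
    n_feature_channels(x$config), x$provenance$n_images))
  invisible(x)
}

#' Predict a per-pixel density map
#'
#' Predictions are clipped at zero (regression forests can emit small
#' negative values); the clipped mass is reported as an attribute.
#'
#' @param object a `density_model`.
#' @param image numeric matrix.
#' @param ... unused.
#' @return Numeric matrix (somata per pixel), attribute `clipped_mass`.
#' @export
predict.density_model <- function(object, image, ...) {
  fm <- features_as_matrix(compute_features(image, object$config))
  pr <- stats::predict(object$forest, data = as.data.frame(fm),
                       num.threads = 1L)$predictions
  clipped <- -sum(pr[pr < 0])
  out <- matrix(pmax(pr, 0), nrow(image), ncol(image))
  attr(out, "clipped_mass") <- clipped
  out
}

#' Count somata in a region crop
#'
#' Integrates the predicted density over the crop's region mask,
#' optionally intersected with a foreground mask from [segment()].
#'
#' @param model a `density_model`.
#' @param crop a `region_crop` (or any list with `image` and `mask`).
#' @param fg_mask optional logical matrix of the crop size.
#' @return A `count_estimate`: `count`, `density` map, `code`.
#' @export
count_crop <- function(model, crop, fg_mask = NULL) {
  mask <- crop$mask
  if (!is.null(fg_mask)) {
    if (!all(dim(fg_mask) == dim(mask)))
      stop("foreground mask shape does not match the crop")
    mask <- mask & fg_mask
  }
  if (!any(mask))
    return(structure(list(count = 0, density = NULL,
                          code = crop$code %||% NA_character_),
                     class = "count_estimate"))
  dens <- predict(model, crop$image)
  structure(list(count = sum(dens[mask]), density = dens,
                 code = crop$code %||% NA_character_),
            class = "count_estimate")
}

#' @export
print.count_estimate <- function(x, ...) {
  cat(sprintf("Count estimate%s: %.2f\n",
              if (is.na(x$code)) "" else paste0(" [", x$code, "]"), x$count))
  invisible(x)
}

#' Counting accuracy on annotated evaluation images
#'
#' Accuracy is the complement of the mean relative count error:
#' `100 * (1 - mean_i |est_i - true_i| / max(true_i, 1))`, floored at 0.
#' The `max(., 1)` guard makes neuron-free evaluation tiles well defined.
#'
#' @param model a `density_model`.
#' @param eval_set list of `annotated_image` objects.
#' @return List with `accuracy` (percent), `per_image` data.frame
#'   (true, estimated, relative error).
#' @export
evaluate_accuracy <- function(model, eval_set) {
  if (length(eval_set) == 0L) stop("empty evaluation set")
  res <- lapply(eval_set, function(ai) {
    est <- sum(predict(model, ai$image))
    true <- nrow(ai$dots)
    c(true = true, est = est, rel_err = abs(est - true) / max(true, 1))
  })
  tab <- as.data.frame(do.call(rbind, res))
  list(accuracy = max(0, 100 * (1 - mean(tab$rel_err))), per_image = tab)
}

#' Accuracy as a function of training-set size
#'
#' Trains the density model on nested subsets of a training pool and
#' evaluates each on a common held-out set; the classical saturating
#' learning curve of the counting stage.
#'
#' @param design a `cohort_design` (rendering parameters).
#' @param train_sizes increasing training-set sizes.
#' @param n_eval held-out evaluation images.
#' @param seed integer seed.
#' @param ... passed to [train_density_model()].
#' @return data.frame with `n_train` and `accuracy`.
#' @export
accuracy_curve <- function(design, train_sizes = c(20, 60, 100, 150, 250),
                           n_eval = 100L, seed = 1L, ...) {
  pool <- simulate_training_set(design, max(train_sizes), seed)
  eval_set <- simulate_training_set(design, n_eval, seed_child(seed, 7919L))
  acc <- vapply(train_sizes, function(n) {
    m <- train_density_model(pool[seq_len(n)], seed = seed_child(seed, n), ...)
    evaluate_accuracy(m, eval_set)$accuracy
  }, numeric(1))
  data.frame(n_train = train_sizes, accuracy = acc)
}
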