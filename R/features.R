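## Gaussian-derivative feature bank shared by the pixel classifier and the
## density counter: six filter families (Gaussian smoothing, Laplacian of
## Gaussian, Gaussian gradient magnitude, difference of Gaussians, structure
## tensor eigenvalues, Hessian eigenvalues) evaluated at a fixed set of
## scales.  All filters are separable and applied exactly by small banded
## convolution matrices with mirror (reflect-101) border handling.

#' Feature bank configuration
#'
#' @param sigmas strictly increasing positive scales in px
#'   (default 1.0, 1.6, 3.5, 5.0).
#' @param families subset of the six supported filter families.
#' @return A `feature_bank` configuration object.
#' @export
feature_bank <- function(sigmas = c(1.0, 1.6, 3.5, 5.0),
                         families = c("gaussian_smoothing",
                                      "laplacian_of_gaussian",
                                      "gaussian_gradient_magnitude",
                                      "difference_of_gaussians",
                                      "structure_tensor_eigenvalues",
                                      "hessian_eigenvalues")) {
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("gaussian_smoothing",
                                    "laplacian_of_gaussian",
                                    "gaussian_gradient_magnitude",
                                    "difference_of_gaussians",
                                    "structure_tensor_eigenvalues",
                                    "hessian_eigenvalues"))
  if (any(sigmas <= 0) || any(diff(sigmas) <= 0))
    stop("sigmas must be strictly increasing and > 0")
  structure(list(sigmas = sigmas, families = families),
            class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat("Feature bank:", length(x$families), "families x",
      length(x$sigmas), "scales =", n_feature_channels(x), "channels\n")
  invisible(x)
}

#' Number of channels a feature bank produces
#'
#' Eigenvalue families contribute two channels per scale, the others one.
#'
#' @param config a `feature_bank`.
#' @return Integer channel count.
#' @export
n_feature_channels <- function(config) {
  per <- ifelse(config$families %in% c("structure_tensor_eigenvalues",
                                       "hessian_eigenvalues"), 2L, 1L)
  sum(per) * length(config$sigmas)
}

## Sampled Gaussian and derivative kernels, truncated at 3 sigma.
## Derivative kernels are recentred to exact zero sum so that constant
## images give exactly zero derivative responses despite truncation.
gauss_kernel <- function(sigma, order = 0L) {
  hw <- max(1L, ceiling(3 * sigma))
  x <- seq(-hw, hw)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
              "0" = g,
              "1" = -x / sigma^2 * g,
              "2" = (x^2 - sigma^2) / sigma^4 * g)
  if (order > 0L) k <- k - mean(k)
  k
}

## Banded convolution matrix with mirror (reflect-101) borders: row i of the
## result holds the kernel centred at sample i.
conv_matrix <- function(n, kernel) {
  hw <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - hw - 1L
    j <- seq_len(n) + off
    ## reflect-101 indices
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + kernel[k]
  }
  M
}

## Separable filtering: order_r along rows (y), order_c along columns (x).
sep_filter <- function(img, sigma, order_r = 0L, order_c = 0L) {
  Mr <- conv_matrix(nrow(img), gauss_kernel(sigma, order_r))
  Mc <- conv_matrix(ncol(img), gauss_kernel(sigma, order_c))
  Mr %*% img %*% t(Mc)
}

sorted_eigen_2x2 <- function(axx, axy, ayy) {
  tr <- axx + ayy
  d <- sqrt(pmax(0, (axx - ayy)^2 + 4 * axy^2))
  list(hi = (tr + d) / 2, lo = (tr - d) / 2)
}

#' Compute the per-pixel feature stack
#'
#' Evaluates the configured filter families at every scale. The difference
#' of Gaussians at scale `s` uses the pair `(s, 1.6 s)`; the structure tensor
#' uses inner scale `s / 2` and outer scale `s`; eigenvalue channels are
#' sorted descending.
#'
#' @param image numeric matrix with finite values.
#' @param config a `feature_bank`.
#' @return 3-D array `nrow x ncol x channels` with channel names like
#'   `"laplacian_of_gaussian_s1.6"`.
#' @export
compute_features <- function(image, config = feature_bank()) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  chans <- list()
  for (s in config$sigmas) {
    smooth <- NULL
    get_smooth <- function() {
      if (is.null(smooth)) smooth <<- sep_filter(image, s)
      smooth
    }
    for (fam in config$families) {
      tag <- paste0(fam, "_s", s)
      if (fam == "gaussian_smoothing") {
        chans[[tag]] <- get_smooth()
      } else if (fam == "laplacian_of_gaussian") {
        chans[[tag]] <- sep_filter(image, s, 2L, 0L) +
          sep_filter(image, s, 0L, 2L)
      } else if (fam == "gaussian_gradient_magnitude") {
        gx <- sep_filter(image, s, 0L, 1L)
        gy <- sep_filter(image, s, 1L, 0L)
        chans[[tag]] <- sqrt(gx^2 + gy^2)
      } else if (fam == "difference_of_gaussians") {
        chans[[tag]] <- get_smooth() - sep_filter(image, 1.6 * s)
      } else if (fam == "structure_tensor_eigenvalues") {
        gx <- sep_filter(image, s / 2, 0L, 1L)
        gy <- sep_filter(image, s / 2, 1L, 0L)
        e <- sorted_eigen_2x2(sep_filter(gx * gx, s),
                              sep_filter(gx * gy, s),
                              sep_filter(gy * gy, s))
        chans[[paste0(tag, "_1")]] <- e$hi
        chans[[paste0(tag, "_2")]] <- e$lo
      } else if (fam == "hessian_eigenvalues") {
        e <- sorted_eigen_2x2(sep_filter(image, s, 0L, 2L),
                              sep_filter(image, s, 1L, 1L),
                              sep_filter(image, s, 2L, 0L))
        chans[[paste0(tag, "_1")]] <- e$hi
        chans[[paste0(tag, "_2")]] <- e$lo
      }
    }
  }
  out <- array(unlist(chans, use.names = FALSE),
               dim = c(nrow(image), ncol(image), length(chans)),
               dimnames = list(NULL, NULL, names(chans)))
  out
}

## Flatten a feature array to a pixel x channel matrix.
features_as_matrix <- function(feat) {
  d <- dim(feat)
  m <- matrix(feat, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(feat)[[3]]
  m
}
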