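## Misfolded-protein burden scoring: rolling-ball background subtraction
## (grayscale opening with a non-flat, ball-shaped structuring element)
## followed by Renyi-entropy automatic thresholding of the 256-bin
## histogram; the burden is the area fraction of the suprathreshold mask.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (non-flat, height `sqrt(r^2 - d^2)`) structuring element of
#' the given radius, and subtracts it; the result is clipped at zero.
#' Features narrower than the ball (somata, plaques) survive; smooth
#' large-scale shading is removed. Borders are handled by replicate padding.
#'
#' @param image numeric matrix.
#' @param radius_px ball radius in px (default 20; must be >= 1 and smaller
#'   than both image extents).
#' @return Background-corrected image (same size), attribute `background`.
#' @export
rolling_ball_subtract <- function(image, radius_px = 20L) {
  stopifnot(is.matrix(image))
  if (radius_px < 1) stop("radius must be >= 1")
  if (radius_px >= min(dim(image)))
    stop("radius must be smaller than the image extent")
  bg <- ball_dilate(ball_erode(image, radius_px), radius_px)
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}

ball_offsets <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- d$dy^2 + d$dx^2 <= r^2
  d <- d[keep, ]
  d$z <- sqrt(r^2 - d$dy^2 - d$dx^2)
  d
}

pad_replicate <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  img[ri, ci, drop = FALSE]
}

ball_erode <- function(img, r) {
  P <- pad_replicate(img, r)
  off <- ball_offsets(r)
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(off))) {
    sub <- P[(1:nr) + r + off$dy[i], (1:nc) + r + off$dx[i], drop = FALSE]
    acc <- pmin(acc, sub - off$z[i])
  }
  acc
}

ball_dilate <- function(img, r) {
  P <- pad_replicate(img, r)
  off <- ball_offsets(r)
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(off))) {
    sub <- P[(1:nr) + r + off$dy[i], (1:nc) + r + off$dx[i], drop = FALSE]
    acc <- pmax(acc, sub + off$z[i])
  }
  acc
}

#' Renyi-entropy automatic threshold of a 256-bin histogram
#'
#' Computes the entropy-maximising split of the histogram at three Renyi
#' orders - the Shannon limit (order -> 1), order 1/2 and order 2 - and
#' combines the three candidate thresholds with the published
#' order-dependent weighting rule (sorted candidates t1 <= t2 <= t3 receive
#' weights depending on their mutual distances; the final threshold blends
#' them through the cumulative histogram mass between t1 and t3).
#'
#' @param hist_counts nonnegative integer vector of length 256.
#' @return Integer threshold bin in 0..255 (intensities strictly above it
#'   are foreground).
#' @export
renyi_threshold <- function(hist_counts) {
  if (length(hist_counts) != 256L) stop("expected a 256-bin histogram")
  if (any(hist_counts < 0)) stop("negative histogram counts")
  nz <- which(hist_counts > 0)
  if (length(nz) < 2L) stop("degenerate histogram: fewer than 2 nonempty bins")
  p <- hist_counts / sum(hist_counts)
  P1 <- cumsum(p)
  first <- nz[1]; last <- nz[length(nz)]
  t1 <- renyi_best(p, P1, first, last, order = 1)
  t2 <- renyi_best(p, P1, first, last, order = 0.5)
  t3 <- renyi_best(p, P1, first, last, order = 2)
  ts <- sort(c(t1, t2, t3))
  if (abs(ts[1] - ts[2]) <= 5) {
    if (abs(ts[2] - ts[3]) <= 5) b <- c(1, 2, 1) else b <- c(0, 1, 3)
  } else {
    if (abs(ts[2] - ts[3]) <= 5) b <- c(3, 1, 0) else b <- c(1, 2, 1)
  }
  omega <- P1[ts[3]] - P1[ts[1]]
  thr <- ts[1] * (P1[ts[1]] + 0.25 * omega * b[1]) +
    0.25 * ts[2] * omega * b[2] +
    ts[3] * (1 - P1[ts[3]] + 0.25 * omega * b[3])
  as.integer(round(thr)) - 1L     # bins are 1-based in R; report 0..255
}

## Best split for one Renyi order; candidates run over bins with mass on
## both sides. order = 1 is the Shannon/Kapur limit.
renyi_best <- function(p, P1, first, last, order) {
  best <- -Inf; best_t <- first
  for (t in first:(last - 1L)) {
    w0 <- P1[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:t] / w0
    p1 <- p[(t + 1L):length(p)] / w1
    crit <- if (order == 1) {
      -sum(p0[p0 > 0] * log(p0[p0 > 0])) - sum(p1[p1 > 0] * log(p1[p1 > 0]))
    } else {
      (log(sum(p0^order)) + log(sum(p1^order))) / (1 - order)
    }
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}

## Shannon-only (Kapur) threshold; exposed for validation against
## exhaustive search.
shannon_threshold <- function(hist_counts) {
  p <- hist_counts / sum(hist_counts)
  P1 <- cumsum(p)
  nz <- which(hist_counts > 0)
  renyi_best(p, P1, nz[1], nz[length(nz)], order = 1) - 1L
}

#' Burden configuration
#'
#' @param rolling_ball_radius_px rolling-ball radius (default 20).
#' @param bins histogram bins (fixed at 256).
#' @param literal_order if `TRUE`, threshold the raw image first and apply
#'   background subtraction afterwards (the literal reading of the original
#'   protocol wording); the default subtracts background first.
#' @return A `burden_config`.
#' @export
burden_config <- function(rolling_ball_radius_px = 20L, bins = 256L,
                          literal_order = FALSE) {
  stopifnot(rolling_ball_radius_px >= 1, bins == 256L)
  structure(list(radius = rolling_ball_radius_px, bins = bins,
                 literal_order = literal_order), class = "burden_config")
}

#' Misfolded-protein burden of an image
#'
#' Pipeline: rolling-ball background subtraction, 256-bin histogram,
#' Renyi-entropy threshold, burden = fraction of pixels strictly above the
#' threshold. With `literal_order = TRUE` in the configuration the threshold
#' is computed on the raw image instead and background subtraction is only
#' reported.
#'
#' @param image numeric matrix.
#' @param config a [burden_config()].
#' @return A `burden_result`: `threshold` (intensity), `area_fraction`,
#'   `mask`, `corrected` image.
#' @export
burden_fraction <- function(image, config = burden_config()) {
  corrected <- rolling_ball_subtract(image, config$radius)
  target <- if (config$literal_order) image else corrected
  rng <- range(target)
  if (diff(rng) <= 0) stop("degenerate histogram: image is constant")
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  h <- as.integer(table(cut(as.vector(target), breaks = breaks,
                            include.lowest = TRUE,
                            labels = seq_len(256L)))[as.character(1:256)])
  h[is.na(h)] <- 0L
  tbin <- renyi_threshold(h)
  thr <- breaks[tbin + 2L]      # upper edge of threshold bin (0-based bin)
  mask <- target > thr
  structure(list(threshold = thr, threshold_bin = tbin,
                 area_fraction = mean(mask), mask = mask,
                 corrected = corrected),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Burden: threshold %.3g, area fraction %.3f\n",
              x$threshold, x$area_fraction))
  invisible(x)
}
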