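## Planar polygon utilities used by the atlas, parcellation and the
## synthetic generator.  Polygons are n x 2 matrices of (x, y) vertices in
## atlas millimetres, implicitly closed (last vertex joins the first).
## Point-in-polygon uses the even-odd (ray crossing) rule throughout; a pixel
## belongs to a region iff its centre is inside the polygon.

#' Unsigned area of a simple polygon
#'
#' Shoelace formula; the absolute value is returned so vertex order
#' (clockwise or counter-clockwise) does not matter.
#'
#' @param poly numeric matrix with two columns (x, y), one row per vertex.
#' @return Area in squared input units.
#' @export
poly_area <- function(poly) {
  poly <- as_poly(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @inheritParams poly_area
#' @return Numeric length-2 vector (x, y).
#' @export
poly_centroid <- function(poly) {
  poly <- as_poly(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x[j]) * cross), sum((y + y[j]) * cross)) / (6 * a)
}

#' Scale a polygon about a fixed point
#'
#' Used to model regional atrophy: the outline shrinks isotropically about
#' its centroid, so area scales with `factor^2`.
#'
#' @inheritParams poly_area
#' @param factor positive scalar linear scale factor.
#' @param about centre of scaling; defaults to the polygon centroid.
#' @return Scaled polygon matrix.
#' @export
poly_scale <- function(poly, factor, about = poly_centroid(poly)) {
  poly <- as_poly(poly)
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  sweep(sweep(poly, 2L, about) * factor, 2L, about, "+")
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray-crossing test. Points exactly on an edge may fall on
#' either side; callers that care about boundary pixels should not rely on
#' edge-point behaviour.
#'
#' @param x,y numeric vectors of point coordinates (recycled to equal length).
#' @inheritParams poly_area
#' @return Logical vector, `TRUE` where the point lies inside.
#' @export
point_in_poly <- function(x, y, poly) {
  poly <- as_poly(poly)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  px <- poly[, 1L]; py <- poly[, 2L]
  m <- nrow(poly)
  inside <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    yi <- py[i]; yj <- py[j]
    crosses <- (yi > y) != (yj > y)
    if (any(crosses)) {
      xin <- px[i] + (y[crosses] - yi) * (px[j] - px[i]) / (yj - yi)
      hit <- x[crosses] < xin
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside
}

## Proper intersection test for two segments (shared endpoints do not count).
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

poly_edges <- function(poly) {
  n <- nrow(poly)
  lapply(seq_len(n), function(i) list(poly[i, ], poly[if (i == n) 1L else i + 1L, ]))
}

#' Do two simple polygons self-intersect or share interior?
#'
#' Interior overlap test used for atlas validation: polygons overlap when any
#' edges properly cross or one contains a vertex (or centroid) of the other.
#' Touching along a shared boundary does not count as overlap.
#'
#' @param a,b polygon matrices.
#' @return Logical scalar.
#' @export
polys_overlap <- function(a, b) {
  a <- as_poly(a); b <- as_poly(b)
  ea <- poly_edges(a); eb <- poly_edges(b)
  for (s in ea) for (t in eb)
    if (segments_cross(s[[1]], s[[2]], t[[1]], t[[2]])) return(TRUE)
  if (any(point_in_poly(a[, 1], a[, 2], b))) return(TRUE)
  if (any(point_in_poly(b[, 1], b[, 2], a))) return(TRUE)
  ca <- poly_centroid(a); cb <- poly_centroid(b)
  if (point_in_poly(ca[1], ca[2], b) || point_in_poly(cb[1], cb[2], a)) return(TRUE)
  FALSE
}

## Self-intersection check (simple polygon invariant).
poly_is_simple <- function(poly) {
  poly <- as_poly(poly)
  e <- poly_edges(poly)
  n <- length(e)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (j == i + 1L || (i == 1L && j == n)) next
    if (segments_cross(e[[i]][[1]], e[[i]][[2]], e[[j]][[1]], e[[j]][[2]]))
      return(FALSE)
  }
  TRUE
}

as_poly <- function(poly) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("a polygon needs an n x 2 coordinate matrix with n >= 3")
  if (anyNA(poly)) stop("polygon contains missing coordinates")
  poly
}

## --- section frames -------------------------------------------------------
## A frame ties pixel indices to atlas millimetres for one section image:
## x_mm = x0 + (col - 1) * px_mm ; y_mm = y0 - (row - 1) * px_mm
## (row 1 is the dorsal-most image row). Columns/rows are 1-based in R.

make_frame <- function(x0, y0, pixel_size_mm, nrow, ncol) {
  list(x0 = x0, y0 = y0, px = pixel_size_mm, nrow = as.integer(nrow),
       ncol = as.integer(ncol))
}

frame_px_to_mm <- function(frame, col, row) {
  cbind(x = frame$x0 + (col - 1) * frame$px,
        y = frame$y0 - (row - 1) * frame$px)
}

frame_mm_to_px <- function(frame, x, y) {
  cbind(col = (x - frame$x0) / frame$px + 1,
        row = (frame$y0 - y) / frame$px + 1)
}

#' Rasterise a polygon onto a section frame
#'
#' Marks pixels whose centres fall inside the polygon (even-odd rule).
#' Returns a logical matrix of the full frame size.
#'
#' @param poly polygon in frame (mm) coordinates.
#' @param frame section frame as used by the synthetic generator.
#' @return Logical matrix (`nrow` x `ncol`).
#' @keywords internal
rasterize_poly <- function(poly, frame) {
  poly <- as_poly(poly)
  mask <- matrix(FALSE, frame$nrow, frame$ncol)
  ## bounding box in pixel indices
  px <- frame_mm_to_px(frame, poly[, 1], poly[, 2])
  c0 <- max(1L, floor(min(px[, "col"]))); c1 <- min(frame$ncol, ceiling(max(px[, "col"])))
  r0 <- max(1L, floor(min(px[, "row"]))); r1 <- min(frame$nrow, ceiling(max(px[, "row"])))
  if (c0 > c1 || r0 > r1) return(mask)
  cols <- c0:c1; rows <- r0:r1
  grid <- expand.grid(row = rows, col = cols)
  mm <- frame_px_to_mm(frame, grid$col, grid$row)
  inside <- point_in_poly(mm[, "x"], mm[, "y"], poly)
  mask[cbind(grid$row, grid$col)] <- inside
  mask
}
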