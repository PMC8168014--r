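## Landmark-based registration between atlas plates (mm) and section images
## (px), plus polygon parcellation of sections into per-region crops.
## The forward direction maps section pixels to atlas mm; the backward
## direction maps atlas mm to section pixels and is obtained by fitting the
## reversed correspondence, not by numerically inverting the forward fit.

#' Fit a landmark warp between a section and an atlas plate
#'
#' Least-squares fit of a similarity, affine or thin-plate-spline transform
#' to paired landmarks. Both directions are fitted independently from the
#' same pairs.
#'
#' @param landmarks data.frame with columns `atlas_x`, `atlas_y` (mm) and
#'   `sec_x`, `sec_y` (px); one row per landmark pair. A `name` column is
#'   optional.
#' @param model `"affine"` (default), `"similarity"` or `"tps"`.
#' @return An object of class `lha_warp` with `forward`/`backward` transform
#'   functions, the `model` name, `residual_px` (RMS residual of the backward
#'   fit, px) and the landmark table.
#' @examples
#' lm <- data.frame(atlas_x = c(0, 1, 0, 1), atlas_y = c(0, 0, 1, 1),
#'                  sec_x = c(10, 110, 10, 110), sec_y = c(200, 200, 100, 100))
#' w <- fit_warp(lm)
#' warp_apply(w, cbind(0.5, 0.5), "backward")
#' @export
fit_warp <- function(landmarks, model = c("affine", "similarity", "tps")) {
  model <- match.arg(model)
  A <- cbind(landmarks$atlas_x, landmarks$atlas_y)
  S <- cbind(landmarks$sec_x, landmarks$sec_y)
  if (anyNA(A) || anyNA(S)) stop("landmark table contains missing values")
  need <- switch(model, similarity = 2L, affine = 3L, tps = 4L)
  if (nrow(A) < need)
    stop(sprintf("model '%s' needs at least %d landmark pairs", model, need))
  if (model != "similarity" && is_collinear(A))
    stop("degenerate landmark configuration: points are collinear")
  fwd <- fit_transform(S, A, model)   # section px -> atlas mm
  bwd <- fit_transform(A, S, model)   # atlas mm -> section px
  res <- sqrt(mean(rowSums((bwd(A) - S)^2)))
  structure(list(model = model, forward = fwd, backward = bwd,
                 residual_px = res, landmarks = landmarks),
            class = "lha_warp")
}

#' @export
print.lha_warp <- function(x, ...) {
  cat(sprintf("Landmark warp (%s), %d pairs, backward residual %.3g px\n",
              x$model, nrow(x$landmarks), x$residual_px))
  invisible(x)
}

#' Apply a fitted warp to points
#'
#' @param warp an `lha_warp`.
#' @param pts n x 2 matrix of points.
#' @param direction `"forward"` (section px to atlas mm) or `"backward"`.
#' @return n x 2 matrix of mapped points.
#' @export
warp_apply <- function(warp, pts, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  pts <- matrix(as.numeric(pts), ncol = 2L)
  warp[[direction]](pts)
}

is_collinear <- function(P, tol = 1e-9) {
  P0 <- sweep(P, 2L, colMeans(P))
  d <- svd(P0, nu = 0, nv = 0)$d
  d[2] <= tol * max(d[1], 1)
}

fit_transform <- function(from, to, model) {
  switch(model,
    affine = {
      X <- cbind(1, from)
      B <- qr.solve(X, to)            # 3 x 2 coefficient matrix
      function(p) cbind(1, p) %*% B
    },
    similarity = {
      n <- nrow(from)
      ## params (a, b, tx, ty): x' = a x - b y + tx ; y' = b x + a y + ty
      X <- rbind(cbind(from[, 1], -from[, 2], 1, 0),
                 cbind(from[, 2],  from[, 1], 0, 1))
      yv <- c(to[, 1], to[, 2])
      th <- qr.solve(X, yv)
      function(p) cbind(th[1] * p[, 1] - th[2] * p[, 2] + th[3],
                        th[2] * p[, 1] + th[1] * p[, 2] + th[4])
    },
    tps = fit_tps(from, to))
}

## Thin-plate spline with kernel U(r) = r^2 log(r^2); exact interpolation
## at the landmarks (no smoothing), affine part included.
fit_tps <- function(from, to) {
  n <- nrow(from)
  U <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))
  d2 <- as.matrix(dist(from))^2
  K <- U(d2)
  P <- cbind(1, from)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  ## slight ridge on the kernel block guards near-degenerate configurations
  diag(L)[seq_len(n)] <- diag(L)[seq_len(n)] + 1e-10
  rhs <- rbind(to, matrix(0, 3, 2))
  W <- tryCatch(solve(L, rhs), error = function(e)
    stop("degenerate landmark configuration for thin-plate spline fit"))
  ctrl <- from
  function(p) {
    d2p <- outer(rowSums(p^2), rowSums(ctrl^2), "+") - 2 * p %*% t(ctrl)
    d2p[d2p < 0] <- 0
    U(d2p) %*% W[seq_len(n), , drop = FALSE] +
      cbind(1, p) %*% W[n + 1:3, , drop = FALSE]
  }
}

#' Assign a section to the best-fitting atlas plate
#'
#' Fits an affine warp from every candidate plate's named landmarks to the
#' section's landmarks and selects the plate with the smallest RMS residual;
#' exact ties break to the more anterior plate.
#'
#' @param atlas an `lha_atlas`.
#' @param section_landmarks data.frame with columns `name`, `x`, `y`
#'   (section px).
#' @param min_shared minimum number of shared landmark names required.
#' @return List with `plate` (index), `ap_mm`, `residual_px` and the fitted
#'   `warp`.
#' @export
assign_plate <- function(atlas, section_landmarks, min_shared = 3L) {
  best <- NULL
  for (k in seq_along(atlas$plates)) {
    pl <- atlas$plates[[k]]
    m <- merge(pl$landmarks, section_landmarks, by = "name",
               suffixes = c("_atlas", "_sec"))
    if (nrow(m) < min_shared) next
    lmk <- data.frame(atlas_x = m$x_atlas, atlas_y = m$y_atlas,
                      sec_x = m$x_sec, sec_y = m$y_sec)
    w <- tryCatch(fit_warp(lmk, "affine"), error = function(e) NULL)
    if (is.null(w)) next
    ## strictly better, or tie (within numerical noise) -> keep the earlier
    ## (more anterior) plate
    if (is.null(best) || w$residual_px < best$residual_px - 1e-9)
      best <- list(plate = k, ap_mm = pl$ap_mm, residual_px = w$residual_px,
                   warp = w)
  }
  if (is.null(best))
    stop("no atlas plate shares >= ", min_shared,
         " landmark names with the section")
  best
}

#' Parcellate a section image into per-region crops
#'
#' Backward-warps every leaf-region outline of a plate onto the section,
#' rasterises it (a pixel belongs to a region iff its centre falls inside the
#' warped polygon, even-odd rule), and cuts a padded, masked crop per
#' (region, hemisphere). Regions whose warped polygon misses the image are
#' skipped. Each crop carries a code
#' `<brain>_<section>_<region>_<hemisphere>` so it can be re-identified
#' downstream.
#'
#' @param image numeric matrix (rows = image y, 1 = dorsal edge).
#' @param plate one plate of an `lha_atlas`.
#' @param warp an `lha_warp` whose backward direction maps this plate's mm
#'   coordinates to the section's pixels.
#' @param atlas the `lha_atlas` the plate belongs to (for the ontology).
#' @param pixel_size_mm pixel pitch of the section image in mm.
#' @param brain_id,section_index identifiers stamped into each crop.
#' @param pad context padding of the crop bounding box in px (masked out
#'   before any counting).
#' @return List of `region_crop` objects: `region`, `hemisphere`, `bbox`
#'   (row0, row1, col0, col1), `image` (masked crop), `mask`, `area_mm2`,
#'   `empty` flag and `code`.
#' @export
parcellate <- function(image, plate, warp, atlas, pixel_size_mm,
                       brain_id = "brain", section_index = 1L, pad = 8L) {
  stopifnot(is.matrix(image))
  leaves <- setdiff(atlas$regions$id,
                    atlas$regions$parent[!is.na(atlas$regions$parent)])
  crops <- list()
  for (o in plate$outlines) {
    if (!o$region %in% leaves) next
    ppx <- warp_apply(warp, o$polygon, "backward")   # (col, row)
    mask <- rasterize_px_poly(ppx, nrow(image), ncol(image))
    if (!any(mask)) next
    idx <- which(mask, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(image), max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(image), max(idx[, 2]) + pad)
    sub <- image[r0:r1, c0:c1, drop = FALSE]
    msk <- mask[r0:r1, c0:c1, drop = FALSE]
    sub[!msk] <- 0
    crops[[length(crops) + 1L]] <- structure(
      list(brain_id = brain_id, section_index = section_index,
           region = o$region, hemisphere = o$hemisphere,
           bbox = c(row0 = r0, row1 = r1, col0 = c0, col1 = c1),
           image = sub, mask = msk,
           area_mm2 = sum(mask) * pixel_size_mm^2,
           pixel_size_mm = pixel_size_mm,
           empty = FALSE,
           code = paste(brain_id, section_index, o$region, o$hemisphere,
                        sep = "_")),
      class = "region_crop")
  }
  crops
}

## Rasterise a polygon given directly in pixel coordinates (col, row);
## pixel centres at integer indices, 1-based.
rasterize_px_poly <- function(ppx, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  c0 <- max(1L, floor(min(ppx[, 1]))); c1 <- min(ncol, ceiling(max(ppx[, 1])))
  r0 <- max(1L, floor(min(ppx[, 2]))); r1 <- min(nrow, ceiling(max(ppx[, 2])))
  if (c0 > c1 || r0 > r1) return(mask)
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  inside <- point_in_poly(grid$col, grid$row, ppx)
  mask[cbind(grid$row, grid$col)] <- inside
  mask
}

#' @export
print.region_crop <- function(x, ...) {
  cat(sprintf("Region crop %s: %d x %d px, area %.4f mm2%s\n", x$code,
              nrow(x$image), ncol(x$image), x$area_mm2,
              if (isTRUE(x$empty)) " [flagged empty]" else ""))
  invisible(x)
}
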