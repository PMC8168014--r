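## Synthetic cohort generator.  Produces serial-section image stacks with
## exact ground truth (per-region/hemisphere soma counts, region volumes,
## injection geometry) that emulate the statistical structure the analysis
## assumes: region-dependent soma densities, a genotype x region projection
## effect, LHA atrophy, smooth autofluorescence background, dendritic
## fragment artifacts and a bright injection-site blob with optional dorsal
## backflow.  Counts are Poisson per region so cohorts show realistic
## sampling variation; an optional negative-binomial dispersion adds
## between-brain biological variability.
##
## Seed hierarchy: cohort seed -> per-brain seeds -> per-section seeds, so a
## single brain (or section) regenerates independently of the rest.

seed_child <- function(seed, i) {
  ## Lehmer step; stays exact in doubles and below 2^31
  as.integer((as.numeric(seed) * 48271 + i) %% 2147483647)
}

#' Describe a synthetic cohort
#'
#' Bundles every generative parameter of a cohort: sample size, genotypes,
#' per-region soma densities for the reference (first) genotype, the
#' genotype x region effect map, LHA atrophy factors, the ipsi/contra split,
#' image noise and the injection geometry.
#'
#' Default densities follow a relative profile (limbic and orbital areas
#' densest, sensory cortex and small nuclei sparser) scaled so that the
#' expected total number of labelled neurons per reference brain equals
#' `total_neurons` (50,000 by default, of which 80% ipsilateral, i.e. about
#' 40,000 ipsi vs 10,000 contra).
#'
#' @param atlas an `lha_atlas`; region volumes implied by `ap_range`/`ap_step`
#'   calibrate the absolute density scale.
#' @param n_per_genotype brains per genotype (default 6).
#' @param genotypes genotype labels; the first is the reference.
#' @param total_neurons expected total labelled somata per reference brain.
#' @param region_density optional named vector of somata per mm^3 for the
#'   reference genotype; overrides the calibrated default.
#' @param effect_map named list `genotype -> named numeric vector` of
#'   multiplicative count factors per region (unlisted regions: 1).
#' @param lha_atrophy named vector of LHA linear volume scale factors in
#'   (0, 1] per genotype (area scales with factor^(2/3) per section so that
#'   volume scales with the factor).
#' @param contra_fraction fraction of labelled somata on the contralateral
#'   side (default 0.2).
#' @param dispersion optional negative-binomial size parameter; `NULL` for
#'   pure Poisson counts.
#' @param ap_range,ap_step anterior-posterior extent (mm) and section spacing
#'   (mm; 0.07 = every 70-um section).
#' @param pixel_size_mm pixel pitch of rendered sections.
#' @param noise list of rendering parameters: `bg_mean`, `bg_sd`,
#'   `bg_field_amp` (smooth autofluorescence amplitude), `soma_peak` (range),
#'   `soma_radius_px` (range), `dendrite_rate` (artifacts per tile/section),
#'   `tile_mean_count`, `tile_bg_prob`.
#' @param injection list: `side`, `ap`, `volume_mm3`, `backflow_fraction`,
#'   `intensity`.
#' @param seed cohort seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(atlas,
                          n_per_genotype = 6L,
                          genotypes = c("WT", "mSOD1"),
                          total_neurons = 50000,
                          region_density = NULL,
                          effect_map = list(),
                          lha_atrophy = c(mSOD1 = 0.75),
                          contra_fraction = 0.2,
                          dispersion = NULL,
                          ap_range = c(2.6, -3.0),
                          ap_step = 0.07,
                          pixel_size_mm = 0.015,
                          noise = list(),
                          injection = list(),
                          seed = 1L) {
  stopifnot(contra_fraction >= 0, contra_fraction <= 1,
            n_per_genotype >= 1, ap_step > 0, pixel_size_mm > 0)
  noise_def <- list(bg_mean = 100, bg_sd = 10, bg_field_amp = 25,
                    soma_peak = c(300, 600), soma_radius_px = c(2, 4),
                    dendrite_rate = 1.5, tile_mean_count = 18,
                    tile_bg_prob = 0.1)
  noise <- utils::modifyList(noise_def, noise)
  inj_def <- list(side = "L", ap = -1.2, volume_mm3 = 0.5,
                  backflow_fraction = 0, intensity = 3000)
  injection <- utils::modifyList(inj_def, injection)
  vols <- atlas_region_volumes(atlas, ap_range, ap_step)
  if (is.null(region_density)) {
    rel <- default_density_profile(names(vols))
    scale <- total_neurons / sum(rel[names(vols)] * vols)
    region_density <- rel[names(vols)] * scale
    names(region_density) <- names(vols)
  }
  if (any(region_density < 0)) stop("densities must be >= 0")
  for (g in names(effect_map)) if (any(unlist(effect_map[[g]]) <= 0))
    stop("effect factors must be > 0")
  if (any(lha_atrophy <= 0 | lha_atrophy > 1))
    stop("lha_atrophy factors must lie in (0, 1]")
  structure(list(
    n_per_genotype = as.integer(n_per_genotype), genotypes = genotypes,
    region_density = region_density, effect_map = effect_map,
    lha_atrophy = lha_atrophy, contra_fraction = contra_fraction,
    dispersion = dispersion, ap_range = ap_range, ap_step = ap_step,
    pixel_size_mm = pixel_size_mm, noise = noise, injection = injection,
    seed = as.integer(seed)), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Synthetic cohort design:", paste(x$genotypes, collapse = "/"),
      sprintf("x %d brains, %d regions, AP %+.1f..%+.1f step %.0f um\n",
              x$n_per_genotype, length(x$region_density),
              x$ap_range[1], x$ap_range[2], 1000 * x$ap_step))
  invisible(x)
}

## Relative soma density profile (arbitrary units, rescaled by the design):
## limbic/orbital areas project most densely to the LHA, motor and sensory
## cortex moderately, small nuclei sparsely.
default_density_profile <- function(regions) {
  rel <- c(ACA = 10, PL = 10, ILA = 9, AI = 8, ORBl = 6, ORBvl = 6, ORBm = 5,
           BLA = 6, BMA = 5, TT = 4, PIR = 3.5, MOs = 4, MOp = 2.5, SS = 1.2,
           ACB = 3, CP = 1.0, DMH = 6, VMH = 4, PVH = 5, LHA = 8)
  out <- rel[regions]
  out[is.na(out)] <- 1
  names(out) <- regions
  out
}

effect_factor <- function(design, genotype, region) {
  em <- design$effect_map[[genotype]]
  if (is.null(em)) return(1)
  f <- unlist(em)[region]
  if (is.null(f) || is.na(f)) 1 else as.numeric(f)
}

lha_scale_of <- function(design, genotype) {
  s <- unlist(design$lha_atrophy)[genotype]
  if (is.null(s) || is.na(s)) 1 else as.numeric(s)
}

#' Simulate one brain's serial sections with ground truth
#'
#' Draws per-(region, hemisphere, section) soma counts from the design's
#' expectation (density x sectional volume x genotype effect x hemisphere
#' share), places somata uniformly inside the region outlines, and (if
#' `render = TRUE`) renders each section: smooth autofluorescence field plus
#' Gaussian noise, somata as isotropic Gaussian blobs, thin bright dendritic
#' fragments, and the injection-site blob. LHA outlines are shrunk about
#' their centroid for atrophied genotypes before sampling and rendering, so
#' both the rendered area and the truth volume scale.
#'
#' @param atlas an `lha_atlas`.
#' @param design a `cohort_design`.
#' @param genotype genotype label (must appear in the design).
#' @param brain_seed integer seed for this brain (see [seed_child()]).
#' @param brain_id identifier stamped on sections and truth tables.
#' @param render render images (`TRUE`) or produce geometry/truth only.
#' @param store_dots keep per-section soma positions and labels in the
#'   output (for validation studies).
#' @return A `brain_dataset`: `sections` (list of `ap_mm`, `plate`, `image`,
#'   `landmarks` in px, `frame`), `truth` (counts per region x hemisphere and
#'   ipsi/contra, volumes, totals), `injection` (per-section areas, volume,
#'   backflow fraction), plus identifiers.
#' @export
simulate_brain <- function(atlas, design, genotype, brain_seed,
                           brain_id = paste0(genotype, "_", brain_seed),
                           render = TRUE, store_dots = FALSE) {
  if (!genotype %in% design$genotypes)
    stop("genotype '", genotype, "' not in design")
  aps <- seq(design$ap_range[1], design$ap_range[2], by = -design$ap_step)
  px <- design$pixel_size_mm
  th <- atlas$section_thickness_mm
  lha_s <- lha_scale_of(design, genotype)
  ## linear in-plane shrink so that the volume scales by lha_s
  lha_lin <- lha_s^(1 / 2) # area factor lha_s per section; AP extent kept
  frame_nrow <- as.integer(ceiling(4.8 / px))
  frame_ncol <- as.integer(ceiling(5.8 / px))
  frame <- make_frame(x0 = -2.9, y0 = 4.7, pixel_size_mm = px,
                      nrow = frame_nrow, ncol = frame_ncol)
  leaves <- setdiff(atlas$regions$id,
                    atlas$regions$parent[!is.na(atlas$regions$parent)])
  inj <- injection_geometry(atlas, design)
  counts <- list(); vols <- numeric(0)
  sections <- vector("list", length(aps))
  side <- design$injection$side
  for (si in seq_along(aps)) {
    s_ap <- aps[si]
    set.seed(seed_child(brain_seed, si))
    k <- nearest_plate(atlas, s_ap)
    pl <- atlas$plates[[k]]
    dots_all <- NULL
    for (o in pl$outlines) {
      if (!o$region %in% leaves) next
      poly <- o$polygon
      if (o$region == "LHA" && lha_lin < 1) poly <- poly_scale(poly, lha_lin)
      area <- poly_area(poly)
      vols[o$region] <- (if (is.null(vols[o$region]) || is.na(vols[o$region])) 0
                         else vols[o$region]) + area * th
      dens <- design$region_density[[o$region]]
      if (is.null(dens) || is.na(dens)) dens <- 0
      share <- if (o$hemisphere == side) 2 * (1 - design$contra_fraction)
               else 2 * design$contra_fraction
      mu <- dens * area * th * effect_factor(design, genotype, o$region) * share
      n <- if (is.null(design$dispersion)) stats::rpois(1, mu)
           else stats::rnbinom(1, size = design$dispersion, mu = mu)
      key <- paste(o$region, o$hemisphere, sep = ".")
      counts[[key]] <- (counts[[key]] %||% 0L) + n
      if (n > 0) {
        pts <- sample_in_poly(n, poly)
        dots_all <- rbind(dots_all, data.frame(
          x = pts[, 1], y = pts[, 2], region = o$region,
          side_lr = o$hemisphere))
      }
    }
    img <- NULL
    lmk_px <- NULL
    pxy <- frame_mm_to_px(frame, pl$landmarks$x, pl$landmarks$y)
    lmk_px <- data.frame(name = pl$landmarks$name,
                         x = pxy[, "col"], y = pxy[, "row"])
    if (render) {
      img <- render_background(frame_nrow, frame_ncol, design$noise)
      if (!is.null(dots_all)) {
        dpx <- frame_mm_to_px(frame, dots_all$x, dots_all$y)
        img <- render_somata(img, dpx[, "col"], dpx[, "row"], design$noise)
      }
      img <- render_dendrites(img, design$noise,
                              n_seg = stats::rpois(1, 4 * design$noise$dendrite_rate))
      img <- render_injection(img, frame, inj, s_ap)
      img[img < 0] <- 0
    }
    sections[[si]] <- list(ap_mm = s_ap, plate = k, image = img,
                           landmarks = lmk_px, frame = frame,
                           dots = if (store_dots) dots_all)
  }
  cnt <- truth_count_table(counts, side)
  structure(list(
    brain_id = brain_id, genotype = genotype, seed = brain_seed,
    pixel_size_mm = px, sections = sections,
    injection = injection_truth(inj, aps, th, design),
    truth = list(counts = cnt, volumes = vols, total = sum(cnt$count),
                 lha_scale = lha_s)),
    class = "brain_dataset")
}

#' @export
print.brain_dataset <- function(x, ...) {
  cat(sprintf("Brain %s (%s): %d sections, %d labelled somata (truth)\n",
              x$brain_id, x$genotype, length(x$sections), x$truth$total))
  invisible(x)
}

truth_count_table <- function(counts, side) {
  if (length(counts) == 0L)
    return(data.frame(region = character(), hemisphere = character(),
                      side_lr = character(), count = integer()))
  keys <- strsplit(names(counts), ".", fixed = TRUE)
  data.frame(
    region = vapply(keys, `[[`, character(1), 1),
    side_lr = vapply(keys, `[[`, character(1), 2),
    hemisphere = ifelse(vapply(keys, `[[`, character(1), 2) == side,
                        "ipsi", "contra"),
    count = as.integer(unlist(counts)), row.names = NULL)
}

## Uniform rejection sampling inside a polygon.
sample_in_poly <- function(n, poly) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    x <- stats::runif(m, xr[1], xr[2]); y <- stats::runif(m, yr[1], yr[2])
    ok <- point_in_poly(x, y, poly)
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

## --- rendering primitives -------------------------------------------------

bilinear_field <- function(nrow, ncol, knots = 7L) {
  g <- matrix(stats::rnorm(knots * knots), knots, knots)
  rows <- seq(1, knots, length.out = nrow)
  cols <- seq(1, knots, length.out = ncol)
  ## separable linear interpolation
  ri <- pmin(floor(rows), knots - 1L); rf <- rows - ri
  ci <- pmin(floor(cols), knots - 1L); cf <- cols - ci
  a <- g[ri, ci, drop = FALSE] * outer(1 - rf, 1 - cf) +
       g[ri + 1L, ci, drop = FALSE] * outer(rf, 1 - cf) +
       g[ri, ci + 1L, drop = FALSE] * outer(1 - rf, cf) +
       g[ri + 1L, ci + 1L, drop = FALSE] * outer(rf, cf)
  a
}

render_background <- function(nrow, ncol, noise) {
  noise$bg_mean + noise$bg_field_amp * bilinear_field(nrow, ncol) +
    matrix(stats::rnorm(nrow * ncol, 0, noise$bg_sd), nrow, ncol)
}

## Add isotropic Gaussian blobs at (col, row) positions.
render_somata <- function(img, cols, rows, noise) {
  n <- length(cols)
  if (n == 0L) return(img)
  radius <- stats::runif(n, noise$soma_radius_px[1], noise$soma_radius_px[2])
  peak <- stats::runif(n, noise$soma_peak[1], noise$soma_peak[2])
  for (i in seq_len(n)) {
    sg <- radius[i] / 2
    hw <- ceiling(3 * sg)
    r0 <- round(rows[i]); c0 <- round(cols[i])
    rr <- (r0 - hw):(r0 + hw); cc <- (c0 - hw):(c0 + hw)
    keep_r <- rr >= 1 & rr <= nrow(img); keep_c <- cc >= 1 & cc <= ncol(img)
    if (!any(keep_r) || !any(keep_c)) next
    gy <- exp(-((rr[keep_r] - rows[i])^2) / (2 * sg^2))
    gx <- exp(-((cc[keep_c] - cols[i])^2) / (2 * sg^2))
    img[rr[keep_r], cc[keep_c]] <- img[rr[keep_r], cc[keep_c]] +
      peak[i] * outer(gy, gx)
  }
  img
}

## Thin bright curvilinear segments emulating dendrite fragments.
render_dendrites <- function(img, noise, n_seg) {
  if (n_seg <= 0) return(img)
  for (i in seq_len(n_seg)) {
    r <- stats::runif(1, 5, nrow(img) - 5)
    c <- stats::runif(1, 5, ncol(img) - 5)
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 8, 22)
    amp <- stats::runif(1, 0.3, 0.6) *
      mean(noise$soma_peak)
    t <- seq(0, len, by = 0.5)
    curv <- stats::runif(1, -0.03, 0.03)
    rr <- round(r + t * sin(ang + curv * t))
    cc <- round(c + t * cos(ang + curv * t))
    ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
    img[cbind(rr[ok], cc[ok])] <- img[cbind(rr[ok], cc[ok])] + amp
  }
  img
}

## --- injection site -------------------------------------------------------

## Geometry of the injection: a sphere centred in the LHA plus an optional
## dorsal backflow column along the capillary track.
injection_geometry <- function(atlas, design) {
  inj <- design$injection
  k <- nearest_plate(atlas, inj$ap)
  pl <- atlas$plates[[k]]
  os <- plate_outlines(pl, "LHA", inj$side)
  if (length(os) == 0L) stop("no LHA outline at the injection AP")
  ctr <- poly_centroid(os[[1]]$polygon)
  y_d <- region_dorsal_y(pl, "LHA")
  R <- (3 * inj$volume_mm3 / (4 * pi))^(1 / 3)
  ## dorsal cap of the sphere above the LHA dorsal boundary
  hcap <- max(0, ctr[2] + R - y_d)
  vcap <- pi * hcap^2 * (3 * R - hcap) / 3
  f <- inj$backflow_fraction
  vb <- if (f > 0) max(0, (f * inj$volume_mm3 - vcap) / (1 - f)) else 0
  rb <- 0.12
  list(center = ctr, ap = inj$ap, R = R, side = inj$side, y_dorsal = y_d,
       v_main = inj$volume_mm3, v_back = vb, r_back = rb,
       intensity = inj$intensity)
}

## Cross-section radius of the main sphere at AP offset d.
inj_disc_radius <- function(geom, s_ap) {
  d2 <- geom$R^2 - (s_ap - geom$ap)^2
  if (d2 <= 0) 0 else sqrt(d2)
}

## Area of a disc of radius r centred at yc lying above the line y = yd.
disc_area_above <- function(r, yc, yd) {
  if (r <= 0) return(0)
  if (yd <= yc - r) return(pi * r^2)
  if (yd >= yc + r) return(0)
  h <- yc + r - yd                       # cap height
  r^2 * acos(1 - h / r) - (r - h) * sqrt(2 * r * h - h^2)
}

## AP half-extent of the backflow column (rendered on sections within
## +/- 1.5 section steps of the injection AP).
backflow_sections <- function(geom, design) 1.5 * design$ap_step

render_injection <- function(img, frame, geom, s_ap) {
  r <- inj_disc_radius(geom, s_ap)
  if (r > 0) {
    ctr_px <- frame_mm_to_px(frame, geom$center[1], geom$center[2])
    rpx <- r / frame$px
    img <- add_disc(img, ctr_px[1, "col"], ctr_px[1, "row"], rpx, geom$intensity)
  }
  if (geom$v_back > 0 && abs(s_ap - geom$ap) <= 1.5 * 0.07 + 1e-9) {
    ## not knowing the design step here, use the physical 70-um spacing:
    ## the column is rendered on sections within ~100 um of the track
    n_sec <- 3
    h <- geom$v_back / (n_sec * 0.07 * 2 * geom$r_back)
    x0 <- geom$center[1] - geom$r_back; x1 <- geom$center[1] + geom$r_back
    y0 <- geom$y_dorsal; y1 <- geom$y_dorsal + h
    p <- frame_mm_to_px(frame, c(x0, x1), c(y1, y0))
    rr <- max(1, round(p[1, "row"])):min(nrow(img), round(p[2, "row"]))
    cc <- max(1, round(p[1, "col"])):min(ncol(img), round(p[2, "col"]))
    img[rr, cc] <- img[rr, cc] + geom$intensity
  }
  img
}

add_disc <- function(img, c0, r0, rpx, intensity) {
  hw <- ceiling(rpx)
  rr <- max(1, round(r0) - hw):min(nrow(img), round(r0) + hw)
  cc <- max(1, round(c0) - hw):min(ncol(img), round(c0) + hw)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sub <- img[rr, cc, drop = FALSE]
  sub[d2 <= rpx^2] <- sub[d2 <= rpx^2] + intensity
  img[rr, cc] <- sub
  img
}

## Exact per-section truth for the injection: areas, volume, backflow.
injection_truth <- function(geom, aps, thickness, design) {
  areas <- vapply(aps, function(s) {
    r <- inj_disc_radius(geom, s)
    a <- if (r > 0) pi * r^2 else 0
    if (geom$v_back > 0 && abs(s - geom$ap) <= 1.5 * 0.07 + 1e-9)
      a <- a + geom$v_back / (3 * 0.07)
    a
  }, numeric(1))
  dorsal <- vapply(aps, function(s) {
    r <- inj_disc_radius(geom, s)
    a <- disc_area_above(r, geom$center[2], geom$y_dorsal)
    if (geom$v_back > 0 && abs(s - geom$ap) <= 1.5 * 0.07 + 1e-9)
      a <- a + geom$v_back / (3 * 0.07)
    a
  }, numeric(1))
  vol <- sum(areas) * thickness
  list(side = geom$side, center = geom$center, ap = geom$ap,
       areas_mm2 = areas, volume_mm3 = vol,
       backflow_fraction = if (vol > 0) sum(dorsal) * thickness / vol else 0,
       y_dorsal = geom$y_dorsal, intensity = geom$intensity)
}

## --- annotated training tiles --------------------------------------------

#' Simulate dot-annotated soma images for counter training
#'
#' Generates square tiles with known soma centroids spanning low to high
#' density, including neuron-free background tiles, with the same rendering
#' model as whole sections (smooth background, noise, Gaussian somata,
#' dendritic fragments).
#'
#' @param design a `cohort_design` (its `noise` block drives rendering).
#' @param n_images number of tiles (> 0).
#' @param seed integer seed.
#' @param tile_px tile side length in px.
#' @return List of `annotated_image` objects: `image`, `dots` (n x 2 matrix
#'   of (col, row) centroids), `fg_mask` (logical soma-signal mask).
#' @export
simulate_training_set <- function(design, n_images, seed, tile_px = 96L) {
  if (n_images <= 0) stop("n_images must be > 0")
  lapply(seq_len(n_images), function(i) {
    set.seed(seed_child(seed, i))
    simulate_tile(design$noise, tile_px)
  })
}

simulate_tile <- function(noise, tile_px) {
  n <- if (stats::runif(1) < noise$tile_bg_prob) 0L else {
    lambda <- stats::runif(1, 0.3, 1.7) * noise$tile_mean_count
    stats::rpois(1, lambda)
  }
  margin <- 4
  dots <- if (n > 0)
    cbind(col = stats::runif(n, margin, tile_px - margin),
          row = stats::runif(n, margin, tile_px - margin))
  else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("col", "row")))
  img <- render_background(tile_px, tile_px, noise)
  soma <- matrix(0, tile_px, tile_px)
  if (n > 0) soma <- render_somata(soma, dots[, "col"], dots[, "row"], noise)
  img <- img + soma
  img <- render_dendrites(img, noise, stats::rpois(1, noise$dendrite_rate))
  img[img < 0] <- 0
  structure(list(image = img, dots = dots,
                 fg_mask = soma > 0.15 * noise$soma_peak[1]),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("Annotated image: %d x %d px, %d dot annotations\n",
              nrow(x$image), ncol(x$image), nrow(x$dots)))
  invisible(x)
}

#' Simulate a misfolded-protein burden image with known truth
#'
#' Blobby foreground occupying (close to) the requested area fraction on a
#' smooth intensity-gradient background. The foreground mask is obtained by
#' thresholding a smooth random field at the appropriate quantile, so the
#' realised fraction matches the request up to discretisation.
#'
#' @param area_fraction target above-background area fraction in \[0, 1\].
#' @param seed integer seed.
#' @param size image side length in px.
#' @param contrast foreground intensity lift over the background.
#' @return List with `image`, `truth_mask` (logical), `truth_fraction`.
#' @export
simulate_burden_image <- function(area_fraction, seed, size = 192L,
                                  contrast = 120) {
  if (is.na(area_fraction) || area_fraction < 0 || area_fraction > 1)
    stop("area_fraction must lie in [0, 1]")
  set.seed(seed)
  ramp <- outer(seq(0, 60, length.out = size), seq(0, 40, length.out = size), "+")
  field <- bilinear_field(size, size, knots = 13L)
  mask <- if (area_fraction == 0) matrix(FALSE, size, size)
          else field >= stats::quantile(field, 1 - area_fraction)
  img <- 60 + ramp + 6 * bilinear_field(size, size, knots = 5L) +
    matrix(stats::rnorm(size * size, 0, 3), size, size)
  img[mask] <- img[mask] + contrast * (0.7 + 0.3 * field[mask] / max(field))
  img[img < 0] <- 0
  list(image = img, truth_mask = mask, truth_fraction = mean(mask))
}

## --- count-level cohort simulation (for the statistical benchmarks) ------

#' Simulate a cohort at the count-table level
#'
#' Draws per-brain, per-structure counts directly (no image rendering) for
#' statistical operating-characteristic studies: Poisson counts around
#' structure baselines, multiplied by genotype x structure effects, with an
#' optional negative-binomial brain-level dispersion.
#'
#' @param n_per_genotype brains per genotype.
#' @param genotypes genotype labels (first = reference).
#' @param baseline named vector of expected counts per structure for the
#'   reference genotype.
#' @param effect_map named list `genotype -> named vector` of multiplicative
#'   effects (unlisted structures: 1).
#' @param seed integer seed.
#' @param dispersion optional negative-binomial size; `NULL` = Poisson.
#' @return data.frame with columns `brain`, `genotype`, `structure`, `count`.
#' @export
simulate_count_cohort <- function(n_per_genotype, genotypes, baseline,
                                  effect_map = list(), seed = 1L,
                                  dispersion = NULL) {
  set.seed(seed)
  rows <- list()
  for (g in genotypes) for (b in seq_len(n_per_genotype)) {
    mu <- baseline
    em <- effect_map[[g]]
    if (!is.null(em)) {
      idx <- intersect(names(em), names(mu))
      mu[idx] <- mu[idx] * unlist(em[idx])
    }
    n <- if (is.null(dispersion)) stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), size = dispersion, mu = mu)
    rows[[length(rows) + 1L]] <- data.frame(
      brain = paste0(g, b), genotype = g, structure = names(mu), count = n,
      row.names = NULL)
  }
  do.call(rbind, rows)
}
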