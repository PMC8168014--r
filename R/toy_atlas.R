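## Construction of the packaged synthetic ("toy") atlas.  The atlas is a
## deliberately simplified forebrain: per-plate brain outlines are half
## ellipses and regions are rectangles placed inside them, but the region
## ontology, the naming, the AP layout (prefrontal/orbital areas anteriorly,
## hypothalamic nuclei and amygdala posteriorly) and the landmark mechanics
## mirror a real coronal reference atlas.  The packaged
## `inst/extdata/toy_atlas.json` is written by `build_toy_atlas()`; the
## builder is exported so the fixture is fully reproducible from code.

toy_regions <- function() {
  r <- function(id, name, parent = NA, pool = NA)
    data.frame(id = id, name = name, parent = parent, pool = pool,
               stringsAsFactors = FALSE)
  rbind(
    r("ROOT", "brain"),
    r("CTX", "cerebral cortex", "ROOT"),
    r("STR", "striatum", "ROOT"),
    r("HY", "hypothalamus", "ROOT"),
    r("AMY", "amygdala", "ROOT"),
    r("MOs", "secondary motor area", "CTX"),
    r("MOp", "primary motor area", "CTX"),
    r("SS", "somatosensory areas", "CTX"),
    r("ACA", "anterior cingulate area", "CTX"),
    r("PL", "prelimbic area", "CTX", "PL+ORBm"),
    r("ILA", "infralimbic area", "CTX"),
    r("ORBm", "orbital area, medial part", "CTX", "PL+ORBm"),
    r("ORBl", "orbital area, lateral part", "CTX", "ORBl/vl+AI"),
    r("ORBvl", "orbital area, ventrolateral part", "CTX", "ORBl/vl+AI"),
    r("AI", "agranular insular area", "CTX", "ORBl/vl+AI"),
    r("PIR", "piriform area", "CTX"),
    r("TT", "taenia tecta", "CTX"),
    r("ACB", "nucleus accumbens", "STR"),
    r("CP", "caudoputamen", "STR"),
    r("LHA", "lateral hypothalamic area", "HY"),
    r("DMH", "dorsomedial nucleus of the hypothalamus", "HY"),
    r("VMH", "ventromedial hypothalamic nucleus", "HY"),
    r("PVH", "paraventricular hypothalamic nucleus", "HY"),
    r("BLA", "basolateral amygdalar nucleus", "AMY"),
    r("BMA", "basomedial amygdalar nucleus", "AMY"))
}

## Half-ellipse brain outline for one hemisphere; w = half width, h = height.
outline_half <- function(w, h, side) {
  phi <- seq(pi / 2, 3 * pi / 2, length.out = 9)
  x <- w * cos(phi); y <- h / 2 + (h / 2) * sin(phi)
  if (side == "R") x <- -x
  cbind(round(x, 4), round(y, 4))
}

## Rectangle inside the ellipse: y band as fractions of h, x band as
## fractions of the safe (ellipse-limited) half width over that band.
band_rect <- function(w, h, ylo, yhi, xlo, xhi, side) {
  y0 <- h * ylo; y1 <- h * yhi
  half_at <- function(y) w * sqrt(pmax(0, 1 - (2 * y / h - 1)^2))
  safe <- 0.93 * min(half_at(y0), half_at(y1))
  x0 <- safe * xlo; x1 <- safe * xhi
  s <- if (side == "L") -1 else 1
  m <- cbind(s * c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  round(m[, , drop = FALSE], 4)
}

## Region layout per AP bracket: list of (region, ylo, yhi, xlo, xhi).
toy_layout <- function(ap) {
  L <- list()
  add <- function(id, ylo, yhi, xlo, xhi) L[[length(L) + 1L]] <<-
    list(id = id, ylo = ylo, yhi = yhi, xlo = xlo, xhi = xhi)
  if (ap >= 1.8) {              # prefrontal / orbital plates
    add("MOs", 0.84, 0.93, 0.06, 0.40)
    add("MOp", 0.66, 0.82, 0.48, 0.80)
    add("PL", 0.62, 0.80, 0.03, 0.22)
    add("ILA", 0.44, 0.60, 0.03, 0.22)
    add("ORBm", 0.26, 0.42, 0.03, 0.22)
    add("ORBvl", 0.26, 0.42, 0.26, 0.50)
    add("ORBl", 0.26, 0.42, 0.54, 0.80)
    add("AI", 0.44, 0.60, 0.56, 0.86)
    add("TT", 0.08, 0.22, 0.06, 0.30)
  } else if (ap >= 0.8) {       # pregenual plates
    add("MOs", 0.86, 0.94, 0.06, 0.42)
    add("MOp", 0.70, 0.84, 0.46, 0.78)
    add("ACA", 0.68, 0.83, 0.03, 0.20)
    add("PL", 0.52, 0.66, 0.03, 0.20)
    add("ILA", 0.38, 0.50, 0.03, 0.20)
    add("SS", 0.52, 0.68, 0.60, 0.90)
    add("AI", 0.36, 0.50, 0.60, 0.90)
    add("ACB", 0.26, 0.40, 0.26, 0.50)
    add("PIR", 0.08, 0.24, 0.52, 0.84)
    add("TT", 0.08, 0.24, 0.06, 0.30)
  } else if (ap >= -0.3) {      # level of the crossing / anterior striatum
    add("MOs", 0.87, 0.95, 0.06, 0.40)
    add("MOp", 0.72, 0.86, 0.44, 0.76)
    add("ACA", 0.71, 0.85, 0.03, 0.18)
    add("SS", 0.52, 0.70, 0.60, 0.92)
    add("CP", 0.44, 0.68, 0.24, 0.54)
    add("AI", 0.34, 0.50, 0.62, 0.92)
    add("PIR", 0.10, 0.28, 0.50, 0.84)
  } else if (ap >= -1.3) {      # tuberal hypothalamus, anterior amygdala
    add("MOs", 0.87, 0.95, 0.06, 0.36)
    add("MOp", 0.72, 0.86, 0.42, 0.74)
    add("ACA", 0.71, 0.85, 0.03, 0.18)
    add("SS", 0.50, 0.70, 0.60, 0.92)
    add("CP", 0.46, 0.68, 0.24, 0.54)
    add("PVH", 0.44, 0.52, 0.03, 0.13)
    add("LHA", 0.22, 0.42, 0.16, 0.473)
    add("VMH", 0.03, 0.12, 0.06, 0.26)
    add("BMA", 0.06, 0.20, 0.44, 0.60)
    add("BLA", 0.22, 0.38, 0.58, 0.82)
    add("PIR", 0.06, 0.20, 0.64, 0.88)
  } else {                      # posterior hypothalamus / amygdala
    add("SS", 0.52, 0.72, 0.58, 0.90)
    add("DMH", 0.44, 0.54, 0.03, 0.15)
    add("LHA", 0.22, 0.42, 0.16, 0.473)
    add("VMH", 0.03, 0.12, 0.06, 0.26)
    add("BMA", 0.06, 0.20, 0.44, 0.60)
    add("BLA", 0.22, 0.38, 0.58, 0.82)
    add("PIR", 0.06, 0.20, 0.64, 0.88)
  }
  L
}

## Plate landmarks; the named set is shared across plates but the geometric
## configuration varies non-affinely with AP so that plate assignment by fit
## residual is well posed.
toy_landmarks <- function(ap, w, h) {
  th <- (50 + 18 * sin(1.3 * ap)) * pi / 180
  fx_y <- h * (0.38 + 0.07 * sin(2.1 * ap + 1))
  lm <- rbind(
    data.frame(name = "dorsal_midline", x = 0, y = h),
    data.frame(name = "ventral_midline", x = 0, y = 0),
    data.frame(name = "lateral_left", x = -w, y = h / 2),
    data.frame(name = "lateral_right", x = w, y = h / 2),
    data.frame(name = "dorsolateral_left", x = -w * cos(th),
               y = h / 2 + (h / 2) * sin(th)),
    data.frame(name = "dorsolateral_right", x = w * cos(th),
               y = h / 2 + (h / 2) * sin(th)),
    data.frame(name = "fornix_left", x = -0.25 * w, y = fx_y))
  lm$x <- round(lm$x, 4); lm$y <- round(lm$y, 4)
  lm
}

#' Build the packaged toy atlas
#'
#' Constructs the synthetic coronal atlas shipped with the package: 25
#' regions (including LHA and the other hypothalamic nuclei, the prefrontal,
#' orbital and insular areas, motor and sensory cortex, piriform cortex,
#' taenia tecta and amygdalar nuclei), 13 plates from AP +2.6 mm to -3.0 mm,
#' and 7 named landmarks per plate. The LHA outlines are sized so that a
#' serial 70-um reconstruction of the unatrophied LHA comes to about
#' 2.75 mm^3 bilaterally.
#'
#' @return A validated `lha_atlas` object.
#' @seealso [load_atlas()], [save_atlas_json()]
#' @export
build_toy_atlas <- function() {
  ap <- c(2.6, 2.2, 1.8, 1.4, 1.0, 0.5, 0.0, -0.5, -1.0, -1.5, -2.0, -2.5, -3.0)
  wv <- c(1.6, 1.9, 2.1, 2.3, 2.4, 2.5, 2.6, 2.6, 2.6, 2.5, 2.4, 2.3, 2.1)
  hv <- c(2.6, 3.0, 3.3, 3.5, 3.6, 3.8, 4.0, 4.2, 4.3, 4.3, 4.2, 4.0, 3.8)
  plates <- vector("list", length(ap))
  for (k in seq_along(ap)) {
    w <- wv[k]; h <- hv[k]
    outlines <- list(
      list(region = "ROOT", hemisphere = "L", polygon = outline_half(w, h, "L")),
      list(region = "ROOT", hemisphere = "R", polygon = outline_half(w, h, "R")))
    for (lay in toy_layout(ap[k])) for (side in c("L", "R"))
      outlines[[length(outlines) + 1L]] <- list(
        region = lay$id, hemisphere = side,
        polygon = band_rect(w, h, lay$ylo, lay$yhi, lay$xlo, lay$xhi, side))
    plates[[k]] <- list(ap_mm = ap[k], midline_x = 0,
                        landmarks = toy_landmarks(ap[k], w, h),
                        outlines = outlines)
  }
  atlas <- structure(
    list(regions = toy_regions(), plates = plates,
         section_thickness_mm = 0.07, schema_version = 1L),
    class = "lha_atlas")
  validate_atlas(atlas)
  atlas
}

#' Write an atlas to its JSON interchange format
#'
#' Serialises an `lha_atlas` to the versioned JSON schema read by
#' [load_atlas()]: a `regions` list (id, name, parent, pool) and a `plates`
#' list ({ap_mm, midline_x, landmarks, outlines: {region, hemisphere,
#' polygon: [[x, y], ...]}}).
#'
#' @param atlas an `lha_atlas`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_atlas_json <- function(atlas, path) {
  reg <- lapply(seq_len(nrow(atlas$regions)), function(i) {
    r <- atlas$regions[i, ]
    out <- list(id = r$id, name = r$name)
    if (!is.na(r$parent)) out$parent <- r$parent
    if (!is.na(r$pool)) out$pool <- r$pool
    out
  })
  plates <- lapply(atlas$plates, function(p) list(
    ap_mm = p$ap_mm, midline_x = p$midline_x,
    landmarks = lapply(seq_len(nrow(p$landmarks)), function(i)
      list(name = p$landmarks$name[i], x = p$landmarks$x[i], y = p$landmarks$y[i])),
    outlines = lapply(p$outlines, function(o) list(
      region = o$region, hemisphere = o$hemisphere,
      polygon = lapply(seq_len(nrow(o$polygon)), function(i)
        as.numeric(o$polygon[i, ]))))))
  obj <- list(schema_version = atlas$schema_version,
              section_thickness_mm = atlas$section_thickness_mm,
              regions = reg, plates = plates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Per-region bilateral volume implied by a serial reconstruction of the
## atlas itself: every `step` mm a section takes the outline areas of its
## nearest plate; volume = sum(area) * thickness.
atlas_region_volumes <- function(atlas, ap_range = c(2.6, -3.0), step = 0.07,
                                 thickness = atlas$section_thickness_mm,
                                 lha_scale = 1) {
  aps <- seq(ap_range[1], ap_range[2], by = -step)
  vols <- numeric(0)
  for (s in aps) {
    pl <- atlas$plates[[nearest_plate(atlas, s)]]
    for (o in pl$outlines) {
      if (o$region == "ROOT") next
      a <- poly_area(o$polygon)
      if (o$region == "LHA") a <- a * lha_scale^2
      vols[o$region] <- (if (is.na(vols[o$region])) 0 else vols[o$region]) + a
    }
  }
  vols * thickness
}
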