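## Atlas model: a hierarchical region ontology plus per-plate 2-D polygon
## outlines along the anterior-posterior (AP) axis.  The package ships a
## self-contained synthetic ("toy") atlas with the topology of the named
## forebrain regions (LHA and other hypothalamic nuclei, prefrontal/orbital
## areas, motor/sensory cortex, amygdala, ...) so that registration,
## parcellation and quantification are fully testable offline.  It is not a
## redistribution of any reference atlas.
##
## Coordinate conventions: atlas space in mm; x increases rightward, y
## increases dorsally; AP in mm relative to bregma. The midline is at
## `midline_x` on every plate.

#' Load an atlas from its JSON description
#'
#' Reads and validates an atlas file: a region ontology (unique ids, acyclic
#' parent links, many-to-one pooling map) and a list of coronal plates ordered
#' by decreasing AP coordinate, each holding named landmarks and closed region
#' outlines per hemisphere. Validation errors name the offending region or
#' plate.
#'
#' @param path path to the atlas JSON file. Defaults to the packaged toy
#'   atlas.
#' @return An object of class `lha_atlas` with elements `regions`
#'   (data.frame: id, name, parent, pool), `plates` (list of plates, each with
#'   `ap_mm`, `midline_x`, `landmarks`, `outlines`), and
#'   `section_thickness_mm`.
#' @examples
#' atlas <- load_atlas()
#' atlas
#' @export
load_atlas <- function(path = system.file("extdata", "toy_atlas.json",
                                          package = "lhatrace")) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  regions <- do.call(rbind, lapply(raw$regions, function(r) {
    data.frame(id = r$id, name = r$name %||% r$id,
               parent = if (is.null(r$parent)) NA_character_ else r$parent,
               pool = if (is.null(r$pool)) NA_character_ else r$pool,
               stringsAsFactors = FALSE)
  }))
  plates <- lapply(raw$plates, function(p) {
    lm <- do.call(rbind, lapply(p$landmarks, function(l)
      data.frame(name = l$name, x = l$x, y = l$y, stringsAsFactors = FALSE)))
    outlines <- lapply(p$outlines, function(o) {
      list(region = o$region, hemisphere = o$hemisphere,
           polygon = do.call(rbind, lapply(o$polygon, unlist)))
    })
    list(ap_mm = p$ap_mm, midline_x = p$midline_x %||% 0,
         landmarks = lm, outlines = outlines)
  })
  atlas <- structure(
    list(regions = regions, plates = plates,
         section_thickness_mm = raw$section_thickness_mm %||% 0.07,
         schema_version = raw$schema_version %||% 1L),
    class = "lha_atlas")
  validate_atlas(atlas)
  atlas
}

#' @export
print.lha_atlas <- function(x, ...) {
  ap <- vapply(x$plates, `[[`, numeric(1), "ap_mm")
  cat("Atlas model:", nrow(x$regions), "regions,", length(x$plates),
      sprintf("plates (AP %+.2f to %+.2f mm),", max(ap), min(ap)),
      sprintf("section thickness %.0f um\n", 1000 * x$section_thickness_mm))
  invisible(x)
}

## Full invariant check; stops with an informative message on violation.
validate_atlas <- function(atlas) {
  reg <- atlas$regions
  if (anyDuplicated(reg$id))
    stop("duplicate region id: ", reg$id[duplicated(reg$id)][1])
  ## acyclic parent links, parents exist
  for (id in reg$id) {
    seen <- character()
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cyclic parent link at region ", id)
      seen <- c(seen, cur)
      if (!cur %in% reg$id) stop("unknown parent region: ", cur)
      cur <- reg$parent[match(cur, reg$id)]
    }
  }
  if (atlas$section_thickness_mm <= 0) stop("section thickness must be > 0")
  ap <- vapply(atlas$plates, `[[`, numeric(1), "ap_mm")
  if (any(diff(ap) >= 0)) stop("plates must be strictly ordered by decreasing AP")
  for (k in seq_along(atlas$plates)) {
    pl <- atlas$plates[[k]]
    tag <- sprintf("plate %d (AP %+.2f)", k, pl$ap_mm)
    for (o in pl$outlines) {
      if (!o$region %in% reg$id)
        stop(tag, ": outline references unknown region '", o$region, "'")
      if (!o$hemisphere %in% c("L", "R"))
        stop(tag, ": hemisphere must be 'L' or 'R'")
      if (!poly_is_simple(o$polygon))
        stop(tag, ": polygon for region '", o$region, "' self-intersects")
    }
    ## same-hemisphere polygons pairwise interior-disjoint, except along
    ## ancestor/descendant lines of the ontology (a nucleus may sit inside
    ## the brain outline of its ancestor).
    for (h in c("L", "R")) {
      os <- Filter(function(o) o$hemisphere == h, pl$outlines)
      if (length(os) < 2L) next
      for (i in seq_len(length(os) - 1L)) for (j in seq(i + 1L, length(os))) {
        ri <- os[[i]]$region; rj <- os[[j]]$region
        if (is_ancestor(atlas, ri, rj) || is_ancestor(atlas, rj, ri)) next
        if (polys_overlap(os[[i]]$polygon, os[[j]]$polygon))
          stop(tag, ": overlapping same-hemisphere outlines '", ri,
               "' and '", rj, "' (", h, ")")
      }
    }
  }
  invisible(TRUE)
}

is_ancestor <- function(atlas, anc, id) {
  cur <- atlas$regions$parent[match(id, atlas$regions$id)]
  while (!is.na(cur)) {
    if (cur == anc) return(TRUE)
    cur <- atlas$regions$parent[match(cur, atlas$regions$id)]
  }
  FALSE
}

region_depth <- function(atlas, id) {
  d <- 0L
  cur <- atlas$regions$parent[match(id, atlas$regions$id)]
  while (!is.na(cur)) {
    d <- d + 1L
    cur <- atlas$regions$parent[match(cur, atlas$regions$id)]
  }
  d
}

#' Index of the atlas plate nearest to an AP coordinate
#'
#' @param atlas an `lha_atlas`.
#' @param ap_mm anterior-posterior coordinate in mm.
#' @return Integer plate index.
#' @export
nearest_plate <- function(atlas, ap_mm) {
  ap <- vapply(atlas$plates, `[[`, numeric(1), "ap_mm")
  lo <- min(ap) - 0.5; hi <- max(ap) + 0.5
  if (ap_mm < lo || ap_mm > hi)
    stop(sprintf("AP %+.2f mm outside plate range [%+.2f, %+.2f]", ap_mm, lo, hi))
  which.min(abs(ap - ap_mm))
}

#' Look up the atlas region containing a point
#'
#' Finds the nearest plate along AP, then returns the id of the deepest
#' (most specific) region whose outline contains the point under the even-odd
#' rule, or `NA` if the point lies outside all outlines.
#'
#' @inheritParams nearest_plate
#' @param x,y point coordinates in atlas mm.
#' @return Region id (character) or `NA_character_`.
#' @export
region_at <- function(atlas, ap_mm, x, y) {
  pl <- atlas$plates[[nearest_plate(atlas, ap_mm)]]
  hit <- Filter(function(o) point_in_poly(x, y, o$polygon), pl$outlines)
  if (length(hit) == 0L) return(NA_character_)
  ids <- vapply(hit, `[[`, character(1), "region")
  ids[which.max(vapply(ids, function(i) region_depth(atlas, i), integer(1)))]
}

#' Ipsi/contralateral assignment of a point
#'
#' A point is ipsilateral iff it lies on the injection side of the plate
#' midline; points exactly on the midline are assigned ipsilateral
#' (deterministic tie-break).
#'
#' @param plate one plate of an `lha_atlas`.
#' @param x point x coordinate(s) in mm.
#' @param injection_side `"L"` or `"R"`, the hemisphere of the injection.
#' @return Character vector of `"ipsi"` / `"contra"`.
#' @export
hemisphere_of <- function(plate, x, injection_side = "L") {
  injection_side <- match.arg(injection_side, c("L", "R"))
  dx <- x - plate$midline_x
  on_side <- if (injection_side == "L") dx <= 0 else dx >= 0
  ifelse(on_side, "ipsi", "contra")
}

## Hemisphere letter of a point (left/right of midline); midline -> "L".
hemi_letter <- function(plate, x) ifelse(x - plate$midline_x <= 0, "L", "R")

## All outlines for one region on a plate (list; possibly empty).
plate_outlines <- function(plate, region, hemisphere = NULL) {
  Filter(function(o) o$region == region &&
           (is.null(hemisphere) || o$hemisphere == hemisphere), plate$outlines)
}

## AP coordinates of plates that carry a given region.
region_ap_span <- function(atlas, region) {
  ap <- vapply(atlas$plates, `[[`, numeric(1), "ap_mm")
  has <- vapply(atlas$plates, function(p) length(plate_outlines(p, region)) > 0, logical(1))
  ap[has]
}

## Dorsal boundary (max y) of a region's outlines on a plate; -Inf if absent.
region_dorsal_y <- function(plate, region) {
  os <- plate_outlines(plate, region)
  if (length(os) == 0L) return(-Inf)
  max(vapply(os, function(o) max(o$polygon[, 2]), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
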