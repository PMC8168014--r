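## Per-brain aggregation: region volumes from parcellated crops, injection
## site volumetry from the serial images, the cohort exclusion rules, and
## the selection/pooling of analysis regions.

#' Region volumes from a brain's parcellated crops
#'
#' Volume of each region is the sum over sections of its cropped area times
#' the section thickness. Hemispheres are summed (bilateral volume).
#'
#' @param crops list of `region_crop` objects for all sections of one brain.
#' @param thickness_mm section thickness (default 0.07, i.e. 70 um).
#' @return Named numeric vector of volumes in mm^3.
#' @export
region_volumes <- function(crops, thickness_mm = 0.07) {
  v <- numeric(0)
  for (cr in crops) {
    v[cr$region] <- (if (is.na(v[cr$region] %||% NA)) 0 else v[cr$region]) +
      cr$area_mm2 * thickness_mm
  }
  ## drop the names introduced by indexing with NA guards
  v[!is.na(v)]
}

#' Injection-site volumetry and backflow from serial sections
#'
#' Thresholds each section at a configured intensity, keeps the connected
#' component containing the nominal injection centre (plus any suprathreshold
#' component lying dorsal to the LHA dorsal boundary over the injection
#' x-range: the capillary-track backflow), and integrates cross-section
#' areas times the section thickness. The backflow fraction is the volume
#' dorsal to the LHA dorsal boundary divided by the whole injection volume;
#' the centroid is assigned to a region with [region_at()].
#'
#' @param brain a `brain_dataset` with rendered sections.
#' @param atlas the `lha_atlas`.
#' @param intensity_threshold absolute intensity cut-off; defaults to half
#'   the design injection intensity recorded in the brain.
#' @return An `injection_report`: `brain_id`, `injection_volume_mm3`,
#'   `centroid_region`, `backflow_fraction`, per-section areas.
#' @export
injection_report <- function(brain, atlas, intensity_threshold = NULL) {
  if (is.null(intensity_threshold))
    intensity_threshold <- 0.5 * (brain$injection$intensity %||% 3000)
  th <- atlas$section_thickness_mm
  ctr <- brain$injection$center
  areas <- numeric(length(brain$sections))
  dorsal <- numeric(length(brain$sections))
  wsum <- c(0, 0); wtot <- 0; ap_w <- 0
  for (si in seq_along(brain$sections)) {
    sec <- brain$sections[[si]]
    if (is.null(sec$image)) stop("sections are not rendered")
    mask <- sec$image >= intensity_threshold
    if (!any(mask)) next
    frame <- sec$frame
    pl <- atlas$plates[[sec$plate]]
    y_d <- region_dorsal_y(pl, "LHA")
    if (!is.finite(y_d))
      y_d <- region_dorsal_y(atlas$plates[[nearest_plate(atlas, brain$injection$ap)]], "LHA")
    lab <- label_components(mask)
    ctr_px <- frame_mm_to_px(frame, ctr[1], ctr[2])
    r0 <- round(ctr_px[1, "row"]); c0 <- round(ctr_px[1, "col"])
    main_id <- if (r0 >= 1 && r0 <= nrow(mask) && c0 >= 1 && c0 <= ncol(mask))
      lab[r0, c0] else 0L
    keep <- mask & (lab == main_id)
    if (main_id == 0L) keep[] <- FALSE
    ## dorsal (backflow) components over the injection x-range
    for (id in setdiff(unique(lab[lab > 0L]), main_id)) {
      idx <- which(lab == id, arr.ind = TRUE)
      mm <- frame_px_to_mm(frame, idx[, 2], idx[, 1])
      if (min(mm[, "y"]) >= y_d && abs(mean(mm[, "x"]) - ctr[1]) < 0.5)
        keep[idx] <- TRUE
    }
    if (!any(keep)) next
    idx <- which(keep, arr.ind = TRUE)
    mm <- frame_px_to_mm(frame, idx[, 2], idx[, 1])
    a_px <- frame$px^2
    areas[si] <- nrow(idx) * a_px
    dorsal[si] <- sum(mm[, "y"] > y_d) * a_px
    wsum <- wsum + colSums(mm) * a_px
    ap_w <- ap_w + sec$ap_mm * areas[si]
    wtot <- wtot + areas[si]
  }
  if (wtot == 0) stop("no suprathreshold injection signal in any section")
  cen <- wsum / wtot
  ap_c <- ap_w / wtot
  vol <- sum(areas) * th
  structure(list(
    brain_id = brain$brain_id, injection_volume_mm3 = vol,
    centroid_region = region_at(atlas, ap_c, cen[1], cen[2]),
    centroid = c(x = unname(cen[1]), y = unname(cen[2]), ap = ap_c),
    backflow_fraction = sum(dorsal) * th / vol,
    areas_mm2 = areas,
    total_labeled = brain$truth$total %||% NA_real_),
    class = "injection_report")
}

#' @export
print.injection_report <- function(x, ...) {
  cat(sprintf(
    "Injection report %s: %.3f mm3, centroid %s, backflow %.1f%%\n",
    x$brain_id, x$injection_volume_mm3, x$centroid_region,
    100 * x$backflow_fraction))
  invisible(x)
}

## 4-connected component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- cl + d[2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Apply the cohort exclusion rules to one brain
#'
#' A brain is excluded when (i) the injection volume exceeds `max_volume`
#' (strictly), (ii) the injection centroid falls outside the LHA, (iii) the
#' dorsal backflow fraction exceeds `max_backflow` (strictly), or (iv) the
#' overall number of labelled neurons falls below `min_total` (strictly).
#' All violated reasons are listed; boundary values (exactly 1 mm^3, exactly
#' 10%, exactly 25,000) are included, matching the strict inequalities of
#' the exclusion rules.
#'
#' @param report an `injection_report`.
#' @param total_labeled total labelled neuron count for the brain; defaults
#'   to the count recorded in the report.
#' @param max_volume injection volume limit in mm^3 (default 1.0).
#' @param max_backflow backflow fraction limit (default 0.10).
#' @param min_total minimum overall labelled neuron count (default 25,000).
#' @param lha_region region id that must contain the centroid.
#' @return A `qc_decision`: `brain_id`, `included`, `reasons`.
#' @export
apply_qc <- function(report, total_labeled = report$total_labeled,
                     max_volume = 1.0, max_backflow = 0.10,
                     min_total = 25000, lha_region = "LHA") {
  reasons <- character(0)
  if (report$injection_volume_mm3 > max_volume)
    reasons <- c(reasons, "oversized_injection")
  if (is.na(report$centroid_region) || report$centroid_region != lha_region)
    reasons <- c(reasons, "mislocalized")
  if (report$backflow_fraction > max_backflow)
    reasons <- c(reasons, "backflow")
  if (!is.na(total_labeled) && total_labeled < min_total)
    reasons <- c(reasons, "low_label")
  structure(list(brain_id = report$brain_id,
                 included = length(reasons) == 0L, reasons = reasons),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat(sprintf("QC %s: %s%s\n", x$brain_id,
              if (x$included) "included" else "EXCLUDED",
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Pool, filter and rank the analysis regions
#'
#' Applies the pooling map (e.g. ORBl/ORBvl/AI as one orbital-insular whole,
#' PL/ORBm as another), drops pooled regions whose reference-cohort mean
#' count (summed over hemispheres) falls below `min_count` (strictly), and
#' keeps the top `k` by that mean, with deterministic ties broken by region
#' id. All genotypes and both hemisphere rows of the surviving regions are
#' retained.
#'
#' @param table data.frame with columns `brain_id`, `genotype`, `region`,
#'   `hemisphere`, `count` (and optionally more).
#' @param pooling named character vector `region -> pool label`; regions
#'   absent from it keep their own id. Use [atlas_pooling()] for the
#'   packaged map.
#' @param min_count minimum reference-genotype mean count (default 100).
#' @param k number of regions retained (default 28).
#' @param reference_genotype genotype whose cohort means drive selection.
#' @return The pooled and filtered table, with attribute `selected` (ranked
#'   region ids).
#' @export
select_analysis_regions <- function(table, pooling = NULL, min_count = 100,
                                    k = 28, reference_genotype = "WT") {
  stopifnot(all(c("brain_id", "genotype", "region", "hemisphere", "count")
                %in% names(table)))
  pooled_id <- table$region
  if (!is.null(pooling)) {
    hit <- pooled_id %in% names(pooling)
    pooled_id[hit] <- pooling[pooled_id[hit]]
  }
  table$region <- pooled_id
  agg <- stats::aggregate(count ~ brain_id + genotype + region + hemisphere,
                          data = table, FUN = sum)
  ref <- agg[agg$genotype == reference_genotype, ]
  if (nrow(ref) == 0L)
    stop("no rows for reference genotype '", reference_genotype, "'")
  per_brain <- stats::aggregate(count ~ brain_id + region, data = ref, FUN = sum)
  means <- stats::aggregate(count ~ region, data = per_brain, FUN = mean)
  means <- means[means$count >= min_count, , drop = FALSE]
  means <- means[order(-means$count, means$region), , drop = FALSE]
  if (k > nrow(means)) {
    warning("only ", nrow(means), " regions survive the count filter; ",
            "all retained")
    k <- nrow(means)
  }
  keep <- means$region[seq_len(k)]
  out <- agg[agg$region %in% keep, , drop = FALSE]
  out <- out[order(out$genotype, out$brain_id, out$region, out$hemisphere), ]
  rownames(out) <- NULL
  attr(out, "selected") <- keep
  out
}

#' Pooling map of the packaged atlas
#'
#' @param atlas an `lha_atlas`.
#' @return Named character vector mapping region ids to pool labels.
#' @export
atlas_pooling <- function(atlas) {
  p <- atlas$regions$pool
  names(p) <- atlas$regions$id
  p[!is.na(p)]
}

#' Ground-truth region count table of a synthetic brain
#'
#' Formats a simulated brain's exact truth as the standard count table used
#' by the selection and statistics stages (useful for validating those
#' stages independently of the imaging stages).
#'
#' @param brain a `brain_dataset`.
#' @return data.frame with `brain_id`, `genotype`, `region`, `hemisphere`,
#'   `count`.
#' @export
truth_region_table <- function(brain) {
  tc <- brain$truth$counts
  data.frame(brain_id = brain$brain_id, genotype = brain$genotype,
             region = tc$region, hemisphere = tc$hemisphere,
             count = tc$count, row.names = NULL)
}
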