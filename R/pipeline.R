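## End-to-end orchestration: simulate -> register -> segment -> count ->
## quantify/QC -> normalise -> statistics (-> burden), with per-stage file
## checkpoints (CSV/JSON) under an output directory and a run manifest with
## config hash and output checksums.  Every stochastic stage derives its
## seed from the global seed, so a rerun with the same configuration
## reproduces identical tables.

#' Assemble (and validate) a pipeline configuration
#'
#' @param atlas_path path to an atlas JSON; `NULL` for the packaged toy
#'   atlas.
#' @param out_dir output directory (created if missing).
#' @param seed global seed (mandatory).
#' @param design list of [cohort_design()] arguments (sample size, effects,
#'   atrophy, AP sampling, noise, injection).
#' @param classifier list: `n_images` (training tiles), `n_trees`,
#'   `threshold`.
#' @param counter list: `n_images`, `n_trees`, `max_depth`.
#' @param qc list: `max_volume`, `max_backflow`, `min_total`.
#' @param select list: `min_count`, `k`.
#' @param stats list: `value` ("normalized", "absolute" or "compensated"),
#'   `target_total`, `reference_lha`, `compensation_mode`.
#' @param burden optional list: `fractions` (named per-group truth
#'   fractions), `n_per_group`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(atlas_path = NULL, out_dir, seed,
                            design = list(),
                            classifier = list(n_images = 12L, n_trees = 50L,
                                              threshold = 0.5),
                            counter = list(n_images = 60L, n_trees = 20L,
                                           max_depth = 80L),
                            qc = list(max_volume = 1.0, max_backflow = 0.10,
                                      min_total = 25000),
                            select = list(min_count = 100, k = 28),
                            stats = list(value = "normalized",
                                         target_total = 50000,
                                         reference_lha = 2.75,
                                         compensation_mode = "literal"),
                            burden = NULL) {
  if (missing(seed) || is.null(seed)) stop("a global seed is mandatory")
  if (missing(out_dir)) stop("an output directory is required")
  if (!is.null(atlas_path) && !file.exists(atlas_path))
    stop("atlas path does not exist: ", atlas_path)
  defaults <- formals(pipeline_config)
  cfg <- list(atlas_path = atlas_path, out_dir = out_dir,
              seed = as.integer(seed), design = design,
              classifier = utils::modifyList(eval(defaults$classifier), classifier),
              counter = utils::modifyList(eval(defaults$counter), counter),
              qc = utils::modifyList(eval(defaults$qc), qc),
              select = utils::modifyList(eval(defaults$select), select),
              stats = utils::modifyList(eval(defaults$stats), stats),
              burden = burden)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Run the full quantification pipeline
#'
#' Simulates a cohort from the configuration, trains the pixel classifier
#' and density counter, and runs every brain through registration,
#' parcellation, segmentation, counting, volumetry and QC; included brains
#' then feed normalisation and the genotype x structure statistics. Count
#' tables, QC decisions and statistics are written as CSV/JSON under the
#' output directory; per-brain count tables act as checkpoints and are
#' reused on rerun (`resume = TRUE`) when the configuration hash matches.
#'
#' @param config a [pipeline_config()] or the path to a YAML file with the
#'   same fields.
#' @param resume reuse existing per-brain checkpoints (default `TRUE`).
#' @return A `run_manifest` (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config, resume = TRUE) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, y)
  }
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  timing <- c()
  tick <- function(stage, t0) {
    timing[stage] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  t0 <- Sys.time()
  atlas <- if (is.null(config$atlas_path)) load_atlas()
           else load_atlas(config$atlas_path)
  design <- do.call(cohort_design,
                    c(list(atlas = atlas), config$design,
                      list(seed = config$seed)))
  tick("setup", t0)

  ## --- model training -----------------------------------------------------
  t0 <- Sys.time()
  cl_tiles <- simulate_training_set(design, config$classifier$n_images,
                                    seed = seed_child(config$seed, 101L))
  strokes <- lapply(seq_along(cl_tiles), function(i)
    strokes_from_annotated(cl_tiles[[i]], seed = seed_child(config$seed, 200L + i)))
  classifier <- train_pixel_classifier(strokes, n_trees = config$classifier$n_trees,
                                       seed = seed_child(config$seed, 301L))
  ct_tiles <- simulate_training_set(design, config$counter$n_images,
                                    seed = seed_child(config$seed, 401L))
  counter <- train_density_model(ct_tiles, n_trees = config$counter$n_trees,
                                 max_depth = config$counter$max_depth,
                                 seed = seed_child(config$seed, 501L))
  tick("training", t0)

  ## --- per-brain processing ----------------------------------------------
  t0 <- Sys.time()
  count_rows <- list(); vol_rows <- list(); qc_list <- list()
  bi <- 0L
  for (g in design$genotypes) for (b in seq_len(design$n_per_genotype)) {
    bi <- bi + 1L
    brain_id <- sprintf("%s_%02d", g, b)
    ck <- file.path(config$out_dir, paste0("counts_", brain_id, ".csv"))
    ckv <- file.path(config$out_dir, paste0("volumes_", brain_id, ".csv"))
    ckq <- file.path(config$out_dir, paste0("qc_", brain_id, ".json"))
    if (resume && file.exists(ck) && file.exists(ckv) && file.exists(ckq) &&
        identical(tryCatch(jsonlite::read_json(ckq)$config_hash,
                           error = function(e) NULL), unname(hash))) {
      count_rows[[brain_id]] <- utils::read.csv(ck)
      vol_rows[[brain_id]] <- utils::read.csv(ckv)
      qcj <- jsonlite::read_json(ckq)
      qc_list[[brain_id]] <- structure(
        list(brain_id = brain_id, included = isTRUE(qcj$included),
             reasons = unlist(qcj$reasons)), class = "qc_decision")
      next
    }
    brain <- simulate_brain(atlas, design, g,
                            brain_seed = seed_child(config$seed, 1000L + bi),
                            brain_id = brain_id)
    crops_all <- list()
    counts <- list()
    for (si in seq_along(brain$sections)) {
      sec <- brain$sections[[si]]
      pa <- assign_plate(atlas, sec$landmarks)
      crops <- parcellate(sec$image, atlas$plates[[pa$plate]], pa$warp, atlas,
                          pixel_size_mm = brain$pixel_size_mm,
                          brain_id = brain_id, section_index = si)
      for (cr in crops) {
        fg <- segment(classifier, cr$image, config$classifier$threshold)
        est <- count_crop(counter, cr, fg)
        key <- paste(cr$region, cr$hemisphere, sep = ".")
        counts[[key]] <- (counts[[key]] %||% 0) + est$count
      }
      crops_all <- c(crops_all, crops)
    }
    vols <- region_volumes(crops_all, atlas$section_thickness_mm)
    side <- design$injection$side
    keys <- strsplit(names(counts), ".", fixed = TRUE)
    ctab <- data.frame(
      brain_id = brain_id, genotype = g,
      region = vapply(keys, `[[`, character(1), 1),
      hemisphere = ifelse(vapply(keys, `[[`, character(1), 2) == side,
                          "ipsi", "contra"),
      count = unlist(counts, use.names = FALSE), row.names = NULL)
    vtab <- data.frame(brain_id = brain_id, genotype = g,
                       region = names(vols), volume_mm3 = unname(vols),
                       row.names = NULL)
    rep_ <- injection_report(brain, atlas)
    qc <- apply_qc(rep_, total_labeled = sum(ctab$count),
                   max_volume = config$qc$max_volume,
                   max_backflow = config$qc$max_backflow,
                   min_total = config$qc$min_total)
    utils::write.csv(ctab, ck, row.names = FALSE)
    utils::write.csv(vtab, ckv, row.names = FALSE)
    jsonlite::write_json(list(config_hash = unname(hash), brain_id = brain_id,
                              included = qc$included, reasons = qc$reasons,
                              injection_volume_mm3 = rep_$injection_volume_mm3,
                              backflow_fraction = rep_$backflow_fraction,
                              centroid_region = rep_$centroid_region),
                         ckq, auto_unbox = TRUE, digits = NA)
    count_rows[[brain_id]] <- ctab
    vol_rows[[brain_id]] <- vtab
    qc_list[[brain_id]] <- qc
  }
  tick("brains", t0)

  ## --- selection, normalisation, statistics -------------------------------
  t0 <- Sys.time()
  included <- names(Filter(function(q) q$included, qc_list))
  counts_all <- do.call(rbind, count_rows)
  vols_all <- do.call(rbind, vol_rows)
  utils::write.csv(counts_all, file.path(config$out_dir, "counts_all.csv"),
                   row.names = FALSE)
  utils::write.csv(vols_all, file.path(config$out_dir, "volumes_all.csv"),
                   row.names = FALSE)
  stats_out <- NULL
  sel <- NULL
  if (length(included) >= 4L &&
      length(unique(counts_all$genotype[counts_all$brain_id %in% included])) >= 2L) {
    tab <- counts_all[counts_all$brain_id %in% included, ]
    sel <- select_analysis_regions(tab, pooling = atlas_pooling(atlas),
                                   min_count = config$select$min_count,
                                   k = config$select$k,
                                   reference_genotype = design$genotypes[1])
    totals <- tapply(tab$count, tab$brain_id, sum)
    values <- stage_values(sel, vols_all, config$stats, totals)
    ipsi <- values[values$hemisphere == "ipsi", ]
    stats_out <- two_way_anova_sidak(
      data.frame(genotype = ipsi$genotype, structure = ipsi$region,
                 value = ipsi$value))
    utils::write.csv(stats_out$posthoc,
                     file.path(config$out_dir, "posthoc_ipsi.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(anova = stats_out$anova, posthoc = stats_out$posthoc,
           value = config$stats$value),
      file.path(config$out_dir, "stats_ipsi.json"), digits = NA,
      dataframe = "rows")
  }
  tick("stats", t0)

  ## --- burden (optional) ---------------------------------------------------
  burden_out <- NULL
  if (!is.null(config$burden)) {
    t0 <- Sys.time()
    fr <- config$burden$fractions
    npg <- config$burden$n_per_group %||% 6L
    groups <- lapply(seq_along(fr), function(gi) {
      vapply(seq_len(npg), function(i) {
        sim <- simulate_burden_image(fr[[gi]],
                                     seed = seed_child(config$seed, 7000L + gi * 100L + i))
        burden_fraction(sim$image)$area_fraction
      }, numeric(1))
    })
    names(groups) <- names(fr)
    burden_out <- one_way_anova_tukey(groups)
    jsonlite::write_json(list(anova = burden_out$anova,
                              posthoc = burden_out$posthoc,
                              group_means = as.list(burden_out$group_means)),
                         file.path(config$out_dir, "burden.json"),
                         digits = NA, dataframe = "rows")
    tick("burden", t0)
  }

  outputs <- list.files(config$out_dir, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
  outputs <- setdiff(outputs, file.path(config$out_dir, "manifest.json"))
  checksums <- tools::md5sum(outputs)
  manifest <- structure(list(
    config_hash = unname(hash), package_version =
      as.character(utils::packageVersion("lhatrace")),
    out_dir = config$out_dir, seed = config$seed,
    qc = lapply(qc_list, function(q) list(brain_id = q$brain_id,
                                          included = q$included,
                                          reasons = q$reasons)),
    included = included, selected_regions = attr(sel, "selected"),
    timing_s = as.list(timing),
    outputs = as.list(stats::setNames(unname(checksums), basename(outputs))),
    stats = stats_out, burden = burden_out,
    elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 2)),
    class = "run_manifest")
  jsonlite::write_json(
    manifest[setdiff(names(manifest), c("stats", "burden"))],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

## Per-brain normalisation of the selected count table; totals are the
## whole-brain counted totals (not just the selected regions).
stage_values <- function(sel, vols_all, stats_cfg, totals) {
  sel$value <- sel$count
  for (b in unique(sel$brain_id)) {
    idx <- sel$brain_id == b
    if (stats_cfg$value == "normalized") {
      sel$value[idx] <- normalize_50k(sel$count[idx], totals[[b]],
                                      target = stats_cfg$target_total)
    } else if (stats_cfg$value == "compensated") {
      lv <- vols_all$volume_mm3[vols_all$brain_id == b &
                                  vols_all$region == "LHA"]
      sel$value[idx] <- atrophy_compensate(sel$count[idx], sum(lv),
                                           reference = stats_cfg$reference_lha,
                                           mode = stats_cfg$compensation_mode)
    }
  }
  sel
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run", substr(x$config_hash, 1, 8), "- outputs in", x$out_dir, "\n")
  inc <- vapply(x$qc, function(q) isTRUE(q$included), logical(1))
  cat(sprintf("QC: %d/%d brains included\n", sum(inc), length(inc)))
  cat("Stage timing (s):",
      paste(names(x$timing_s), unlist(x$timing_s), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Summarise a pipeline run as a report
#'
#' Collates the run's checkpointed tables into the panels a cohort study
#' reports: per-region counts (normalised per the run configuration) by
#' genotype, LHA/hypothalamic volumes by genotype, the QC summary, and the
#' genotype x structure statistics. Also written as `report.md`.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param out_dir directory holding the run outputs (defaults to the
#'   manifest's).
#' @return List of report tables, invisibly; the markdown report path as
#'   attribute `path`.
#' @export
make_report <- function(manifest, out_dir = manifest$out_dir) {
  counts <- utils::read.csv(file.path(out_dir, "counts_all.csv"))
  vols <- utils::read.csv(file.path(out_dir, "volumes_all.csv"))
  inc <- manifest$included
  counts_inc <- counts[counts$brain_id %in% inc, ]
  by_region <- stats::aggregate(count ~ genotype + region, data = counts_inc,
                                FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  lha <- vols[vols$region == "LHA", ]
  qc_tab <- data.frame(
    brain_id = vapply(manifest$qc, `[[`, character(1), "brain_id"),
    included = vapply(manifest$qc, function(q) isTRUE(q$included), logical(1)),
    reasons = vapply(manifest$qc, function(q)
      paste(unlist(q$reasons), collapse = ";"), character(1)), row.names = NULL)
  path <- file.path(out_dir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Cohort quantification report",
               sprintf("Run %s, seed %d", substr(manifest$config_hash, 1, 8),
                       manifest$seed),
               "", "## Quality control", ""), con)
  utils::write.table(qc_tab, con, sep = " | ", row.names = FALSE, quote = FALSE)
  writeLines(c("", "## LHA volumes (mm^3, per brain)", ""), con)
  utils::write.table(lha, con, sep = " | ", row.names = FALSE, quote = FALSE)
  if (!is.null(manifest$stats)) {
    writeLines(c("", "## Genotype x structure statistics (ipsilateral)", ""), con)
    utils::write.table(format(manifest$stats$anova, digits = 4), con,
                       sep = " | ", row.names = FALSE, quote = FALSE)
    writeLines("", con)
    utils::write.table(format(manifest$stats$posthoc, digits = 4), con,
                       sep = " | ", row.names = FALSE, quote = FALSE)
  }
  out <- list(qc = qc_tab, counts_by_region = by_region, lha_volumes = lha,
              stats = manifest$stats, burden = manifest$burden)
  attr(out, "path") <- path
  invisible(out)
}
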