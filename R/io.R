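## File interchange: sections and crops as 16-bit grayscale TIFF, dot
## annotations and count tables as CSV, cohort designs as YAML.

#' Write a brain's sections as 16-bit grayscale TIFFs
#'
#' @param brain a `brain_dataset` with rendered sections.
#' @param dir output directory (created if missing).
#' @param max_intensity intensity mapped to the 16-bit ceiling.
#' @return Character vector of file paths.
#' @export
write_section_tiffs <- function(brain, dir, max_intensity = 4095) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (si in seq_along(brain$sections)) {
    sec <- brain$sections[[si]]
    if (is.null(sec$image)) next
    p <- file.path(dir, sprintf("%s_sec%03d.tiff", brain$brain_id, si))
    tiff::writeTIFF(pmin(pmax(sec$image / max_intensity, 0), 1), p,
                    bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  paths
}

#' Read a grayscale TIFF back to an intensity matrix
#'
#' @param path TIFF path.
#' @param max_intensity intensity the 16-bit ceiling maps back to.
#' @return Numeric matrix.
#' @export
read_section_tiff <- function(path, max_intensity = 4095) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m * max_intensity
}

#' Write region crops as coded TIFFs
#'
#' Filenames follow `<brain>_<section>_<region>_<hemisphere>.tiff` so each
#' crop can be re-identified downstream.
#'
#' @param crops list of `region_crop` objects.
#' @param dir output directory.
#' @param max_intensity 16-bit scaling ceiling.
#' @return Character vector of file paths.
#' @export
write_crop_tiffs <- function(crops, dir, max_intensity = 4095) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(crops, function(cr) {
    p <- file.path(dir, paste0(cr$code, ".tiff"))
    tiff::writeTIFF(pmin(pmax(cr$image / max_intensity, 0), 1), p,
                    bits.per.sample = 16L)
    p
  }, character(1))
}

#' Write dot annotations of a training set as CSV
#'
#' @param training list of `annotated_image` objects.
#' @param path output CSV (columns: image, col, row).
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(training, path) {
  rows <- do.call(rbind, lapply(seq_along(training), function(i) {
    d <- training[[i]]$dots
    if (nrow(d) == 0L) return(NULL)
    data.frame(image = i, col = d[, "col"], row = d[, "row"])
  }))
  if (is.null(rows)) rows <- data.frame(image = integer(), col = numeric(),
                                        row = numeric())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a cohort design as YAML
#'
#' Serialises every scalar/vector field of a [cohort_design()]; the atlas is
#' not embedded and must be supplied again on load.
#'
#' @param design a `cohort_design`.
#' @param path YAML file path.
#' @return `path` invisibly (`save`), or a `cohort_design` (`load`).
#' @export
save_design_yaml <- function(design, path) {
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' @rdname save_design_yaml
#' @param atlas an `lha_atlas` used to rebuild the design.
#' @export
load_design_yaml <- function(path, atlas) {
  y <- yaml::read_yaml(path)
  y$region_density <- unlist(y$region_density)
  y$lha_atrophy <- unlist(y$lha_atrophy)
  do.call(cohort_design, c(list(atlas = atlas), y))
}
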