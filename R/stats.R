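## Normalisations and the statistical battery: 50k count normalisation,
## LHA-atrophy compensation, two-way ANOVA (genotype x structure) with
## Sidak-corrected per-structure comparisons, one-way ANOVA with Tukey HSD,
## and pooled-variance t-tests from raw values or summary statistics.

#' 50k count normalisation
#'
#' Rescales a brain's per-region counts so that the brain total equals
#' `target` (50,000 by default): each region's count is divided by the
#' brain's total count and multiplied by the target.
#'
#' @param counts named numeric vector of per-region counts.
#' @param total brain total (defaults to `sum(counts)`).
#' @param target normalisation target (default 50,000).
#' @return Named numeric vector summing to `target`.
#' @export
normalize_50k <- function(counts, total = sum(counts), target = 50000) {
  if (is.na(total) || total <= 0) stop("total count must be > 0")
  counts / total * target
}

#' LHA atrophy compensation
#'
#' In the literal (default) mode each count is multiplied by the ratio of
#' the brain's LHA volume to the wild-type reference volume (2.75 mm^3), so
#' counts of atrophied brains shrink. The `"density"` mode divides by that
#' ratio instead, which corresponds to reading the compensated values as
#' projection densities per mm^3 of LHA; it is exposed for comparison only.
#' Compensation followed by 50k normalisation equals 50k normalisation
#' alone, since the per-brain ratio cancels.
#'
#' @param counts named numeric vector of per-region counts.
#' @param lha_volume_mm3 the brain's LHA volume (> 0).
#' @param reference reference LHA volume (default 2.75 mm^3).
#' @param mode `"literal"` (multiply by volume/reference) or `"density"`.
#' @return Compensated counts.
#' @export
atrophy_compensate <- function(counts, lha_volume_mm3, reference = 2.75,
                               mode = c("literal", "density")) {
  mode <- match.arg(mode)
  if (is.na(lha_volume_mm3) || lha_volume_mm3 <= 0)
    stop("LHA volume must be > 0")
  if (reference <= 0) stop("reference volume must be > 0")
  ratio <- lha_volume_mm3 / reference
  if (mode == "literal") counts * ratio else counts / ratio
}

#' Sidak family-wise adjustment
#'
#' @param p unadjusted p-values.
#' @param m family size.
#' @return Adjusted p-values `1 - (1 - p)^m`, clipped to \[0, 1\].
#' @export
sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Two-way ANOVA with Sidak per-structure comparisons
#'
#' Fits the fixed-effects genotype x structure model with interaction and
#' reports, for each structure, the genotype comparison
#' `t = (mean_A - mean_B) / sqrt(MS_res * (1/n_A + 1/n_B))` on the residual
#' degrees of freedom, Sidak-corrected over the structure family
#' (`p' = 1 - (1 - p)^m`). For unbalanced layouts Type-II sums of squares
#' are used with the residual df of the fitted layout; for balanced layouts
#' these equal the classical decomposition.
#'
#' @param data data.frame with columns `genotype`, `structure`, `value`.
#' @param family_size Sidak family size; defaults to the number of
#'   structures.
#' @return List of class `lha_anova2`: `anova` (effect, F, df1, df2, p),
#'   `posthoc` (structure, means, t, p, p_sidak), `ms_res`, `df_res`,
#'   `cell_means`.
#' @export
two_way_anova_sidak <- function(data, family_size = NULL) {
  stopifnot(all(c("genotype", "structure", "value") %in% names(data)))
  data$genotype <- factor(data$genotype)
  data$structure <- factor(data$structure)
  if (nlevels(data$genotype) < 2L || nlevels(data$structure) < 2L)
    stop("need >= 2 genotypes and >= 2 structures")
  tab <- table(data$genotype, data$structure)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: genotype '%s' x structure '%s'",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]]))
  }
  if (any(tab < 2L)) stop("need >= 2 replicates per cell")
  fit <- stats::lm(value ~ genotype * structure, data = data)
  a2 <- car::Anova(fit, type = 2)
  df_res <- fit$df.residual
  ms_res <- a2["Residuals", "Sum Sq"] / df_res
  eff <- setdiff(rownames(a2), "Residuals")
  atab <- data.frame(effect = eff, F = a2[eff, "F value"],
                     df1 = a2[eff, "Df"], df2 = df_res,
                     p = a2[eff, "Pr(>F)"], row.names = NULL)
  cell_means <- stats::aggregate(value ~ genotype + structure, data = data,
                                 FUN = mean)
  if (is.null(family_size)) family_size <- nlevels(data$structure)
  posthoc <- NULL
  if (nlevels(data$genotype) == 2L) {
    gl <- levels(data$genotype)
    rows <- lapply(levels(data$structure), function(s) {
      a <- data$value[data$structure == s & data$genotype == gl[1]]
      b <- data$value[data$structure == s & data$genotype == gl[2]]
      t <- (mean(a) - mean(b)) / sqrt(ms_res * (1 / length(a) + 1 / length(b)))
      p <- 2 * stats::pt(-abs(t), df_res)
      data.frame(structure = s, mean_A = mean(a), mean_B = mean(b),
                 t = t, df = df_res, p_unadjusted = p,
                 p_sidak = sidak_adjust(p, family_size))
    })
    posthoc <- do.call(rbind, rows)
  }
  structure(list(anova = atab, posthoc = posthoc, ms_res = ms_res,
                 df_res = df_res, cell_means = cell_means,
                 family_size = family_size,
                 genotypes = levels(data$genotype)),
            class = "lha_anova2")
}

#' @export
print.lha_anova2 <- function(x, ...) {
  cat("Two-way ANOVA (genotype x structure)\n")
  print(transform(x$anova, F = round(F, 3), p = signif(p, 4)))
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$p_sidak < 0.05, , drop = FALSE]
    cat(sprintf("Sidak post-hoc (family %d): %d of %d structures significant\n",
                x$family_size, nrow(sig), nrow(x$posthoc)))
    if (nrow(sig)) print(transform(sig, t = round(t, 3),
                                   p_sidak = signif(p_sidak, 3)))
  }
  invisible(x)
}

#' Two-tailed unpaired Student's t-test (pooled variance)
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param two_tailed if `FALSE`, the one-tailed p is returned.
#' @return List `t`, `df`, `p`.
#' @export
unpaired_t <- function(values_a, values_b, two_tailed = TRUE) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values")
  pooled_t_from_summary(mean(values_a), stats::sd(values_a), n1,
                        mean(values_b), stats::sd(values_b), n2,
                        two_tailed = two_tailed)
}

#' Pooled t-test from summary statistics
#'
#' Classical equal-variance Student's t from group means, SDs and sizes:
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`,
#' `t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2))`, `df = n1 + n2 - 2`.
#' Degenerate case (both SDs zero, equal means) returns `t = 0`, `p = 1`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @param two_tailed two-tailed p (default).
#' @return List `t`, `df`, `p`.
#' @examples
#' # hypothalamic volumetry from printed summary statistics
#' pooled_t_from_summary(750.8, 74.3, 72, 886.9, 86.5, 43)
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  two_tailed = TRUE) {
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- stats::pt(-abs(t), df) * if (two_tailed) 2 else 1
  list(t = t, df = df, p = min(1, p))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return List of class `lha_anova1`: `anova` (F, df1, df2, p), `posthoc`
#'   data.frame (pair, diff, p_tukey), `group_means`.
#' @export
one_way_anova_tukey <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs >= 2 values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  atab <- data.frame(effect = "group", F = s["group", "F value"],
                     df1 = s["group", "Df"], df2 = s["Residuals", "Df"],
                     p = s["group", "Pr(>F)"], row.names = NULL)
  tk <- stats::TukeyHSD(fit)$group
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_tukey = tk[, "p adj"], row.names = NULL)
  structure(list(anova = atab, posthoc = posthoc,
                 group_means = vapply(groups, mean, numeric(1))),
            class = "lha_anova1")
}

#' @export
print.lha_anova1 <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(transform(x$posthoc, diff = round(diff, 3),
                  p_tukey = signif(p_tukey, 3)))
  invisible(x)
}
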