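test_that("50k normalisation rescales counts and conserves the target", {
  out <- normalize_50k(c(A = 10, B = 40))
  expect_equal(out, c(A = 10000, B = 40000))
  expect_equal(normalize_50k(c(X = 123))[["X"]], 50000)
  set.seed(1)
  counts <- rpois(30, runif(30, 10, 5000))
  expect_lt(abs(sum(normalize_50k(counts)) - 50000), 1e-6)
  expect_error(normalize_50k(c(A = 0, B = 0)), "total")
})

test_that("atrophy compensation is literal, invertible, and cancels under 50k", {
  counts <- c(A = 100, B = 250)
  expect_equal(atrophy_compensate(counts, 2.75), counts)
  expect_equal(atrophy_compensate(c(A = 100), 1.375)[["A"]], 50)
  expect_equal(atrophy_compensate(c(A = 100), 1.375, mode = "density")[["A"]],
               200)
  expect_error(atrophy_compensate(counts, 0), "volume")
  ## compensation then 50k normalisation == 50k normalisation alone
  comp <- atrophy_compensate(counts, 1.9)
  expect_equal(normalize_50k(comp), normalize_50k(counts))
})

test_that("a balanced 2 x 28 x 3 layout has genotype denominator df 112", {
  set.seed(7)
  d <- expand.grid(genotype = c("WT", "mSOD1"),
                   structure = sprintf("S%02d", 1:28), rep = 1:3)
  d$value <- rnorm(nrow(d), 100, 10)
  res <- two_way_anova_sidak(d)
  expect_equal(res$df_res, 112)
  expect_equal(res$anova$df2[res$anova$effect == "genotype"], 112)
  expect_equal(nrow(res$posthoc), 28)
  expect_true(all(res$posthoc$p_sidak >= res$posthoc$p_unadjusted - 1e-12))
})

test_that("identical groups give F near zero and p near one", {
  d <- expand.grid(genotype = c("A", "B"), structure = c("s1", "s2"),
                   rep = 1:3)
  ## identical genotype groups: value depends on structure and replicate only
  d$value <- 5 * as.numeric(factor(d$structure)) + c(0.1, -0.2, 0.3)[d$rep]
  res <- two_way_anova_sidak(d)
  g <- res$anova[res$anova$effect == "genotype", ]
  expect_lt(g$F, 1e-10)
  expect_gt(g$p, 0.99)
})

test_that("two-way F values match a hand-computed sums-of-squares oracle", {
  set.seed(11)
  d <- expand.grid(genotype = c("A", "B"), structure = c("s1", "s2"),
                   rep = 1:2)
  d$value <- rnorm(8, 10, 2)
  res <- two_way_anova_sidak(d)
  ## textbook balanced decomposition
  gm <- mean(d$value)
  mg <- tapply(d$value, d$genotype, mean)
  ms <- tapply(d$value, d$structure, mean)
  mc <- tapply(d$value, interaction(d$genotype, d$structure), mean)
  ss_g <- 4 * sum((mg - gm)^2)
  ss_s <- 4 * sum((ms - gm)^2)
  ss_i <- 2 * sum((mc - gm)^2) - ss_g - ss_s
  ss_r <- sum((d$value - mc[interaction(d$genotype, d$structure)])^2)
  f_oracle <- c(ss_g / 1, ss_s / 1, ss_i / 1) / (ss_r / 4)
  got <- res$anova$F[match(c("genotype", "structure", "genotype:structure"),
                           res$anova$effect)]
  expect_equal(got, unname(f_oracle), tolerance = 1e-10)
})

test_that("empty or thin cells are rejected with the cell named", {
  d <- expand.grid(genotype = c("A", "B"), structure = c("s1", "s2"), rep = 1:2)
  d$value <- rnorm(8)
  expect_error(two_way_anova_sidak(d[!(d$genotype == "B" & d$structure == "s2"), ]),
               "empty cell.*B.*s2")
})

test_that("the unpaired t-test matches hand computation and its summary twin", {
  r <- unpaired_t(c(1, 2), c(3, 4))
  expect_equal(r$df, 2)
  expect_equal(r$t, -2.828, tolerance = 1e-3)
  a <- rnorm(7, 5, 2); b <- rnorm(9, 6, 1)
  r1 <- unpaired_t(a, b)
  r2 <- pooled_t_from_summary(mean(a), sd(a), 7, mean(b), sd(b), 9)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$t, 0)
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$p, 1)
})

test_that("the summary-statistics t reduces to the classical equal-n form", {
  m1 <- 10; m2 <- 12; s <- 3; n <- 8
  r <- pooled_t_from_summary(m1, s, n, m2, s, n)
  expect_equal(r$t, (m1 - m2) / (s * sqrt(2 / n)))
  expect_equal(r$df, 2 * n - 2)
})

test_that("Sidak adjustment is monotone and never above Bonferroni", {
  p <- c(1e-5, 1e-3, 0.01, 0.05, 0.2, 0.8)
  ps <- sidak_adjust(p, 28)
  expect_true(all(diff(ps) >= 0))
  expect_equal(sidak_adjust(p, 1), p)
  expect_true(all(ps <= pmin(1, p * 28) + 1e-12))
  expect_true(all(ps >= p))
})

test_that("one-way ANOVA with Tukey reproduces df and the SS oracle", {
  set.seed(13)
  groups <- lapply(1:4, function(i) rnorm(6, i, 1))
  names(groups) <- paste0("g", 1:4)
  res <- one_way_anova_tukey(groups)
  expect_equal(res$anova$df1, 3)
  expect_equal(res$anova$df2, 20)
  same <- one_way_anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(same$anova$F, 1e-10)
  ## 3-group brute-force sums of squares
  g3 <- list(a = c(1, 3, 2), b = c(4, 6, 5), c = c(9, 7, 8))
  r3 <- one_way_anova_tukey(g3)
  gm <- mean(unlist(g3))
  ssb <- sum(vapply(g3, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g3, function(v) sum((v - mean(v))^2), numeric(1)))
  expect_equal(r3$anova$F, (ssb / 2) / (ssw / 6), tolerance = 1e-10)
  expect_error(one_way_anova_tukey(list(a = 1:3)), "groups")
})

test_that("null count cohorts keep the family-wise error near nominal", {
  baseline <- stats::setNames(rep(700, 28), sprintf("S%02d", 1:28))
  hits <- vapply(1:120, function(r) {
    co <- simulate_count_cohort(3, c("WT", "mSOD1"), baseline, seed = 5000 + r)
    res <- two_way_anova_sidak(data.frame(genotype = co$genotype,
                                          structure = co$structure,
                                          value = co$count))
    any(res$posthoc$p_sidak < 0.05)
  }, logical(1))
  ## 120 quick replicates here; the full 500-replicate check runs in the
  ## acceptance suite
  expect_lte(mean(hits), 0.10)
})
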