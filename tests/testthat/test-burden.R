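test_that("rolling-ball subtraction removes shading and keeps blobs", {
  flat <- matrix(5, 40, 40)
  out <- rolling_ball_subtract(flat, 10)
  expect_lt(max(abs(out)), 1e-9)
  ## smooth ramp + one narrow blob
  n <- 96
  ramp <- outer(seq(0, 80, length.out = n), seq(0, 40, length.out = n), "+")
  img <- ramp
  blob <- outer(dnorm(seq(-3, 3, length.out = 7)),
                dnorm(seq(-3, 3, length.out = 7)))
  blob <- 100 * blob / max(blob)
  img[45:51, 45:51] <- img[45:51, 45:51] + blob
  out <- rolling_ball_subtract(img, 20)
  expect_true(all(out <= img - 0 + 1e-9))
  expect_gt(max(out[45:51, 45:51]), 0.9 * 100)
  away <- out[5:30, 60:90]
  expect_lt(max(away), 0.05 * diff(range(ramp)))
  expect_error(rolling_ball_subtract(matrix(1, 10, 10), 12), "extent")
  expect_error(rolling_ball_subtract(matrix(1, 10, 10), 0), "radius")
})

test_that("the Shannon split matches exhaustive search on random histograms", {
  set.seed(21)
  brute_shannon <- function(h) {
    p <- h / sum(h)
    best <- -Inf; bt <- NA
    for (t in 1:255) {
      w0 <- sum(p[1:t]); w1 <- 1 - w0
      if (w0 <= 0 || w1 <= 0) next
      q0 <- p[1:t][p[1:t] > 0] / w0
      q1 <- p[(t + 1):256][p[(t + 1):256] > 0] / w1
      crit <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
      if (crit > best) { best <- crit; bt <- t }
    }
    bt - 1L
  }
  for (i in 1:50) {
    h <- rpois(256, lambda = runif(1, 0.5, 20))
    mode1 <- sample(40:90, 1); mode2 <- sample(150:220, 1)
    h[mode1 + (-3:3)] <- h[mode1 + (-3:3)] + rpois(7, 500)
    h[mode2 + (-3:3)] <- h[mode2 + (-3:3)] + rpois(7, 300)
    expect_identical(lhatrace:::shannon_threshold(h), brute_shannon(h))
  }
})

test_that("the combined threshold splits bimodal histograms and is scale-free", {
  h <- integer(256)
  h[49:53] <- c(100L, 400L, 1000L, 400L, 100L)
  h[199:203] <- c(80L, 300L, 800L, 300L, 80L)
  t1 <- renyi_threshold(h)
  ## strictly between the mode peaks (0-based bins 50 and 200); values
  ## above the threshold are foreground
  expect_gt(t1, 50); expect_lt(t1, 200)
  expect_identical(renyi_threshold(h * 10L), t1)
  expect_error(renyi_threshold(c(integer(255), 5L)), "degenerate")
  expect_error(renyi_threshold(integer(10)), "256")
})

test_that("burden estimates track the generated truth fraction", {
  sim <- simulate_burden_image(0.25, seed = 31)
  res <- burden_fraction(sim$image)
  expect_gte(res$area_fraction, 0.20)
  expect_lte(res$area_fraction, 0.30)
  fr <- c(0.05, 0.15, 0.30)
  est <- vapply(seq_along(fr), function(i)
    burden_fraction(simulate_burden_image(fr[i], seed = 40 + i)$image)$area_fraction,
    numeric(1))
  expect_true(all(diff(est) > 0))
  expect_error(burden_fraction(matrix(3, 64, 64)), "degenerate")
})

test_that("group burden ordering is recovered by the one-way battery", {
  fr <- c(MOp = 0.30, ORB_AI = 0.18, PL_ORBm = 0.08, SS = 0.05)
  groups <- lapply(seq_along(fr), function(gi)
    vapply(1:5, function(i)
      burden_fraction(simulate_burden_image(fr[[gi]],
                                            seed = 100 * gi + i)$image)$area_fraction,
      numeric(1)))
  names(groups) <- names(fr)
  res <- one_way_anova_tukey(groups)
  expect_identical(names(sort(res$group_means, decreasing = TRUE)),
                   names(fr)[order(-fr)])
  expect_lt(res$anova$p, 0.001)
  extreme <- res$posthoc[grepl("MOp", res$posthoc$pair) &
                           grepl("SS", res$posthoc$pair), ]
  expect_lt(extreme$p_tukey, 0.01)
})
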