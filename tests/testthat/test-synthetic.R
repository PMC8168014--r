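test_that("zero densities give empty truth and background-only images", {
  design <- small_design()
  design$region_density[] <- 0
  design$noise$dendrite_rate <- 0
  design$injection$volume_mm3 <- 0.001
  brain <- simulate_brain(toy_atlas, design, "WT", brain_seed = 1)
  expect_equal(sum(brain$truth$counts$count), 0L)
  img <- brain$sections[[2]]$image   # a section without injection signal
  expect_lt(max(img), design$noise$bg_mean + 10 * design$noise$bg_sd +
              3 * design$noise$bg_field_amp)
})

test_that("default WT design realises ~50,000 somata within Poisson bounds", {
  design <- cohort_design(toy_atlas, seed = 1)
  brain <- simulate_brain(toy_atlas, design, "WT", brain_seed = 2,
                          render = FALSE)
  expect_lt(abs(brain$truth$total - 50000), 3 * sqrt(50000))
  ipsi <- sum(brain$truth$counts$count[brain$truth$counts$hemisphere == "ipsi"])
  expect_lt(abs(ipsi / brain$truth$total - 0.8), 0.02)
  ## truth conservation
  expect_identical(brain$truth$total, sum(brain$truth$counts$count))
})

test_that("the genotype effect map shifts truth counts by the set factor", {
  pool <- c("ORBl", "ORBvl", "AI")
  design <- cohort_design(toy_atlas, ap_range = c(2.6, 0.8), ap_step = 0.1,
                          total_neurons = 20000,
                          effect_map = list(mSOD1 = c(ORBl = 1.8, ORBvl = 1.8,
                                                      AI = 1.8)),
                          seed = 3)
  pool_total <- function(g, seed) {
    b <- simulate_brain(toy_atlas, design, g, brain_seed = seed, render = FALSE)
    sum(b$truth$counts$count[b$truth$counts$region %in% pool])
  }
  wt <- vapply(1:20, function(i) pool_total("WT", 100 + i), numeric(1))
  mut <- vapply(1:20, function(i) pool_total("mSOD1", 200 + i), numeric(1))
  expect_gt(mean(mut) / mean(wt), 1.7)
  expect_lt(mean(mut) / mean(wt), 1.9)
})

test_that("LHA atrophy scales both truth volume and rendered area", {
  design <- small_design()
  wt <- simulate_brain(toy_atlas, design, "WT", brain_seed = 4, render = FALSE)
  mut <- simulate_brain(toy_atlas, design, "mSOD1", brain_seed = 4,
                        render = FALSE)
  ratio <- mut$truth$volumes[["LHA"]] / wt$truth$volumes[["LHA"]]
  expect_lt(abs(ratio - 0.75), 0.05 * 0.75)
})

test_that("identical design and seed regenerate a bit-identical brain", {
  design <- small_design(total = 500)
  b1 <- simulate_brain(toy_atlas, design, "WT", brain_seed = 5)
  b2 <- simulate_brain(toy_atlas, design, "WT", brain_seed = 5)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$sections[[3]]$image, b2$sections[[3]]$image)
  b3 <- simulate_brain(toy_atlas, design, "WT", brain_seed = 6)
  expect_false(identical(b1$sections[[3]]$image, b3$sections[[3]]$image))
})

test_that("training tiles carry consistent annotations at the set density", {
  design <- cohort_design(toy_atlas, seed = 1)
  expect_error(simulate_training_set(design, 0, seed = 1), "n_images")
  tiles <- simulate_training_set(design, 250, seed = 7)
  counts <- vapply(tiles, function(t) nrow(t$dots), numeric(1))
  expect_true(all(vapply(tiles, function(t)
    nrow(t$dots) == 0 ||
      (all(t$dots >= 1) && all(t$dots[, "col"] <= ncol(t$image)) &&
         all(t$dots[, "row"] <= nrow(t$image))), logical(1))))
  ## aggregate dot density vs the design expectation
  expected <- (1 - design$noise$tile_bg_prob) * design$noise$tile_mean_count
  expect_lt(abs(mean(counts) - expected) / expected, 0.05)
  ## neuron-free background tiles are present
  expect_gt(sum(counts == 0), 0)
})

test_that("burden images honour the requested area fraction deterministically", {
  expect_error(simulate_burden_image(1.2, seed = 1), "area_fraction")
  z <- simulate_burden_image(0, seed = 1)
  expect_equal(sum(z$truth_mask), 0)
  s <- simulate_burden_image(0.25, seed = 2)
  expect_gte(s$truth_fraction, 0.23)
  expect_lte(s$truth_fraction, 0.27)
  s2 <- simulate_burden_image(0.25, seed = 2)
  expect_identical(s$image, s2$image)
})

test_that("generator backflow fraction round-trips through injection_report", {
  design <- small_design(total = 200)
  design$injection$backflow_fraction <- 0.2
  brain <- simulate_brain(toy_atlas, design, "WT", brain_seed = 9)
  expect_lt(abs(brain$injection$backflow_fraction - 0.2), 0.02)
  rep_ <- injection_report(brain, toy_atlas)
  expect_lt(abs(rep_$backflow_fraction - brain$injection$backflow_fraction),
            0.03)
  expect_lt(abs(rep_$injection_volume_mm3 - brain$injection$volume_mm3),
            0.1 * brain$injection$volume_mm3)
})
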