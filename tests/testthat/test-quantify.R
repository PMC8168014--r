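fake_crop <- function(region, area, hemi = "L") {
  structure(list(region = region, hemisphere = hemi, area_mm2 = area,
                 code = paste0("x_", region)), class = "region_crop")
}

fake_report <- function(brain_id = "b1", volume = 0.5, region = "LHA",
                        backflow = 0, total = 40000) {
  structure(list(brain_id = brain_id, injection_volume_mm3 = volume,
                 centroid_region = region, backflow_fraction = backflow,
                 total_labeled = total), class = "injection_report")
}

test_that("region volume is area times thickness, with analytic scaling", {
  v <- region_volumes(list(fake_crop("LHA", 1.0)))
  expect_equal(v[["LHA"]], 0.07)
  ## linear in thickness
  expect_equal(region_volumes(list(fake_crop("LHA", 1.0)), 0.14)[["LHA"]], 0.14)
  ## quadratic in pixel size: area itself carries the pixel-size square
  crops2 <- list(fake_crop("LHA", 0.25), fake_crop("LHA", 0.25, "R"))
  expect_equal(region_volumes(crops2)[["LHA"]], 2 * 0.25 * 0.07)
})

test_that("a serially reconstructed WT LHA lands on the reference volume", {
  design <- cohort_design(toy_atlas, seed = 1)
  wt <- simulate_brain(toy_atlas, design, "WT", brain_seed = 3, render = FALSE)
  expect_lt(abs(wt$truth$volumes[["LHA"]] - 2.75) / 2.75, 0.05)
  ## image-based estimate on a restricted AP window matches its own truth
  d2 <- small_design(total = 100)
  b2 <- simulate_brain(toy_atlas, d2, "WT", brain_seed = 3)
  crops <- list()
  for (si in seq_along(b2$sections)) {
    sec <- b2$sections[[si]]
    pa <- assign_plate(toy_atlas, sec$landmarks)
    crops <- c(crops, parcellate(sec$image, toy_atlas$plates[[pa$plate]],
                                 pa$warp, toy_atlas,
                                 pixel_size_mm = d2$pixel_size_mm))
  }
  est <- region_volumes(crops)[["LHA"]]
  expect_lt(abs(est - b2$truth$volumes[["LHA"]]) / b2$truth$volumes[["LHA"]],
            0.05)
})

test_that("atrophied brains reconstruct at the atrophy factor", {
  d <- small_design(total = 100)
  wt <- simulate_brain(toy_atlas, d, "WT", brain_seed = 4, render = FALSE)
  mut <- simulate_brain(toy_atlas, d, "mSOD1", brain_seed = 4, render = FALSE)
  expect_lt(abs(mut$truth$volumes[["LHA"]] / wt$truth$volumes[["LHA"]] - 0.75),
            0.05 * 0.75)
})

test_that("injection volume equals summed cross-sections times thickness", {
  d <- small_design(total = 100)
  b <- simulate_brain(toy_atlas, d, "WT", brain_seed = 5)
  rep_ <- injection_report(b, toy_atlas)
  expect_equal(rep_$injection_volume_mm3, sum(rep_$areas_mm2) * 0.07)
  expect_identical(rep_$centroid_region, "LHA")
  expect_lt(rep_$backflow_fraction, 0.05)
  ## no signal -> clean error
  d0 <- small_design(total = 100)
  d0$injection$intensity <- 0
  b0 <- simulate_brain(toy_atlas, d0, "WT", brain_seed = 5)
  expect_error(injection_report(b0, toy_atlas, intensity_threshold = 1500),
               "no suprathreshold")
})

test_that("exclusion thresholds are strict as printed", {
  expect_true(apply_qc(fake_report(volume = 1.0))$included)
  q <- apply_qc(fake_report(volume = 1.2))
  expect_false(q$included); expect_identical(q$reasons, "oversized_injection")
  expect_true(apply_qc(fake_report(backflow = 0.10))$included)
  expect_false(apply_qc(fake_report(backflow = 0.101))$included)
  expect_true(apply_qc(fake_report(total = 25000))$included)
  q2 <- apply_qc(fake_report(total = 24999))
  expect_false(q2$included); expect_identical(q2$reasons, "low_label")
})

test_that("a constructed cohort is excluded for exactly the right reasons", {
  cohort <- list(
    apply_qc(fake_report("ok1")),
    apply_qc(fake_report("ok2")),
    apply_qc(fake_report("ok3")),
    apply_qc(fake_report("ok4")),
    apply_qc(fake_report("big", volume = 1.4)),
    apply_qc(fake_report("off", region = "VMH")),
    apply_qc(fake_report("back", backflow = 0.2)),
    apply_qc(fake_report("dim", total = 12000)))
  included <- vapply(cohort, `[[`, logical(1), "included")
  expect_identical(included, c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_identical(lapply(cohort[5:8], `[[`, "reasons"),
                   list("oversized_injection", "mislocalized", "backflow",
                        "low_label"))
})

test_that("pooling sums counts and conserves the brain total", {
  tab <- data.frame(
    brain_id = "b1", genotype = "WT",
    region = c("ORBl", "ORBvl", "AI", "MOs"),
    hemisphere = "ipsi", count = c(50, 60, 90, 400))
  pooled <- select_analysis_regions(tab, pooling = atlas_pooling(toy_atlas),
                                    min_count = 0, k = 2)
  orb <- pooled$count[pooled$region == "ORBl/vl+AI"]
  expect_equal(orb, 200)
  expect_equal(sum(pooled$count), sum(tab$count))
})

test_that("the count filter boundary and ranking are deterministic", {
  mk <- function(r, n) data.frame(brain_id = c("a", "b"), genotype = "WT",
                                  region = r, hemisphere = "ipsi",
                                  count = c(n, n))
  tab <- rbind(mk("A", 99), mk("B", 100), mk("C", 500), mk("D", 300))
  out <- select_analysis_regions(tab, min_count = 100, k = 3)
  expect_warning(sel2 <- select_analysis_regions(tab, min_count = 100, k = 5),
                 "survive")
  expect_identical(attr(out, "selected"), c("C", "D", "B"))
  expect_false("A" %in% out$region)
  rerun <- select_analysis_regions(tab, min_count = 100, k = 3)
  expect_identical(out, rerun)
  ## deterministic tie-break by region id
  tie <- rbind(mk("Z", 200), mk("Y", 200), mk("X", 200))
  expect_identical(attr(select_analysis_regions(tie, min_count = 0, k = 2),
                        "selected"), c("X", "Y"))
})
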