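## Identity-geometry fixtures: a minimal atlas whose mm coordinates equal
## section px coordinates up to a known scale.
identity_warp <- function() {
  lm <- data.frame(atlas_x = c(0, 200, 0, 200), atlas_y = c(0, 0, 200, 200),
                   sec_x = c(0, 200, 0, 200), sec_y = c(0, 0, 200, 200))
  fit_warp(lm, "affine")
}

square_atlas <- function() {
  ## one plate, a 100x100 px square region (in "mm" units equal to px here)
  regions <- data.frame(id = c("ROOT", "SQ"), name = c("brain", "square"),
                        parent = c(NA, "ROOT"), pool = NA,
                        stringsAsFactors = FALSE)
  poly_sq <- cbind(c(50.5, 150.5, 150.5, 50.5), c(50.5, 50.5, 150.5, 150.5))
  poly_root <- cbind(c(1, 199, 199, 1), c(1, 1, 199, 199))
  plate <- list(ap_mm = 0, midline_x = 100,
                landmarks = data.frame(name = c("a", "b", "c"),
                                       x = c(0, 200, 0), y = c(0, 0, 200)),
                outlines = list(
                  list(region = "ROOT", hemisphere = "L", polygon = poly_root),
                  list(region = "SQ", hemisphere = "L", polygon = poly_sq)))
  structure(list(regions = regions, plates = list(plate),
                 section_thickness_mm = 0.07), class = "lha_atlas")
}

test_that("a 100x100 px region at 5 um/px yields a 0.25 mm2 crop", {
  a <- square_atlas()
  img <- matrix(1, 200, 200)
  crops <- parcellate(img, a$plates[[1]], identity_warp(), a,
                      pixel_size_mm = 0.005)
  sq <- Filter(function(cr) cr$region == "SQ", crops)[[1]]
  expect_equal(sum(sq$mask), 100 * 100)
  expect_equal(sq$area_mm2, 0.25)
  expect_match(sq$code, "SQ")
})

test_that("abutting same-hemisphere regions never share a pixel", {
  design <- small_design()
  brain <- simulate_brain(toy_atlas, design, "WT", brain_seed = 11)
  sec <- brain$sections[[3]]
  pa <- assign_plate(toy_atlas, sec$landmarks)
  crops <- parcellate(sec$image, toy_atlas$plates[[pa$plate]], pa$warp,
                      toy_atlas, pixel_size_mm = design$pixel_size_mm)
  ## reconstruct full-frame masks and check pairwise disjointness
  full <- lapply(crops, function(cr) {
    m <- matrix(FALSE, nrow(sec$image), ncol(sec$image))
    m[cr$bbox["row0"]:cr$bbox["row1"], cr$bbox["col0"]:cr$bbox["col1"]] <- cr$mask
    m
  })
  hem <- vapply(crops, `[[`, character(1), "hemisphere")
  total <- matrix(0L, nrow(sec$image), ncol(sec$image))
  for (i in seq_along(full)) total <- total + full[[i]]
  expect_true(all(total <= 1))   # leaves are disjoint across hemispheres too
  expect_true(length(unique(hem)) == 2L)
})

test_that("parcellation assigns true somata to their generating regions", {
  design <- small_design()
  brain <- simulate_brain(toy_atlas, design, "WT", brain_seed = 13,
                          store_dots = TRUE)
  n_match <- 0L; n_tot <- 0L
  for (sec in brain$sections[seq(1, length(brain$sections), by = 4)]) {
    pa <- assign_plate(toy_atlas, sec$landmarks)
    crops <- parcellate(sec$image, toy_atlas$plates[[pa$plate]], pa$warp,
                        toy_atlas, pixel_size_mm = design$pixel_size_mm)
    if (is.null(sec$dots)) next
    for (cr in crops) {
      dpx <- warp_apply(pa$warp, cbind(sec$dots$x, sec$dots$y), "backward")
      rr <- round(dpx[, 2]); cc <- round(dpx[, 1])
      inside <- rr >= cr$bbox["row0"] & rr <= cr$bbox["row1"] &
        cc >= cr$bbox["col0"] & cc <= cr$bbox["col1"]
      inside[inside] <- cr$mask[cbind(rr[inside] - cr$bbox["row0"] + 1L,
                                      cc[inside] - cr$bbox["col0"] + 1L)]
      n_match <- n_match + sum(inside &
                                 sec$dots$region == cr$region &
                                 sec$dots$side_lr == cr$hemisphere)
      n_tot <- n_tot + sum(inside)
    }
  }
  expect_gt(n_tot, 100)
  expect_gte(n_match / n_tot, 0.99)
})

test_that("per-section crop areas never exceed the brain outline area", {
  design <- small_design()
  brain <- simulate_brain(toy_atlas, design, "WT", brain_seed = 17,
                          render = FALSE)
  sec <- brain$sections[[5]]
  pl <- toy_atlas$plates[[sec$plate]]
  outline_area <- sum(vapply(Filter(function(o) o$region == "ROOT",
                                    pl$outlines),
                             function(o) poly_area(o$polygon), numeric(1)))
  img <- matrix(0, sec$frame$nrow, sec$frame$ncol)
  pa <- assign_plate(toy_atlas, sec$landmarks)
  crops <- parcellate(img, pl, pa$warp, toy_atlas,
                      pixel_size_mm = design$pixel_size_mm)
  expect_lte(sum(vapply(crops, `[[`, numeric(1), "area_mm2")), outline_area)
})
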