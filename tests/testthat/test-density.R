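test_that("the density target integrates to the number of dots", {
  z <- density_target(NULL, c(50, 50))
  expect_equal(sum(z), 0)
  one <- density_target(cbind(25, 25), c(50, 50), sigma_dot = 2)
  expect_lt(abs(sum(one) - 1), 1e-3)
  ## border-truncated kernels are renormalised
  edge <- density_target(cbind(1.2, 49.5), c(50, 50), sigma_dot = 3)
  expect_lt(abs(sum(edge) - 1), 1e-3)
  set.seed(2)
  dots <- cbind(runif(57, 1, 80), runif(57, 1, 60))
  many <- density_target(dots, c(60, 80))
  expect_lt(abs(sum(many) - 57), 0.1)
  expect_error(density_target(cbind(99, 2), c(50, 50)), "bounds")
})

test_that("counts are additive over disjoint masks and zero on empty masks", {
  mod <- small_models()
  tile <- simulate_training_set(mod$design, 1, seed = 61)[[1]]
  n <- nrow(tile$image)
  empty <- list(image = tile$image, mask = matrix(FALSE, n, n), code = "e")
  expect_equal(count_crop(mod$counter, empty)$count, 0)
  left <- matrix(FALSE, n, n); left[, 1:(n / 2)] <- TRUE
  both <- count_crop(mod$counter, list(image = tile$image,
                                       mask = matrix(TRUE, n, n), code = "b"))
  cl <- count_crop(mod$counter, list(image = tile$image, mask = left, code = "l"))
  cr <- count_crop(mod$counter, list(image = tile$image, mask = !left, code = "r"))
  expect_lt(abs(both$count - (cl$count + cr$count)), 1e-6)
  bad <- matrix(TRUE, n + 1, n)
  expect_error(count_crop(mod$counter, list(image = tile$image,
                                            mask = matrix(TRUE, n, n)),
                          fg_mask = bad), "shape")
})

test_that("well-separated somata are counted within 10%", {
  mod <- small_models()
  noise <- mod$design$noise
  set.seed(12)
  img <- lhatrace:::render_background(120, 120, noise)
  centers <- expand.grid(row = seq(12, 110, by = 24),
                         col = seq(12, 110, by = 28))[1:20, ]
  img <- lhatrace:::render_somata(img, centers$col, centers$row, noise)
  est <- sum(predict(mod$counter, img))
  expect_gte(est, 18)
  expect_lte(est, 22)
})

test_that("predictions are non-negative, deterministic, and lightly clipped", {
  mod <- small_models()
  tile <- simulate_training_set(mod$design, 1, seed = 71)[[1]]
  d1 <- predict(mod$counter, tile$image)
  d2 <- predict(mod$counter, tile$image)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
  expect_lt(attr(d1, "clipped_mass"), 0.02 * max(sum(d1), 1))
})

test_that("a realisable target is fitted with low training error", {
  ## density that is an exact function of the image: forest should recover it
  set.seed(3)
  tiles <- lapply(1:5, function(i) {
    dots <- cbind(col = runif(15, 10, 86), row = runif(15, 10, 86))
    img <- density_target(dots, c(96, 96), sigma_dot = 2) * 1000
    structure(list(image = img, dots = dots), class = "annotated_image")
  })
  m <- train_density_model(tiles, seed = 2)
  acc <- evaluate_accuracy(m, tiles)
  expect_gte(acc$accuracy, 97)
})

test_that("accuracy has the documented edge cases", {
  mod <- small_models()
  expect_error(evaluate_accuracy(mod$counter, list()), "empty")
  perfect <- list(structure(list(
    image = matrix(0, 8, 8), dots = matrix(numeric(0), ncol = 2,
                                           dimnames = list(NULL, c("col", "row")))),
    class = "annotated_image"))
  ## a zero image predicts ~0 somata -> perfect on an empty tile is ~100%
  acc <- evaluate_accuracy(mod$counter, perfect)
  expect_gte(acc$accuracy, 95)
})

test_that("training on an empty set fails and seeds fix the fit", {
  expect_error(train_density_model(list(), seed = 1), "empty")
  mod <- small_models()
  tiles <- simulate_training_set(mod$design, 5, seed = 81)
  m1 <- train_density_model(tiles, seed = 9)
  m2 <- train_density_model(tiles, seed = 9)
  expect_identical(predict(m1, tiles[[1]]$image), predict(m2, tiles[[1]]$image))
})

test_that("the learning curve rises from small to large training sets", {
  bench <- accuracy_benchmark()
  design <- cohort_design(toy_atlas, seed = 1)
  tiles <- simulate_training_set(design, 350L, seed = 1L)
  m20 <- train_density_model(tiles[1:20], seed = 1L)
  acc20 <- evaluate_accuracy(m20, tiles[251:350])$accuracy
  expect_lte(acc20, median(bench$acc250) + 1)
  expect_gte(median(bench$acc250), median(bench$acc100) - 1)
})
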