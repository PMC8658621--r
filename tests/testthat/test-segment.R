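test_that("1-D k-means recovers separated clusters with ascending labels", {
  km <- kmeans_1d(c(0, 0, 1, 1), k = 2, seed = 1)
  expect_equal(km$centroids, c(0, 1))
  expect_equal(km$labels, c(1L, 1L, 2L, 2L))

  km3 <- kmeans_1d(c(0, 0, 0.5, 0.5, 1, 1), k = 3, seed = 1)
  expect_equal(km3$centroids, c(0, 0.5, 1))
  expect_true(all(diff(km3$centroids) > 0))
})

test_that("k-means attains the exhaustive optimum on 8 points", {
  set.seed(10)
  for (i in 1:5) {
    vals <- round(runif(8), 3)
    km <- kmeans_1d(vals, k = 2, seed = i)
    sse <- sum((vals - km$centroids[km$labels])^2)
    expect_equal(sse, exhaustive_kmeans2_sse(vals), tolerance = 1e-9)
  }
})

test_that("k-means matches the dynamic-programming optimum on 30 points", {
  set.seed(20)
  for (k in 2:3) for (i in 1:4) {
    vals <- c(rnorm(10, 0), rnorm(10, 2), rnorm(10, 5))[sample(30)]
    km <- kmeans_1d(vals, k = k, seed = i)
    sse <- sum((vals - km$centroids[km$labels])^2)
    expect_equal(sse, dp_kmeans_sse(vals, k), tolerance = 1e-8)
  }
})

test_that("k-means rejects too few distinct values", {
  expect_error(kmeans_1d(c(1, 1, 1, 2), k = 3), "distinct")
})

test_that("sound-speed segmentation agrees with phantom truth labels", {
  ph <- small_phantom(seed = 5, fgf = 0.3)
  sm <- segment_sound_speed(ph$ss, ph$breast_mask, seed = 5)
  lab <- phantom_labels()
  m <- ph$breast_mask$data != 0
  truth_fg <- ph$truth$data == lab[["fibroglandular"]]
  agreement <- mean((sm$fibroglandular == truth_fg)[m])
  expect_gte(agreement, 0.99)
  expect_true(all((sm$fat | sm$fibroglandular)[m]))
  expect_false(any(sm$fat & sm$fibroglandular))
})

test_that("a single-valued breast falls back to all-fat with a warning", {
  st <- image_stack(array(1425, c(8, 8, 2)))
  mask <- array(TRUE, c(8, 8, 2))
  expect_warning(sm <- segment_sound_speed(st, mask), "all-fat")
  expect_true(all(sm$fat[mask]))
  expect_false(any(sm$fibroglandular))
})

test_that("segmentation is invariant to affine rescaling of intensities", {
  ph <- small_phantom(seed = 6, fgf = 0.3)
  sm1 <- segment_sound_speed(ph$ss, ph$breast_mask, seed = 3)
  resc <- image_stack(2.5 * ph$ss$data + 100, ph$ss$spacing, "sound_speed",
                      origin = ph$ss$origin)
  sm2 <- segment_sound_speed(resc, ph$breast_mask, seed = 3)
  expect_identical(sm1$fibroglandular, sm2$fibroglandular)
})

test_that("trimodal stiffness is recovered exactly and partitions the mask", {
  set.seed(8)
  d <- c(12, 12, 2)
  vals <- sample(c(0.1, 0.5, 0.9), prod(d), replace = TRUE)
  S <- image_stack(array(vals, d), modality = "stiffness")
  mask <- array(TRUE, d)
  st <- segment_stiffness(S, mask, seed = 2)
  expect_equal(st$centroids, c(0.1, 0.5, 0.9))
  expect_true(all(st$soft[S$data == 0.1]))
  expect_true(all(st$hard[S$data == 0.9]))
  expect_equal(sum(st$soft) + sum(st$intermediate) + sum(st$hard), sum(mask))
})

test_that("six-component intersection encodes tissue x stiffness correctly", {
  d <- c(6, 6, 1)
  mask <- array(TRUE, d)
  fg <- array(FALSE, d); fg[1:3, , ] <- TRUE
  hard <- array(FALSE, d); hard[, 1:2, ] <- TRUE
  soft <- array(FALSE, d); soft[, 5:6, ] <- TRUE
  int <- !hard & !soft
  ss_masks <- list(fat = !fg, fibroglandular = fg)
  stiff_masks <- list(soft = soft, intermediate = int, hard = hard)
  labs <- intersect_six(ss_masks, stiff_masks, mask, spacing = c(0.75, 0.75, 2.5))
  # fibroglandular + hard voxel -> hard_fibroglandular
  expect_equal(labs$data[1, 1, 1],
               which(six_component_names() == "hard_fibroglandular"))
  expect_equal(labs$data[6, 6, 1],
               which(six_component_names() == "soft_fat"))
  expect_equal(sum(labs$data > 0), sum(mask))
  counts <- table(factor(labs$data[labs$data > 0], levels = 1:6))
  expect_equal(sum(counts), sum(mask))
})

test_that("all-fat plus all-soft yields a single occupied component", {
  d <- c(5, 5, 2); mask <- array(TRUE, d)
  f <- array(TRUE, d); e <- array(FALSE, d)
  labs <- intersect_six(list(fat = f, fibroglandular = e),
                        list(soft = f, intermediate = e, hard = e),
                        mask, spacing = c(1, 1, 1))
  expect_true(all(labs$data[mask] == 1))
})

test_that("non-partition mask families are rejected", {
  d <- c(4, 4, 1); mask <- array(TRUE, d)
  f <- array(TRUE, d); e <- array(FALSE, d)
  expect_error(intersect_six(list(fat = e, fibroglandular = e),
                             list(soft = f, intermediate = e, hard = e),
                             mask, spacing = c(1, 1, 1)), "partition")
  expect_error(intersect_six(list(fat = f, fibroglandular = f),
                             list(soft = f, intermediate = e, hard = e),
                             mask, spacing = c(1, 1, 1)), "partition")
})

test_that("segmentation masks are deterministic given the seed", {
  ph <- small_phantom(seed = 13, fgf = 0.3)
  m <- ph$breast_mask
  S <- fuse_stiffness(robust_normalize(ph$ss, m), robust_normalize(ph$att, m))
  a <- segment_stiffness(S, m, seed = 99)
  b <- segment_stiffness(S, m, seed = 99)
  expect_identical(a$hard, b$hard)
  expect_identical(a$centroids, b$centroids)
})
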