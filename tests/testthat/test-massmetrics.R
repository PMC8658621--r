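geom_default <- function(n = 40) {
  list(shape = c(n, n), spacing = c(0.75, 0.75), origin = c(0, 0))
}

test_that("an axis-aligned 7.5 mm square rasterizes to 100 pixels", {
  poly <- rbind(c(0, 0), c(7.5, 0), c(7.5, 7.5), c(0, 7.5))
  m <- rasterize_roi(poly, geom_default(20))
  expect_equal(sum(m), 100)
})

test_that("a sub-pixel triangle covers at most one pixel centre", {
  poly <- rbind(c(0.1, 0.1), c(0.6, 0.1), c(0.35, 0.6))
  m <- rasterize_roi(poly, geom_default(10))
  expect_lte(sum(m), 1)
})

test_that("translation by whole pixels preserves the rasterized count", {
  poly <- circle_polygon(c(6, 6), 3.3, 16)
  g <- geom_default(40)
  n0 <- sum(rasterize_roi(poly, g))
  shifted <- sweep(poly, 2, c(3 * 0.75, 5 * 0.75), "+")
  expect_equal(sum(rasterize_roi(shifted, g)), n0)
})

test_that("self-intersecting or degenerate polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(mass_roi(bowtie, 1, "cyst"), "self-intersecting")
  expect_error(mass_roi(rbind(c(0, 0), c(1, 1)), 1, "cyst"), "3 vertices")
})

test_that("stiffness index is the ROI mean", {
  S <- matrix(0.5, 10, 10)
  m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE
  expect_equal(stiffness_index(S, m), 0.5)
  S2 <- matrix(rep(c(0, 1), each = 50), 10, 10)
  expect_equal(stiffness_index(S2, matrix(TRUE, 10, 10)), 0.5)
  set.seed(3)
  S3 <- matrix(runif(100), 10, 10)
  m3 <- matrix(runif(100) > 0.5, 10, 10)
  expect_equal(stiffness_index(S3, m3), sum(S3[m3]) / sum(m3))
  expect_error(stiffness_index(S, matrix(FALSE, 10, 10)), "empty")
})

test_that("component percentages partition the ROI", {
  lab <- matrix(6L, 12, 12)  # hard fibroglandular everywhere
  m <- matrix(FALSE, 12, 12); m[4:9, 4:9] <- TRUE
  p <- roi_component_percentages(lab, m)
  expect_equal(unname(p$stiffness_pct), c(0, 0, 100))
  expect_equal(unname(p$component_pct[6]), 100)

  set.seed(9)
  lab2 <- matrix(sample(1:6, 144, replace = TRUE), 12, 12)
  p2 <- roi_component_percentages(lab2, m)
  expect_equal(sum(p2$stiffness_pct), 100)
  expect_equal(sum(p2$component_pct), 100)

  lab3 <- lab; lab3[4:5, 4:9] <- 0L
  expect_warning(p3 <- roi_component_percentages(lab3, m), "outside")
  expect_equal(sum(p3$stiffness_pct), 100)
})

test_that("GLCM homogeneity has its closed-form values", {
  S <- matrix(0.42, 8, 8)
  m <- matrix(TRUE, 8, 8)
  expect_equal(glcm_homogeneity(S, m), 1.0)

  # strict two-level checkerboard quantising to bins 0 and 7: every
  # horizontal pair differs by 7 levels, so homogeneity = 1/8
  chk <- matrix(rep(c(0.01, 0.99), 32), 8, 8)
  chk[, seq(2, 8, by = 2)] <- 1 - chk[, seq(2, 8, by = 2)]
  expect_equal(glcm_homogeneity(chk, m, offsets = list(c(0L, 1L))), 1 / 8)
})

test_that("GLCM homogeneity equals brute-force pair enumeration", {
  set.seed(11)
  for (i in 1:6) {
    S <- matrix(runif(16), 4, 4)
    m <- matrix(runif(16) > 0.25, 4, 4)
    if (sum(m) < 2) next
    expect_equal(glcm_homogeneity(S, m), brute_glcm_homogeneity(S, m))
  }
})

test_that("GLCM homogeneity ignores constant shifts within bins", {
  set.seed(12)
  centers <- (0:7 + 0.5) / 8
  S <- matrix(sample(centers, 36, replace = TRUE), 6, 6)
  m <- matrix(TRUE, 6, 6)
  expect_equal(glcm_homogeneity(S + 0.01, m), glcm_homogeneity(S, m))
})

test_that("GLCM is undefined when no offset yields a pair", {
  S <- matrix(0.5, 5, 5)
  m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m[1, 4] <- TRUE
  expect_warning(h <- glcm_homogeneity(S, m), "undefined")
  expect_true(is.na(h))
})

test_that("size classification splits at 1.5 cm equivalent diameter", {
  g <- geom_default(60)
  small <- classify_size(mass_roi(circle_polygon(c(20, 20), 5, 64), 1, "cyst"), g)
  expect_equal(small$size_class, "small")
  expect_equal(small$equivalent_diameter_cm, 1.0, tolerance = 0.05)
  large <- classify_size(mass_roi(circle_polygon(c(20, 20), 10, 64), 1, "cyst"), g)
  expect_equal(large$size_class, "large")
  expect_equal(large$equivalent_diameter_cm, 2.0, tolerance = 0.05)
})

test_that("the size tie rule is <=: d just under 15 mm is small", {
  # rectangles of 2 x 157 and 2 x 158 pixels bracket d = 15 mm
  g <- list(shape = c(4, 160), spacing = c(0.75, 0.75), origin = c(0, 0))
  r314 <- rbind(c(0, 0), c(1.5, 0), c(1.5, 117.75), c(0, 117.75))
  r316 <- rbind(c(0, 0), c(1.5, 0), c(1.5, 118.5), c(0, 118.5))
  s1 <- classify_size(mass_roi(r314, 1, "cyst"), g)
  s2 <- classify_size(mass_roi(r316, 1, "cyst"), g)
  expect_equal(s1$area_mm2, 314 * 0.5625)
  expect_equal(s1$size_class, "small")   # d = 14.996 mm
  expect_equal(s2$size_class, "large")   # d = 15.043 mm
})

test_that("phantom cyst ROIs read as soft with full metric records", {
  ph <- small_phantom(seed = 31, fgf = 0.25,
                      masses = list(mass_spec("cyst", c(0, 0, 12), 10)))
  zc <- (seq_len(10) - 0.5) * 2.5
  roi <- mass_roi(circle_polygon(c(0, 0), 4.5), which.min(abs(zc - 12)), "cyst")
  fit <- breast_stiffness(ph$ss, ph$att, ph$breast_mask, rois = list(roi),
                          filter = NULL, seed = 31)
  rec <- fit$masses
  expect_equal(nrow(rec), 1L)
  expect_gt(rec$pct_soft, 80)
  expect_equal(rec$pct_soft + rec$pct_intermediate + rec$pct_hard, 100)
  expect_equal(sum(unlist(rec[paste0("pct_", six_component_names())])), 100)
  expect_true(rec$stiffness_index >= 0 && rec$stiffness_index <= 1)
  expect_equal(rec$size_class, "small")
})
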