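test_that("degenerate fibroglandular fractions give single-tissue breasts", {
  ph <- small_phantom(seed = 3, fgf = 0)
  lab <- phantom_labels()
  m <- ph$breast_mask$data != 0
  expect_true(all(ph$truth$data[m] == lab[["fat"]]))
  expect_true(all(ph$truth$data[!m] == lab[["outside"]]))

  ph1 <- small_phantom(seed = 3, fgf = 1)
  expect_true(all(ph1$truth$data[ph1$breast_mask$data != 0] ==
                    lab[["fibroglandular"]]))
})

test_that("realised fibroglandular fraction matches the request", {
  # the emulated cohort-mean composition on a full-size grid
  spec <- phantom_spec(grid_shape = c(200, 200, 40), breast_radius = 60,
                       fibroglandular_fraction = 0.291, seed = 11)
  ph <- generate_phantom(spec)
  expect_gte(ph$realised_fg_fraction, 0.281)
  expect_lte(ph$realised_fg_fraction, 0.301)
})

test_that("realised fraction stays quantisation-accurate as the grid grows", {
  sizes <- list(c(48, 48, 8), c(96, 96, 12), c(144, 144, 16))
  tol <- c(0.01, 0.005, 0.0025)
  for (i in seq_along(sizes)) {
    spec <- phantom_spec(grid_shape = sizes[[i]],
                         breast_radius = 0.3 * sizes[[i]][1] * 0.75,
                         fibroglandular_fraction = 0.3, seed = 5)
    ph <- generate_phantom(spec)
    expect_lt(abs(ph$realised_fg_fraction - 0.3), tol[i])
  }
})

test_that("phantoms are deterministic in the seed and vary across seeds", {
  a <- small_phantom(seed = 7)
  b <- small_phantom(seed = 7)
  expect_identical(a$ss$data, b$ss$data)
  expect_identical(a$att$data, b$att$data)
  expect_identical(a$truth$data, b$truth$data)
  c_ <- small_phantom(seed = 8)
  expect_false(identical(a$ss$data, c_$ss$data))
})

test_that("attenuation orders cyst < fat < cancer within truth labels", {
  ph <- small_phantom(seed = 2, fgf = 0.25,
                      masses = list(mass_spec("cyst", c(-8, 0, 12), 8),
                                    mass_spec("cancer", c(8, 0, 12), 8)))
  lab <- phantom_labels()
  att <- ph$att$data; tr <- ph$truth$data
  expect_lt(mean(att[tr == lab[["cyst"]]]), mean(att[tr == lab[["fat"]]]))
  expect_lt(mean(att[tr == lab[["fat"]]]), mean(att[tr == lab[["cancer"]]]))
})

test_that("a 10 mm mass spans the voxel counts its diameter implies", {
  # centre placed on an in-plane voxel centre and midway between slice
  # centres: 13 voxels across in-plane (10/0.75), 4 slices through (10/2.5)
  spec <- phantom_spec(grid_shape = c(64, 64, 10), breast_radius = 20,
                       fibroglandular_fraction = 0, seed = 1,
                       masses = list(mass_spec("cancer", c(0.375, 0.375, 10), 10)))
  ph <- generate_phantom(spec)
  lab <- phantom_labels()
  mass <- ph$truth$data == lab[["cancer"]]
  co <- list(x = (seq_len(64) - 0.5) * 0.75 - 24,
             z = (seq_len(10) - 0.5) * 2.5)
  ix <- which(abs(co$x - 0.375) < 1e-9)
  iz <- which(apply(mass, 3, any))
  expect_equal(length(iz), 4L)
  # central in-plane row at the slice nearest the centre
  kc <- iz[which.min(abs(co$z[iz] - 10))]
  expect_equal(sum(mass[, ix, kc]), 13L)
})

test_that("mass insertion rejects invalid placements", {
  ph <- small_phantom(seed = 1, fgf = 0)
  expect_error(
    insert_mass(ph$ss, ph$att, ph$truth, ph$breast_mask,
                mass_spec("cyst", c(21, 0, 12), 10)),
    "outside the breast")
  upd <- insert_mass(ph$ss, ph$att, ph$truth, ph$breast_mask,
                     mass_spec("cyst", c(0, 0, 12), 8))
  expect_error(
    insert_mass(upd$ss, upd$att, upd$truth, ph$breast_mask,
                mass_spec("cancer", c(2, 0, 12), 8)),
    "overlap")
})

test_that("cyst attenuation sits below the fat baseline by construction", {
  ph <- small_phantom(seed = 4, fgf = 0, noise_sd_ss = 0, noise_sd_att = 0,
                      masses = list(mass_spec("cyst", c(0, 0, 12), 10)))
  lab <- phantom_labels()
  expect_true(all(ph$att$data[ph$truth$data == lab[["cyst"]]] < 0.20))
})

test_that("zero heterogeneity gives a noise-free homogeneous interior", {
  ph <- small_phantom(seed = 4, fgf = 0, noise_sd_ss = 0, noise_sd_att = 0,
                      masses = list(mass_spec("fibroadenoma", c(0, 0, 12), 10,
                                              heterogeneity = 0)))
  lab <- phantom_labels()
  vals <- ph$ss$data[ph$truth$data == lab[["fibroadenoma"]]]
  expect_equal(stats::var(vals), 0)
})

test_that("optional skin rim is a thin high-attenuation band inside the mask", {
  ph <- small_phantom(seed = 6, fgf = 0.2, skin_rim = TRUE)
  lab <- phantom_labels()
  rim <- ph$truth$data == lab[["skin"]]
  m <- ph$breast_mask$data != 0
  expect_true(any(rim))
  expect_true(all(m[rim]))
  expect_true(all(ph$att$data[rim] > 0.5))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(fibroglandular_fraction = 1.2), "fraction")
  expect_error(phantom_spec(spacing = c(0.75, -1, 2.5)), "positive")
  expect_error(phantom_spec(grid_shape = c(16, 16, 4), breast_radius = 40),
               "too small")
})
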