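test_that("Welch t-test matches its closed form", {
  # xs = 1,2,3 vs ys = 2,3,4: t = -1/sqrt(2/3) = -1.224745, Welch df = 4,
  # two-sided p = 0.287864 (frozen from the closed-form computation)
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)
})

test_that("Welch t-test handles identical groups and symmetry", {
  r0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  rc <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(rc$p, 1)
  a <- c(0.2, 0.5, 0.9, 0.4); b <- c(0.1, 0.3, 0.35)
  expect_equal(welch_t_test(a, b)$p, welch_t_test(b, a)$p)
  expect_equal(welch_t_test(a, b)$t, -welch_t_test(b, a)$t)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("chi-squared matches its closed form and invariances", {
  # [[10,20],[20,10]]: X^2 = 60*(10*10-20*20)^2/(30*30*30*30) = 20/3
  r <- chi_squared(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  expect_equal(r$p, 1 - stats::pchisq(20 / 3, 1), tolerance = 1e-9)

  prop <- matrix(c(10, 20, 30, 60), 2)  # proportional rows
  r0 <- chi_squared(prop)
  expect_equal(r0$chi2, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  tab <- matrix(c(5, 9, 2, 14, 3, 8), 2)
  expect_equal(chi_squared(tab)$chi2, chi_squared(tab[2:1, ])$chi2)
  expect_equal(chi_squared(tab)$chi2, chi_squared(tab[, c(2, 1, 3)])$chi2)
  expect_error(chi_squared(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_squared(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("the 5-95 percentile interval uses order-statistic interpolation", {
  expect_equal(percentile_interval_5_95(0:100), c(5, 95))
  expect_equal(percentile_interval_5_95(rep(3.2, 10)), c(3.2, 3.2))
  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(sample(10:200, 1))
    expect_equal(percentile_interval_5_95(x),
                 c(manual_quantile7(x, 0.05), manual_quantile7(x, 0.95)))
  }
  expect_error(percentile_interval_5_95(1), "at least 2")
})

test_that("group comparisons produce one row per stratum, pair and metric", {
  set.seed(15)
  mk <- function(h, sz, fl, n, mu)
    data.frame(histology = h, size_class = sz, filtered = fl,
               stiffness_index = pmin(pmax(rnorm(n, mu, 0.05), 0), 1),
               homogeneity = runif(n, 0.5, 1))
  recs <- do.call(rbind, lapply(c(FALSE, TRUE), function(fl)
    do.call(rbind, lapply(c("small", "large"), function(sz)
      rbind(mk("cancer", sz, fl, 6, 0.8),
            mk("fibroadenoma", sz, fl, 6, 0.5),
            mk("cyst", sz, fl, 6, 0.1))))))
  cmp <- compare_mass_groups(recs)
  expect_equal(nrow(cmp), 4 * 3 * 2)  # strata x pairs x metrics
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$lo_a <= cmp$hi_a))
  ca_cy <- cmp[cmp$group_a == "cancer" & cmp$group_b == "cyst" &
                 cmp$metric == "stiffness_index", ]
  expect_true(all(ca_cy$significant))
  expect_true(all(ca_cy$n_a == 6 & ca_cy$n_b == 6))
})

test_that("underpowered strata are skipped with a message", {
  recs <- data.frame(histology = c("cancer", "cancer", "cyst"),
                     size_class = "small", filtered = FALSE,
                     stiffness_index = c(0.8, 0.9, 0.1),
                     homogeneity = c(0.7, 0.8, 0.95))
  expect_message(cmp <- compare_mass_groups(recs), "<2 per group")
  expect_equal(nrow(cmp), 0)
})

test_that("report rendering writes consistent, round-trippable tables", {
  dir <- file.path(tempdir(), "ustiff_reports")
  vols <- component_volume_table(fat = c(347, 160, 16),
                                 fibroglandular = c(61, 87, 66))
  files <- render_reports(volumes = vols, dir = dir)
  expect_named(files, "component_volumes.csv")
  back <- utils::read.csv(files[["component_volumes.csv"]])
  expect_equal(back$total_cc[back$stiffness == "total"], 737)
  expect_equal(names(back), c("stiffness", "fg_cc", "fg_pct", "fat_cc",
                              "fat_pct", "total_cc", "total_pct"))

  set.seed(16)
  recs <- data.frame(histology = rep(c("cancer", "cyst"), each = 4),
                     size_class = "small", filtered = FALSE,
                     breast_id = "b", slice_index = 1,
                     stiffness_index = runif(8), homogeneity = runif(8))
  for (nm in paste0("pct_", six_component_names()))
    recs[[nm]] <- 100 / 6
  cmp <- compare_mass_groups(recs)
  files2 <- render_reports(volumes = vols, records = recs,
                           comparisons = cmp, dir = dir)
  expect_true(all(c("mass_records.csv", "mass_comparisons.csv",
                    "mass_component_distributions.csv") %in% names(files2)))
  dist <- utils::read.csv(files2[["mass_component_distributions.csv"]])
  expect_equal(rowSums(dist[, grepl("^pct_", names(dist))]),
               rep(100, nrow(dist)), ignore_attr = TRUE)
})
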