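test_that("uptake normalization follows the counting-standard rule", {
  # whole added activity in the lysate, 100,000 cells -> 100 %AA
  expect_equal(uptake_percent(1500, 100, 100 / 1500, 1e5), 100)
  # doubling the cell number halves the per-100,000 value
  expect_equal(uptake_percent(1500, 100, 100 / 1500, 2e5), 50)
  # linear in lysate counts
  expect_equal(uptake_percent(c(10, 20, 40), 100, 1 / 15, 1e5),
               uptake_percent(10, 100, 1 / 15, 1e5) * c(1, 2, 4))
  expect_error(uptake_percent(10, 0, 1 / 15, 1e5), "standard_counts")
})

test_that("synthetic uptake measurements recover the generating value", {
  g <- gen_uptake(seed = 4)
  est <- uptake_percent(g$data$lysate_counts, g$data$standard_counts[1],
                        g$data$standard_fraction_of_added[1],
                        g$data$cell_count[1])
  expect_equal(mean(est), 1.87, tolerance = 0.10)
})

test_that("IC50 fit is exact at zero noise and robust to rescaling", {
  cc <- 10^seq(-13, -6, length.out = 8)
  b <- 0.02 + 0.98 / (1 + cc / 1.53e-8)
  fit <- fit_ic50(cc, b)
  expect_false(fit$flagged)
  expect_equal(signif(fit$ic50_m, 3), 1.53e-8)

  fit2 <- fit_ic50(cc, b * 7.3)  # multiplicative rescaling
  expect_equal(fit2$ic50_m, fit$ic50_m, tolerance = 1e-6)

  fit3 <- fit_ic50(cc, b, fix_hill = TRUE)
  expect_identical(fit3$hill, 1)
  expect_equal(fit3$ic50_m, 1.53e-8, tolerance = 1e-3)
})

test_that("degenerate displacement curves are flagged, not fitted", {
  cc <- 10^seq(-13, -6, length.out = 8)
  flat <- fit_ic50(cc, rep(1, 8))
  expect_true(flat$flagged)
  expect_true(is.na(flat$ic50_m))

  expect_error(fit_ic50(cc[1:4], rep(1, 4)), ">= 6 concentrations")
})

test_that("IC50 recovery holds under 5% assay noise", {
  hits <- vapply(1:30, function(s) {
    g <- gen_displacement(seed = s)
    f <- fit_ic50(g$data$concentration_m, g$data$bound)
    !f$flagged && f$ic50_m > 1.53e-8 / 1.5 && f$ic50_m < 1.53e-8 * 1.5
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
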