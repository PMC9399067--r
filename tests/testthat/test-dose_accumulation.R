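test_that("dose components are zero at zero concentration and linear", {
  sv <- reference_svalues()
  z <- phase_dose("Lu-177", 0, "average", sv)
  expect_true(all(z == 0))

  d1 <- phase_dose("Lu-177", 0.2e6, "average", sv)
  d2 <- phase_dose("Lu-177", 0.4e6, "average", sv)
  expect_equal(unname(d2), unname(2 * d1), tolerance = 1e-12)

  # additivity of the total
  expect_equal(d2[["total"]],
               sum(d2[setdiff(names(d2), "total")]), tolerance = 1e-12)
})

test_that("dose table reproduces the exact concentration ratio structure", {
  dt <- dose_table("Lu-177")
  avg <- dt[dt$size_class == "average", ]
  t01 <- avg$total_gy[avg$concentration_bq_per_ml == 0.1e6]
  t05 <- avg$total_gy[avg$concentration_bq_per_ml == 0.5e6]
  expect_equal(t05 / t01, 5, tolerance = 1e-12)

  # min/avg and max/avg column proportionality constant across concentrations
  for (nuc in c("Lu-177", "Ac-225")) {
    d <- dose_table(nuc)
    d <- d[d$concentration_bq_per_ml > 0, ]
    wide <- split(d$total_gy, d$size_class)
    expect_lt(diff(range(wide$minimum / wide$average)), 1e-12)
    expect_lt(diff(range(wide$maximum / wide$average)), 1e-12)
  }
})

test_that("dose table flags the highest concentrations and handles edge cases", {
  dt <- dose_table("Ac-225")
  expect_true(all(dt$excluded_from_fit[dt$concentration_bq_per_ml > 750]))
  expect_false(any(dt$excluded_from_fit[dt$concentration_bq_per_ml <= 750]))

  empty <- dose_table("Lu-177", concentrations = numeric())
  expect_identical(nrow(empty), 0L)

  # missing S values surface as lookup errors
  sv <- reference_svalues()
  sv <- sv[sv$setup != "attached", ]
  expect_error(phase_dose("Lu-177", 0.4e6, "average", sv),
               "no unique S value")
})

test_that("alpha-chain dose per unit concentration dwarfs the beta dose", {
  lu <- dose_table("Lu-177")
  ac <- dose_table("Ac-225")
  per_bq <- function(d) {
    a <- d[d$size_class == "average" & d$concentration_bq_per_ml > 0, ]
    a$total_gy[1] / a$concentration_bq_per_ml[1]
  }
  expect_gt(per_bq(ac) / per_bq(lu), 100)
})

test_that("medium contribution and totals sit near the published dosimetry", {
  # soft comparison against the bundled reference outputs (factor 1.5)
  ref <- reference_dose_totals()
  for (nuc in c("Lu-177", "Ac-225")) {
    d <- dose_table(nuc)
    d <- d[d$size_class == "average" & !d$excluded_from_fit &
             d$concentration_bq_per_ml > 0, ]
    r <- ref[ref$nuclide == nuc, ]
    m <- merge(d, r, by = "concentration_bq_per_ml")
    expect_true(all(m$total_gy / m$average < 1.5 &
                      m$total_gy / m$average > 1 / 1.5))
  }
})
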