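test_that("bound activity per cell follows the uptake normalization", {
  expect_equal(bound_activity_per_cell(0.4e6, 1, 1.87, 1e5), 0.0748,
               tolerance = 1e-12)
  expect_identical(bound_activity_per_cell(0, 1, 1.87, 1e5), 0)
  expect_error(bound_activity_per_cell(1e5, 1, 1.87, 0), "positive")
})

test_that("partition fractions derive from the ratio and sum to one", {
  p <- partition_model(0.76)
  expect_equal(p$membrane, 0.76 / 1.76, tolerance = 1e-12)
  expect_equal(p$internal, 1 / 1.76, tolerance = 1e-12)
  expect_identical(p$membrane + p$internal, 1)
})

test_that("clearance fit recovers noiseless parameters exactly", {
  t <- c(0, 4, 24, 48, 120)
  r <- 0.41 + 0.59 * exp(-log(2) * t / 2.3)
  fit <- fit_clearance(rep(t, 3), rep(r, 3))
  expect_equal(fit$plateau_fraction, 0.41, tolerance = 1e-6)
  expect_equal(fit$biological_half_life_h, 2.3, tolerance = 1e-6)
  expect_false(fit$flagged)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("degenerate and invalid clearance inputs are handled", {
  t <- c(0, 4, 24, 48, 120)
  flat <- fit_clearance(t, rep(1, 5))
  expect_true(flat$flagged)
  expect_true(is.na(flat$biological_half_life_h))

  expect_error(fit_clearance(c(1, 2, 3), c(1, 0.5, 0.4)), ">= 4 time points")
  expect_error(fit_clearance(t, c(1, 0.9, 0.8, 0.7, 1.5)), "\\[0, 1.1\\]")
})

test_that("clearance fit recovers generating values under assay noise", {
  hits <- vapply(1:40, function(s) {
    g <- gen_excretion(seed = s)
    f <- fit_clearance(g$data$time_h, g$data$retained_fraction)
    f$biological_half_life_h >= 2.0 && f$biological_half_life_h <= 2.6 &&
      f$plateau_fraction >= 0.37 && f$plateau_fraction <= 0.45
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("time-integrated activity has the right limits and closed form", {
  # rectangle: no decay, no clearance
  expect_equal(time_integrated_activity(2, Inf, NULL, 10), 2 * 10 * 3600)

  # documented Lu-177 colony-phase value, against quadrature
  clr <- clearance_model(0.41, 2.3)
  tia <- time_integrated_activity(1, 6.647 * 24, clr, 168)
  expect_equal(tia, 1.83e5, tolerance = 0.005)
  expect_equal(tia, quadrature_tia(1, 6.647 * 24, clr, 168),
               tolerance = 1e-8)
})

test_that("closed-form TIA agrees with adaptive quadrature on a grid", {
  grid <- expand.grid(p = c(0, 0.2, 0.41, 0.9),
                      tb = c(0.5, 2.3, 30),
                      tp = c(10, 6.647 * 24, Inf),
                      dur = c(1, 24, 168))
  for (i in seq_len(nrow(grid))) {
    clr <- clearance_model(grid$p[i], grid$tb[i])
    a <- time_integrated_activity(1, grid$tp[i], clr, grid$dur[i])
    b <- quadrature_tia(1, grid$tp[i], clr, grid$dur[i])
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("TIA is monotone in duration and in the half-lives", {
  clr <- clearance_model(0.41, 2.3)
  tia <- function(tp, tb, d)
    time_integrated_activity(1, tp, clearance_model(0.41, tb), d)
  expect_lt(tia(159.5, 2.3, 24), tia(159.5, 2.3, 168))
  expect_lt(tia(50, 2.3, 168), tia(159.5, 2.3, 168))
  expect_lt(tia(159.5, 1.0, 168), tia(159.5, 4.0, 168))
})
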