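test_that("survival fractions and Poisson errors follow the ratio rule", {
  sf <- survival_fractions(c(110, 110, 110, 220, 220, 220),
                           c("d", "d", "d", "0", "0", "0"))
  expect_equal(sf$survival_fraction, 0.5)
  expect_equal(sf$sd, 0.5 * sqrt(1 / 110 + 1 / 220), tolerance = 1e-12)

  # treated identical to untreated
  sf1 <- survival_fractions(c(200, 200, 200, 200), c("a", "a", "0", "0"))
  expect_equal(sf1$survival_fraction, 1)

  # complete kill: zero SF with a one-sided upper bound
  sf0 <- survival_fractions(c(0, 0, 0, 220, 230, 210),
                            c("hi", "hi", "hi", "0", "0", "0"))
  expect_identical(sf0$survival_fraction, 0)
  expect_true(is.na(sf0$sd))
  expect_gt(sf0$sf_upper95, 0)

  expect_error(survival_fractions(c(0, 0), c("a", "0")), "zero")
})

test_that("noiseless log-linear data inverts exactly", {
  d <- c(0.74, 1.48, 2.22, 2.96, 3.70)
  pts <- data.frame(dose = d, survival_fraction = exp(-0.16 * d))
  fit <- fit_alpha(pts)
  expect_equal(fit$alpha, 0.16, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("alpha fitting is dose-scale equivariant and filters points", {
  d <- c(0.5, 1, 2, 4)
  pts <- data.frame(dose = d,
                    survival_fraction = exp(-0.3 * d) * c(1.02, 0.97, 1.01, 0.99),
                    sd = rep(0.02, 4))
  f1 <- fit_alpha(pts)
  pts2 <- pts; pts2$dose <- pts2$dose * 3
  f2 <- fit_alpha(pts2)
  expect_equal(f2$alpha, f1$alpha / 3, tolerance = 1e-12)

  # excluded flag and SF = 0 handling
  pts3 <- rbind(pts, data.frame(dose = c(8, 10),
                                survival_fraction = c(0.2, 0),
                                sd = c(0.05, NA)))
  pts3$excluded <- c(rep(FALSE, 4), TRUE, FALSE)
  expect_warning(f3 <- fit_alpha(pts3), "SF = 0")
  expect_identical(f3$n_points, 4L)

  expect_error(fit_alpha(pts[1:2, ]), ">= 3 usable points")
})

test_that("simulated assays at study noise give high R^2 and alpha coverage", {
  res <- lapply(1:25, function(s)
    simulate_rbe_experiment(seed = s))
  r2 <- vapply(res, function(x)
    min(x$fit_lu$r_squared, x$fit_ac$r_squared), 0)
  expect_gte(mean(r2 >= 0.96), 0.9)
  cover <- vapply(res, function(x)
    abs(x$fit_lu$alpha - 0.16) <= 2 * x$fit_lu$alpha_se &&
      abs(x$fit_ac$alpha - 0.67) <= 2 * x$fit_ac$alpha_se, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("RBE and its propagated error follow the delta method", {
  expect_equal(rbe(list(alpha = 0.3, alpha_se = 0.01),
                   list(alpha = 0.3, alpha_se = 0.01))$rbe, 1)

  r <- rbe(list(alpha = 0.67, alpha_se = 0.06),
           list(alpha = 0.16, alpha_se = 0.01))
  expect_equal(r$rbe, 4.19, tolerance = 0.002)
  expect_equal(r$rbe_se, 0.457, tolerance = 0.002)

  # scale invariance
  r2 <- rbe(list(alpha = 6.7, alpha_se = 0.6),
            list(alpha = 1.6, alpha_se = 0.1))
  expect_equal(r2$rbe, r$rbe, tolerance = 1e-12)

  expect_error(rbe(list(alpha = 0.5, alpha_se = 0.1),
                   list(alpha = 0, alpha_se = 0.1)), "positive")
})

test_that("delta-method RBE error agrees with a Monte Carlo ratio oracle", {
  set.seed(99)
  at <- rnorm(1e5, 0.67, 0.06)
  ar <- rnorm(1e5, 0.16, 0.01)
  mc_sd <- sd(at / ar)
  r <- rbe(list(alpha = 0.67, alpha_se = 0.06),
           list(alpha = 0.16, alpha_se = 0.01))
  expect_equal(r$rbe_se, mc_sd, tolerance = 0.05)
})

test_that("optional quadratic term is available but off by default", {
  d <- c(1, 2, 3, 4, 5)
  pts <- data.frame(dose = d,
                    survival_fraction = exp(-0.2 * d - 0.05 * d^2))
  f_lin <- fit_alpha(pts)
  expect_null(f_lin$beta)
  f_lq <- fit_alpha(pts, include_beta = TRUE)
  expect_equal(f_lq$alpha, 0.2, tolerance = 1e-8)
  expect_equal(f_lq$beta, 0.05, tolerance = 1e-8)
})
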