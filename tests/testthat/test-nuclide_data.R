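test_that("decay chains carry the documented structure", {
  ac <- load_chain("Ac-225")
  lu <- load_chain("Lu-177")

  expect_equal(alpha_emissions_per_decay(ac), 4, tolerance = 1e-12)
  expect_equal(alpha_emissions_per_decay(lu), 0)

  # Lu-177: one radioactive step, stable terminus
  hl <- vapply(lu$steps, `[[`, 0, "half_life_s")
  expect_identical(sum(is.finite(hl)), 1L)

  # branching at Bi-213 sums to one
  bi <- Filter(function(s) s$name == "Bi-213", ac$steps)[[1]]
  expect_equal(sum(vapply(bi$daughters, `[[`, 0, "fraction")), 1,
               tolerance = 1e-9)

  expect_error(load_chain("Th-227"), "unsupported")
})

test_that("chains survive a JSON round trip", {
  for (nuc in c("Lu-177", "Ac-225")) {
    ch <- load_chain(nuc)
    ch2 <- chain_from_json(chain_to_json(ch))
    expect_equal(ch2$parent, ch$parent)
    expect_equal(length(ch2$steps), length(ch$steps))
    for (i in seq_along(ch$steps)) {
      expect_equal(ch2$steps[[i]]$half_life_s, ch$steps[[i]]$half_life_s)
      expect_equal(ch2$steps[[i]]$emissions$mev, ch$steps[[i]]$emissions$mev)
      expect_equal(ch2$steps[[i]]$emissions$yield,
                   ch$steps[[i]]$emissions$yield)
    }
  }
})

test_that("Bateman activities honour initial conditions and equilibrium", {
  ac <- load_chain("Ac-225")

  a0 <- bateman_activities(ac, 0, 1000)
  expect_equal(unname(a0[["Ac-225"]]), 1000, tolerance = 1e-9)
  expect_true(all(a0[setdiff(names(a0), "Ac-225")] == 0))

  # Fr-221 ingrowth after the 30-minute wait
  a30 <- bateman_activities(ac, 30 * 60, 1000)
  expect_equal(a30[["Fr-221"]] / a30[["Ac-225"]], 0.987, tolerance = 2e-3)

  # secular equilibrium at 24 h
  a24 <- bateman_activities(ac, 24 * 3600, 1000)
  expect_equal(a24[["Fr-221"]] / a24[["Ac-225"]], 1.000, tolerance = 1e-3)

  expect_error(bateman_activities(ac, -1, 1000), "non-negative")
})

test_that("Bateman solution matches a stiff ODE oracle and conserves atoms", {
  skip_if_not_installed("deSolve")
  for (nuc in c("Lu-177", "Ac-225")) {
    ch <- load_chain(nuc)
    times <- c(60, 1800, 3600, 86400, 4.32e5, 8.64e5)  # up to 10 days
    oracle <- ode_chain_activities(ch, times, 1)
    mine <- bateman_activities(ch, times, 1)
    sig <- oracle > 1e-12  # members with non-negligible activity
    rel <- abs(mine - oracle) / pmax(oracle, 1e-300)
    expect_lt(max(rel[sig]), 1e-6)
    expect_true(all(mine >= 0))

    # atom conservation including the stable terminus
    lam1 <- log(2) / ch$steps[[1]]$half_life_s
    for (t in times)
      expect_equal(sum(bateman_atoms(ch, t, 1)), 1 / lam1,
                   tolerance = 1e-9)
  }
})

test_that("charged energy per decay is correct and class-additive", {
  lu <- load_chain("Lu-177")
  ac <- load_chain("Ac-225")

  expect_identical(charged_energy_per_decay(lu, "alpha"), 0)
  expect_equal(
    charged_energy_per_decay(lu, c("beta_mean", "conversion_auger_electron")),
    0.147, tolerance = 0.005 / 0.147)
  expect_equal(charged_energy_per_decay(ac, "alpha"), 27.6,
               tolerance = 0.02)

  # additivity over disjoint class sets
  all_classes <- emission_classes()
  total <- charged_energy_per_decay(ac, all_classes)
  parts <- vapply(all_classes, function(cl)
    charged_energy_per_decay(ac, cl), 0)
  expect_equal(sum(parts), total, tolerance = 1e-12)

  expect_error(charged_energy_per_decay(ac, character()), "non-empty")
  expect_error(charged_energy_per_decay(ac, "neutrino"), "unknown")
})

test_that("Fr-221 reaches 98% of equilibrium just under the 30-minute rule", {
  ac <- load_chain("Ac-225")
  t98 <- daughter_equilibration_time(ac, 0.98)
  expect_equal(t98 / 60, 27.1, tolerance = 0.02)
  expect_lt(t98, 30 * 60)
})
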