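# single 5-MeV alpha emitter decaying to a stable daughter
toy_alpha_chain <- function() {
  chain_from_json(paste0(
    '{"parent":"X-1","steps":[',
    '{"name":"X-1","half_life_s":1000,',
    '"emissions":[{"class":"alpha","mev":5,"yield":1}],',
    '"daughters":[["Y-1",1]]},',
    '{"name":"Y-1","half_life_s":null,"emissions":[],"daughters":[]}]}'))
}

photon_only_chain <- function() {
  chain_from_json(paste0(
    '{"parent":"P-1","steps":[',
    '{"name":"P-1","half_life_s":1000,',
    '"emissions":[{"class":"photon","mev":0.2,"yield":1}],',
    '"daughters":[["Q-1",1]]},',
    '{"name":"Q-1","half_life_s":null,"emissions":[],"daughters":[]}]}'))
}

test_that("medium S values match the analytic equilibrium-dose expectation", {
  expect_equal(medium_svalue(load_chain("Lu-177")), 2.30e-11,
               tolerance = 0.10)
  expect_equal(medium_svalue(load_chain("Ac-225")), 4.57e-9,
               tolerance = 0.10)
  expect_identical(medium_svalue(photon_only_chain()), 0)
  # inversely proportional to the medium mass
  expect_equal(medium_svalue(load_chain("Lu-177"), 2),
               medium_svalue(load_chain("Lu-177")) / 2)
})

test_that("self S values respect energy conservation and reproducibility", {
  g <- default_cell_geometry()$floating$average
  ac <- load_chain("Ac-225")
  sv <- suppressWarnings(self_svalue(g, "cytoplasm", ac,
                                     n_histories = 2e4, seed = 11))
  expect_gte(sv$absorbed_fraction, 0)
  expect_lte(sv$absorbed_fraction, 1)
  e_tot <- charged_energy_per_decay(
    ac, c("alpha", "beta_mean", "conversion_auger_electron"))
  m_kg <- nucleus_volume(g) * 1e-15
  expect_lte(sv$value, e_tot * 1.602176634e-13 / m_kg)

  sv2 <- suppressWarnings(self_svalue(g, "cytoplasm", ac,
                                      n_histories = 2e4, seed = 11))
  expect_identical(sv$value, sv2$value)  # bit-reproducible under the seed
  sv3 <- suppressWarnings(self_svalue(g, "cytoplasm", ac,
                                      n_histories = 2e4, seed = 12))
  expect_false(identical(sv$value, sv3$value))

  expect_error(self_svalue(g, "cytoplasm", ac, n_histories = 100),
               ">= 1e4")
})

test_that("alpha self-dose vanishes beyond the particle range", {
  # membrane source ~97 um from a 3-um nucleus: beyond the 37-um range
  g <- floating_cell_geometry(cell_radius = 100, nucleus_radius = 3)
  sv <- suppressWarnings(self_svalue(g, "cell_membrane", toy_alpha_chain(),
                                     n_histories = 1e4, seed = 5))
  expect_identical(sv$value, 0)
})

test_that("self S values decrease with cell size for every source", {
  geo <- default_cell_geometry()
  ac <- load_chain("Ac-225")
  for (setup in c("floating", "attached")) {
    for (src in c("cell_membrane", "cytoplasm")) {
      v <- vapply(c("minimum", "average", "maximum"), function(sz)
        suppressWarnings(self_svalue(geo[[setup]][[sz]], src, ac,
                                     n_histories = 3e4, seed = 21))$value, 0)
      expect_true(all(diff(v) < 0),
                  info = paste(setup, src, paste(signif(v, 3),
                                                 collapse = " > ")))
    }
  }
})

test_that("MC standard error shrinks with the number of histories", {
  g <- default_cell_geometry()$floating$average
  ac <- load_chain("Ac-225")
  r1 <- suppressWarnings(self_svalue(g, "cytoplasm", ac,
                                     n_histories = 1e4, seed = 31))
  r2 <- suppressWarnings(self_svalue(g, "cytoplasm", ac,
                                     n_histories = 9e4, seed = 31))
  expect_lt(r2$mc_rel_err, r1$mc_rel_err)
})

test_that("cross-dose S value behaves with occupancy and nuclide", {
  lu <- load_chain("Lu-177")
  # no neighbours, no cross dose
  cfg0 <- cross_dose_config(occupancy = 1e-9)
  expect_identical(cross_svalue(cfg0, lu, n_realizations = 5,
                                seed = 1)$value, 0)
  # alpha-chain cross dose is far below the alpha self dose
  ac <- load_chain("Ac-225")
  cs_ac <- cross_svalue(cross_dose_config(), ac, n_realizations = 10,
                        seed = 2, cone_samples = 500)
  self_ac <- lookup_svalue(reference_svalues(), "Ac-225", "floating",
                           "cytoplasm", "average")
  expect_lt(cs_ac$value, 0.01 * self_ac)
})

test_that("engine S-value table has the documented layout", {
  tab <- suppressWarnings(compute_svalue_table(
    nuclides = "Ac-225",
    n_histories = 1e4, seed = 3, include_cross = FALSE))
  expect_identical(nrow(tab), 13L)  # 12 self cells + medium
  expect_setequal(unique(tab$setup), c("floating", "attached", "medium"))
  v <- lookup_svalue(tab, "Ac-225", "floating", "cytoplasm", "average")
  expect_true(is.finite(v) && v > 0)
  expect_error(lookup_svalue(tab, "Lu-177", "floating", "cytoplasm",
                             "average"), "no unique S value")
})
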