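# ---------------------------------------------------------------------------
# Bundled reference data and study-condition defaults: geometry of the
# PC3-PIP assay, experimentally derived kinetic constants, concentration
# grids of the clonogenic assay, and reference S values / cumulated doses
# obtained with a full Monte Carlo particle-transport simulation (Geant4)
# of the same set-up, kept for validation and as optional pipeline inputs.
# ---------------------------------------------------------------------------

#' Default cell geometry configuration
#'
#' Three size classes (minimum / average / maximum) for the floating
#' (spherical) and attached (ellipsoidal) set-ups. Floating cell radii are
#' 7, 8.7 and 10 um (the average chosen so that 100,000 cells in 1 mL give
#' an occupancy of ~0.027%); nucleus in-plane semi-axes are set with
#' a = b and heights h = 3, 4, 5 um so the volume-equivalent nucleus radii
#' are 3, 4 and 5 um. These dimensions are working assumptions calibrated
#' to the downstream dosimetry and are fully overridable.
#'
#' @param cell_radii Named or plain numeric vector of floating cell radii
#'   (um) for the minimum, average, maximum classes.
#' @param nucleus_radii Volume-equivalent nucleus radii (um), same order.
#' @param heights Nucleus maximum thickness h (um) per class (must be 3, 4,
#'   5 values from \{3,4,5\}).
#' @param apical_margin_um Cytoplasm margin above/below the nucleus in the
#'   attached model (um): the cytoplasm height is fixed at the nucleus
#'   height plus this margin and the in-plane semi-axes are solved to
#'   preserve the floating-cell volume.
#' @param basal_gap_um When set, sinks the nucleus towards the basal
#'   membrane leaving this gap (um); default `NULL` keeps it centred.
#' @return List with `floating` and `attached` sub-lists of geometry
#'   objects keyed by size class, plus a `dimensions` data.frame.
#' @export
default_cell_geometry <- function(cell_radii = c(7, 8.7, 10),
                                  nucleus_radii = c(3, 4, 5),
                                  heights = c(3, 4, 5),
                                  apical_margin_um = 0.5,
                                  basal_gap_um = NULL) {
  sizes <- c("minimum", "average", "maximum")
  stopifnot(length(cell_radii) == 3L, length(nucleus_radii) == 3L,
            length(heights) == 3L)
  floating <- list(); attached <- list(); dims <- list()
  for (i in seq_along(sizes)) {
    rc <- cell_radii[i]; rn <- nucleus_radii[i]; h <- heights[i]
    cc <- h / 2
    ab <- sqrt(rn^3 / cc)  # a = b such that (a b c)^(1/3) = rn
    floating[[sizes[i]]] <- floating_cell_geometry(rc, rn)
    # attached cell: cytoplasm height fixed at nucleus height plus a thin
    # margin, in-plane semi-axes solved to preserve the floating volume
    v_float <- 4 / 3 * pi * rc^3
    c2 <- cc + apical_margin_um
    s <- sqrt(v_float / (4 / 3 * pi * ab * ab * c2)) / 1
    attached[[sizes[i]]] <- build_attached_geometry(
      ab, ab, h, cytoplasm_scale = s,
      floating_volume = v_float, basal_gap_um = basal_gap_um)
    dims[[i]] <- data.frame(size_class = sizes[i], cell_radius_um = rc,
                            nucleus_radius_um = rn, nucleus_a_um = ab,
                            nucleus_b_um = ab, nucleus_h_um = h)
  }
  list(floating = floating, attached = attached,
       dimensions = do.call(rbind, dims))
}

#' Default kinetic parameters of the assay
#'
#' Experimentally derived defaults: instant uptake of 1.87 %AA per
#' 100,000 cells (average of the 1 h and 3 h uptake measurements, shared
#' by both radioligands), membrane-to-internalized ratio 0.76, biological
#' clearance plateauing at 41% with a 2.3 h half-life, 3 h incubation in
#' 1 mL and a 7-day (168 h) colony-growth phase.
#'
#' @return Named list of kinetic defaults.
#' @export
default_kinetics <- function() {
  list(uptake_pct_per_1e5_cells = 1.87,
       membrane_to_internal_ratio = 0.76,
       plateau_fraction = 0.41,
       biological_half_life_h = 2.3,
       incubation_h = 3,
       colony_h = 168,
       volume_ml = 1)
}

#' Physical half-life of a supported nuclide
#'
#' @param nuclide `"Lu-177"` (6.647 d) or `"Ac-225"` (9.92 d).
#' @return Half-life in hours.
#' @export
physical_half_life_h <- function(nuclide) {
  switch(nuclide,
         "Lu-177" = 6.647 * 24,
         "Ac-225" = 9.92 * 24,
         stop_domain("unsupported nuclide: ", nuclide))
}

#' Default activity concentration grids of the clonogenic assay
#'
#' Concentrations in Bq/mL. The highest concentrations (above 0.5 MBq/mL
#' for Lu-177 and above 0.75 kBq/mL for Ac-225) are flagged for exclusion
#' from dose-response fitting.
#'
#' @param nuclide `"Lu-177"` or `"Ac-225"`.
#' @return data.frame with `concentration_bq_per_ml` and `excluded_from_fit`.
#' @export
default_concentration_grid <- function(nuclide) {
  if (nuclide == "Lu-177") {
    conc <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1, 2) * 1e6
    excl <- conc > 0.5e6
  } else if (nuclide == "Ac-225") {
    conc <- c(0, 0.037, 0.1, 0.185, 0.25, 0.37, 0.5, 0.75,
              1.25, 1.85, 3.7) * 1e3
    excl <- conc > 750
  } else stop_domain("unsupported nuclide: ", nuclide)
  data.frame(concentration_bq_per_ml = conc, excluded_from_fit = excl)
}

#' Reference cellular S values (full transport simulation)
#'
#' Nucleus S values for Lu-177 and the Ac-225 chain in the assay geometry,
#' obtained with a full Monte Carlo particle-transport simulation (Geant4)
#' of the same floating / attached set-ups, including the homogeneous
#' medium contribution and the Lu-177 suspension cross dose. Bundled as a
#' validation reference for the built-in engine and as an optional input
#' to the dose pipeline (so dose accumulation can be exercised
#' independently of transport tolerances).
#'
#' @return `data.frame` in the layout of [compute_svalue_table()].
#' @export
reference_svalues <- function() {
  self_rows <- expand.grid(
    size_class = c("minimum", "average", "maximum"),
    nuclide = c("Lu-177", "Ac-225"),
    source = c("cell_membrane", "cytoplasm"),
    setup = c("floating", "attached"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  self_rows$s_value_gy_per_bq_s <- c(
    # floating, cell_membrane: Lu then Ac (min, avg, max)
    2.02e-4, 1.04e-4, 6.40e-5,   1.05e-1, 5.63e-2, 3.56e-2,
    # floating, cytoplasm
    3.67e-4, 1.98e-4, 1.23e-4,   1.78e-1, 1.01e-1, 6.48e-2,
    # attached, cell_membrane
    3.43e-4, 1.65e-4, 7.66e-5,   1.61e-1, 8.31e-2, 4.05e-2,
    # attached, cytoplasm
    2.14e-4, 1.16e-4, 5.89e-5,   1.09e-1, 6.15e-2, 3.23e-2)
  extra <- data.frame(
    size_class = NA_character_,
    nuclide = c("Lu-177", "Ac-225", "Lu-177"),
    source = NA_character_,
    setup = c("medium", "medium", "cross"),
    s_value_gy_per_bq_s = c(2.30e-11, 4.57e-9, 1.13e-6),
    stringsAsFactors = FALSE)
  out <- rbind(self_rows, extra)
  out$mc_rel_err <- NA_real_
  out$n_histories <- NA_integer_
  out$seed <- NA_integer_
  out[, c("nuclide", "setup", "source", "size_class",
          "s_value_gy_per_bq_s", "mc_rel_err", "n_histories", "seed")]
}

#' Reference cumulated 7-day absorbed doses
#'
#' Published cumulated absorbed doses to the nucleus (Gy) over the 7-day
#' clonogenic assay for the study's activity concentrations and the three
#' size classes, obtained with the reference (Geant4-based) dosimetry.
#' Used for soft validation of the dose pipeline and as the canonical dose
#' grid for dose-response simulation.
#'
#' @return `data.frame` with `nuclide`, `concentration_bq_per_ml`,
#'   `average`, `minimum`, `maximum` (Gy).
#' @export
reference_dose_totals <- function() {
  lu <- data.frame(
    nuclide = "Lu-177",
    concentration_bq_per_ml = c(0.1, 0.2, 0.3, 0.4, 0.5) * 1e6,
    average = c(0.74, 1.48, 2.22, 2.96, 3.70),
    minimum = c(1.48, 2.96, 4.43, 5.91, 7.39),
    maximum = c(0.37, 0.74, 1.11, 1.48, 1.85))
  ac <- data.frame(
    nuclide = "Ac-225",
    concentration_bq_per_ml = c(0.037, 0.1, 0.185, 0.25, 0.37,
                                0.5, 0.75) * 1e3,
    average = c(0.08, 0.22, 0.41, 0.56, 0.83, 1.12, 1.67),
    minimum = c(0.16, 0.42, 0.78, 1.05, 1.55, 2.10, 3.15),
    maximum = c(0.04, 0.11, 0.21, 0.29, 0.42, 0.57, 0.86))
  rbind(lu, ac)
}

#' Reference radiosensitivity and RBE of the assay
#'
#' Fitted radiosensitivity slopes (alpha, per Gy) and the derived relative
#' biological effectiveness from the reference analysis of the clonogenic
#' data; used as generating values by the synthetic-data module and as
#' recovery targets in tests.
#'
#' @return Named list: `alpha` (per nuclide), `alpha_se`, `rbe`, `rbe_se`.
#' @export
reference_radiosensitivity <- function() {
  list(alpha = c("Lu-177" = 0.16, "Ac-225" = 0.67),
       alpha_se = c("Lu-177" = 0.01, "Ac-225" = 0.06),
       rbe = 4.2, rbe_se = 0.46)
}
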