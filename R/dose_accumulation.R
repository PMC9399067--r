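# ---------------------------------------------------------------------------
# MIRD-scheme dose accumulation: absorbed dose to the nucleus =
# sum over source compartments and phases of S value x time-integrated
# activity. Incubation uses the floating (spherical) geometry; colony
# growth uses the attached (ellipsoidal) geometry; the switch happens at
# the end of incubation.
# ---------------------------------------------------------------------------

#' Per-phase dose components for one concentration and size class
#'
#' Combines S values with time-integrated activities: the cell-bound
#' activity (instant uptake, physical decay only during incubation,
#' exponential-plus-plateau clearance afterwards) is split between
#' membrane and cytoplasm by the partition model; the medium component
#' applies during incubation only; the cross component applies to Lu-177
#' during incubation only.
#'
#' @param nuclide `"Lu-177"` or `"Ac-225"`.
#' @param concentration_bq_per_ml Added activity concentration (Bq/mL).
#' @param size_class `"minimum"`, `"average"` or `"maximum"`.
#' @param svalues S-value table ([compute_svalue_table()] or
#'   [reference_svalues()]).
#' @param kinetics Kinetic parameter list, see [default_kinetics()].
#' @return Named numeric vector of dose components (Gy):
#'   `incubation_self_membrane`, `incubation_self_cytoplasm`,
#'   `incubation_medium`, `incubation_cross`, `colony_self_membrane`,
#'   `colony_self_cytoplasm`, and `total`.
#' @export
phase_dose <- function(nuclide, concentration_bq_per_ml, size_class,
                       svalues, kinetics = default_kinetics()) {
  check_number(concentration_bq_per_ml, "concentration", lower = 0)
  part <- partition_model(kinetics$membrane_to_internal_ratio)
  t_phys <- physical_half_life_h(nuclide)
  a_cell <- bound_activity_per_cell(concentration_bq_per_ml,
                                    kinetics$volume_ml,
                                    kinetics$uptake_pct_per_1e5_cells)
  # incubation: bound activity constant apart from physical decay
  tia_inc <- time_integrated_activity(a_cell, t_phys, NULL,
                                      kinetics$incubation_h)
  # colony phase: clearance + physical decay from the post-incubation level
  a0_col <- a_cell * 2^(-kinetics$incubation_h / t_phys)
  clr <- clearance_model(kinetics$plateau_fraction,
                         kinetics$biological_half_life_h)
  tia_col <- time_integrated_activity(a0_col, t_phys, clr,
                                      kinetics$colony_h)
  # medium: total added activity, homogeneous, incubation only
  a_medium <- concentration_bq_per_ml * kinetics$volume_ml
  tia_med <- time_integrated_activity(a_medium, t_phys, NULL,
                                      kinetics$incubation_h)

  s_mem_f <- lookup_svalue(svalues, nuclide, "floating", "cell_membrane",
                           size_class)
  s_cyt_f <- lookup_svalue(svalues, nuclide, "floating", "cytoplasm",
                           size_class)
  s_mem_a <- lookup_svalue(svalues, nuclide, "attached", "cell_membrane",
                           size_class)
  s_cyt_a <- lookup_svalue(svalues, nuclide, "attached", "cytoplasm",
                           size_class)
  s_med <- lookup_svalue(svalues, nuclide, "medium")
  s_cross <- if (nuclide == "Lu-177")
    lookup_svalue(svalues, "Lu-177", "cross") else 0

  comp <- c(
    incubation_self_membrane = tia_inc * part$membrane * s_mem_f,
    incubation_self_cytoplasm = tia_inc * part$internal * s_cyt_f,
    incubation_medium = tia_med * s_med,
    incubation_cross = tia_inc * s_cross,
    colony_self_membrane = tia_col * part$membrane * s_mem_a,
    colony_self_cytoplasm = tia_col * part$internal * s_cyt_a)
  c(comp, total = sum(comp))
}

#' Cumulated dose table over concentrations and size classes
#'
#' Builds the cumulated absorbed-dose table of the clonogenic assay: one
#' row per concentration and size class with the per-component and total
#' absorbed dose to the nucleus, plus the exclusion flag for the highest
#' activity concentrations (which are left out of dose-response fits).
#'
#' @param nuclide `"Lu-177"` or `"Ac-225"`.
#' @param concentrations Numeric vector of concentrations (Bq/mL), or a
#'   data.frame from [default_concentration_grid()] (default).
#' @param svalues S-value table (default: bundled reference values).
#' @param kinetics Kinetic parameter list.
#' @param size_classes Size classes to evaluate.
#' @param excluded_above Concentration (Bq/mL) above which rows are
#'   flagged `excluded_from_fit`; default 0.5 MBq/mL for Lu-177 and
#'   0.75 kBq/mL for Ac-225 (ignored when `concentrations` is a
#'   data.frame carrying its own flags).
#' @return `data.frame` with concentration, size class, component doses
#'   (Gy), `total_gy` and `excluded_from_fit`.
#' @export
dose_table <- function(nuclide, concentrations = NULL,
                       svalues = reference_svalues(),
                       kinetics = default_kinetics(),
                       size_classes = c("average", "minimum", "maximum"),
                       excluded_above = NULL) {
  if (is.null(concentrations))
    concentrations <- default_concentration_grid(nuclide)
  if (is.data.frame(concentrations)) {
    conc <- concentrations$concentration_bq_per_ml
    excl <- concentrations$excluded_from_fit
  } else {
    conc <- concentrations
    if (is.null(excluded_above))
      excluded_above <- if (nuclide == "Lu-177") 0.5e6 else 750
    excl <- conc > excluded_above
  }
  if (!length(conc)) {
    out <- data.frame(nuclide = character(),
                      concentration_bq_per_ml = numeric(),
                      size_class = character(), total_gy = numeric(),
                      excluded_from_fit = logical())
    return(out)
  }
  rows <- list()
  for (i in seq_along(conc)) {
    for (sz in size_classes) {
      comp <- phase_dose(nuclide, conc[i], sz, svalues, kinetics)
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nuclide,
        concentration_bq_per_ml = conc[i],
        size_class = sz,
        t(comp[setdiff(names(comp), "total")]),
        total_gy = unname(comp[["total"]]),
        excluded_from_fit = excl[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
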