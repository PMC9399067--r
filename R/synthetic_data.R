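# ---------------------------------------------------------------------------
# Seeded synthetic-data generators. Every generator is deterministic given
# (seed, parameters), records its generating parameters in the returned
# object, and can write a JSON metadata sidecar next to any file output,
# so downstream recovery tests can re-derive the generating values.
# ---------------------------------------------------------------------------

#' Write a synthetic data.frame with a JSON metadata sidecar
#'
#' @param x A generator result (list with `data` and `params`).
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(x, path) {
  stopifnot(is.list(x), is.data.frame(x$data), is.list(x$params))
  utils::write.csv(x$data, path, row.names = FALSE)
  jsonlite::write_json(x$params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate clonogenic colony counts
#'
#' Colony counts per well are drawn as
#' `Poisson(cells_plated x plating_efficiency x exp(-alpha D))` for each
#' dose, replicate and independent experiment; untreated wells (D = 0)
#' are always included.
#'
#' @param doses_gy Positive doses (Gy) of the treated conditions.
#' @param alpha Generating radiosensitivity (1/Gy).
#' @param plating_efficiency Untreated plating efficiency (default 0.5).
#' @param cells_plated Cells seeded per well (default 450).
#' @param n_experiments,n_replicates Independent experiments x replicate
#'   wells (default 3 x 3).
#' @param seed Integer seed.
#' @return List with `data` (`data.frame`: `experiment`, `replicate`,
#'   `dose_gy`, `condition`, `colonies`) and `params`.
#' @export
gen_clonogenic <- function(doses_gy, alpha, plating_efficiency = 0.5,
                           cells_plated = 450, n_experiments = 3,
                           n_replicates = 3, seed = 1L) {
  stopifnot(all(doses_gy >= 0), alpha >= 0)
  doses <- unique(c(0, doses_gy))
  grid <- expand.grid(experiment = seq_len(n_experiments),
                      replicate = seq_len(n_replicates),
                      dose_gy = doses, KEEP.OUT.ATTRS = FALSE)
  mu <- cells_plated * plating_efficiency * exp(-alpha * grid$dose_gy)
  grid$colonies <- with_seed(seed, stats::rpois(nrow(grid), mu))
  grid$condition <- as.character(grid$dose_gy)
  list(data = grid[, c("experiment", "replicate", "dose_gy", "condition",
                       "colonies")],
       params = list(generator = "gen_clonogenic", seed = seed,
                     alpha = alpha, plating_efficiency = plating_efficiency,
                     cells_plated = cells_plated,
                     n_experiments = n_experiments,
                     n_replicates = n_replicates, doses_gy = doses))
}

#' Simulate a cellular excretion (retention) series
#'
#' Retained fractions on the study's time grid from the
#' exponential-plus-plateau clearance model, with multiplicative Gaussian
#' noise, in a two-experiments-by-triplicate structure.
#'
#' @param plateau_fraction,biological_half_life_h Generating clearance
#'   parameters (defaults 0.41 and 2.3 h).
#' @param times_h Measurement times (default `c(0, 4, 24, 48, 120)` h).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.03).
#' @param n_experiments,n_replicates Replication structure (default 2 x 3).
#' @param seed Integer seed.
#' @return List with `data` (`time_h`, `retained_fraction`, `experiment`,
#'   `replicate`) and `params`.
#' @export
gen_excretion <- function(plateau_fraction = 0.41,
                          biological_half_life_h = 2.3,
                          times_h = c(0, 4, 24, 48, 120),
                          cv = 0.03, n_experiments = 2, n_replicates = 3,
                          seed = 1L) {
  model <- clearance_model(plateau_fraction, biological_half_life_h)
  grid <- expand.grid(experiment = seq_len(n_experiments),
                      replicate = seq_len(n_replicates),
                      time_h = times_h, KEEP.OUT.ATTRS = FALSE)
  r <- retained_fraction(model, grid$time_h)
  grid$retained_fraction <- with_seed(seed, {
    pmin(pmax(r * (1 + stats::rnorm(nrow(grid), 0, cv)), 0), 1.1)
  })
  list(data = grid[, c("time_h", "retained_fraction", "experiment",
                       "replicate")],
       params = list(generator = "gen_excretion", seed = seed,
                     plateau_fraction = plateau_fraction,
                     biological_half_life_h = biological_half_life_h,
                     times_h = times_h, cv = cv,
                     n_experiments = n_experiments,
                     n_replicates = n_replicates))
}

#' Simulate a competitive displacement curve
#'
#' One-site competition sigmoid sampled over a log-spaced competitor
#' concentration grid with multiplicative Gaussian noise.
#'
#' @param ic50_m Generating IC50 in mol/L (default 1.53e-8).
#' @param hill Hill slope (default 1).
#' @param concentrations_m Competitor grid (default 8 points over
#'   1e-13..1e-6 M).
#' @param bottom Nonspecific (fully displaced) level (default 0.02).
#' @param cv Noise CV (default 0.05).
#' @param n_experiments,n_replicates Replication (default 3 x 3).
#' @param seed Integer seed.
#' @return List with `data` (`concentration_m`, `bound`, `experiment`,
#'   `replicate`) and `params`.
#' @export
gen_displacement <- function(ic50_m = 1.53e-8, hill = 1,
                             concentrations_m = 10^seq(-13, -6,
                                                       length.out = 8),
                             bottom = 0.02, cv = 0.05,
                             n_experiments = 3, n_replicates = 3,
                             seed = 1L) {
  stopifnot(ic50_m > 0, hill > 0)
  grid <- expand.grid(experiment = seq_len(n_experiments),
                      replicate = seq_len(n_replicates),
                      concentration_m = concentrations_m,
                      KEEP.OUT.ATTRS = FALSE)
  b <- bottom + (1 - bottom) / (1 + (grid$concentration_m / ic50_m)^hill)
  grid$bound <- with_seed(seed, {
    pmax(b * (1 + stats::rnorm(nrow(grid), 0, cv)), 0)
  })
  list(data = grid[, c("concentration_m", "bound", "experiment",
                       "replicate")],
       params = list(generator = "gen_displacement", seed = seed,
                     ic50_m = ic50_m, hill = hill, bottom = bottom,
                     cv = cv, concentrations_m = concentrations_m,
                     n_experiments = n_experiments,
                     n_replicates = n_replicates))
}

#' Simulate gamma-counter uptake measurements
#'
#' Lysate and standard counts consistent with a given uptake
#' (%AA/100,000 cells), counting-standard fraction and cell number, with
#' multiplicative Gaussian counting noise on the lysate.
#'
#' @param uptake_pct_per_1e5_cells Generating uptake (default 1.87).
#' @param cell_count Cells per well (default 750,000).
#' @param standard_fraction_of_added Fraction of added activity counted as
#'   standard (default 100/1500).
#' @param added_counts Expected counts of the full added activity
#'   (default 1.5e6).
#' @param cv Noise CV (default 0.03).
#' @param n_experiments,n_replicates Replication (default 3 x 3).
#' @param seed Integer seed.
#' @return List with `data` (`lysate_counts`, `standard_counts`,
#'   `standard_fraction_of_added`, `cell_count`, `experiment`,
#'   `replicate`) and `params`.
#' @export
gen_uptake <- function(uptake_pct_per_1e5_cells = 1.87,
                       cell_count = 750000,
                       standard_fraction_of_added = 100 / 1500,
                       added_counts = 1.5e6, cv = 0.03,
                       n_experiments = 3, n_replicates = 3, seed = 1L) {
  grid <- expand.grid(experiment = seq_len(n_experiments),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu_lysate <- added_counts * (uptake_pct_per_1e5_cells / 100) *
    (cell_count / 1e5)
  grid$lysate_counts <- with_seed(seed, {
    pmax(mu_lysate * (1 + stats::rnorm(nrow(grid), 0, cv)), 0)
  })
  grid$standard_counts <- added_counts * standard_fraction_of_added
  grid$standard_fraction_of_added <- standard_fraction_of_added
  grid$cell_count <- cell_count
  list(data = grid,
       params = list(generator = "gen_uptake", seed = seed,
                     uptake_pct_per_1e5_cells = uptake_pct_per_1e5_cells,
                     cell_count = cell_count,
                     standard_fraction_of_added = standard_fraction_of_added,
                     added_counts = added_counts, cv = cv))
}
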