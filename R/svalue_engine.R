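# ---------------------------------------------------------------------------
# S-value engine: absorbed dose rate to the nucleus per unit activity
# (Gy per Bq s) for self-dose (membrane / cytoplasm sources), the
# radioactive medium, and cross-dose from neighbouring cells.
#
# All chain members are simulated at equilibrium and co-located with the
# parent; photons are excluded (their probability of interacting in a
# micrometre-scale nucleus is negligible).
# ---------------------------------------------------------------------------

# charged emissions of a chain, weighted per parent decay
.charged_emission_table <- function(chain) {
  w <- branch_weights(chain)
  rows <- list()
  for (s in chain$steps) {
    em <- s$emissions
    keep <- em$class %in% c("alpha", "beta_mean",
                            "conversion_auger_electron")
    if (any(keep)) {
      e <- em[keep, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        particle = ifelse(e$class == "alpha", "alpha", "electron"),
        mev = e$mev,
        q_mev = e$q_mev,
        ey = e$yield * w[[s$name]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(particle = character(), mev = numeric(),
                      q_mev = numeric(), ey = numeric()))
  do.call(rbind, rows)
}

# Sample emission energies: monoenergetic unless a beta endpoint is given,
# in which case energies are drawn from an allowed-shape continuous
# spectrum approximated by a scaled Beta(1, b) distribution whose mean
# matches the evaluated mean beta energy and whose support is [0, Q].
# The flat-at-zero density mirrors the Coulomb-enhanced low-energy part of
# beta-minus spectra.
.sample_emission_energy <- function(n, mev, q_mev) {
  if (!is.finite(q_mev)) return(rep(mev, n))
  a <- 1.0
  b <- a * (q_mev / mev - 1)
  q_mev * stats::rbeta(n, a, b)
}

#' S value of the radioactive medium
#'
#' Analytic dose rate to the nucleus per unit activity homogeneously
#' distributed over the incubation medium: all charged-particle energy
#' (alpha, mean beta, conversion/Auger) is absorbed locally in the medium
#' mass, photons escape. Valid because charged-particle ranges (< 1 mm)
#' are small against the medium dimensions, so the nucleus sees the
#' medium's equilibrium dose.
#'
#' @param chain A `decay_chain`.
#' @param medium_mass_g Medium mass in grams (default 1 g for 1 mL of
#'   water-equivalent medium).
#' @return S value in Gy/(Bq s).
#' @examples
#' medium_svalue(load_chain("Lu-177"))  # ~2.4e-11
#' @export
medium_svalue <- function(chain, medium_mass_g = 1) {
  check_number(medium_mass_g, "medium_mass_g", lower = 0, allow_zero = FALSE)
  e <- charged_energy_per_decay(
    chain, c("alpha", "beta_mean", "conversion_auger_electron"))
  e * MEV_TO_J / (medium_mass_g * 1e-3)
}

# --- position samplers ------------------------------------------------------

.sample_shell_radii <- function(n, r_in, r_out) {
  (r_in^3 + stats::runif(n) * (r_out^3 - r_in^3))^(1 / 3)
}

.isotropic_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

.sample_ball <- function(n, radius) {
  d <- .isotropic_directions(n)
  d * (radius * stats::runif(n)^(1 / 3))
}

.sample_ellipsoid_interior <- function(n, abc) {
  .sample_ball(n, 1) %*% diag(abc)
}

# uniform-area sampling on an ellipsoid surface (rejection on the
# surface-element weight)
.sample_ellipsoid_surface <- function(n, abc) {
  out <- matrix(0, 0, 3)
  wmax <- max(abc[2] * abc[3], abc[1] * abc[3], abc[1] * abc[2])
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 1.8)
    u <- .isotropic_directions(m)
    w <- sqrt((u[, 1] * abc[2] * abc[3])^2 +
              (u[, 2] * abc[1] * abc[3])^2 +
              (u[, 3] * abc[1] * abc[2])^2)
    acc <- stats::runif(m) < w / wmax
    out <- rbind(out, u[acc, , drop = FALSE] %*% diag(abc))
  }
  out[seq_len(n), , drop = FALSE]
}

.sample_positions <- function(geometry, source, n) {
  if (inherits(geometry, "floating_cell_geometry")) {
    rc <- geometry$cell_radius
    rn <- geometry$nucleus_radius
    r <- switch(source,
      cell_membrane = .sample_shell_radii(n, rc, rc + geometry$membrane_thickness),
      cytoplasm = .sample_shell_radii(n, rn, rc),
      stop_domain("source must be cell_membrane or cytoplasm"))
    return(list(kind = "sphere", r = r))
  }
  if (inherits(geometry, "attached_cell_geometry")) {
    abc_n <- c(geometry$a, geometry$b, geometry$c)
    abc_c <- c(geometry$a_cyt, geometry$b_cyt, geometry$c_cyt)
    if (source == "cell_membrane") {
      p <- .sample_ellipsoid_surface(n, abc_c)
    } else if (source == "cytoplasm") {
      z0 <- geometry$nucleus_offset %||% 0
      p <- matrix(0, 0, 3)
      while (nrow(p) < n) {
        m <- ceiling((n - nrow(p)) * 1.3)
        cand <- .sample_ellipsoid_interior(m, abc_c)
        inside_nuc <- (cand[, 1] / abc_n[1])^2 + (cand[, 2] / abc_n[2])^2 +
          ((cand[, 3] - z0) / abc_n[3])^2 < 1
        p <- rbind(p, cand[!inside_nuc, , drop = FALSE])
      }
      p <- p[seq_len(n), , drop = FALSE]
    } else stop_domain("source must be cell_membrane or cytoplasm")
    return(list(kind = "ellipsoid", p = p))
  }
  stop_domain("unknown geometry class")
}

# entry distance and chord of a ray (origin at radius r, direction cosine
# mu towards the polar axis) through a concentric sphere of radius rn
.sphere_chord <- function(r, mu, rn) {
  disc <- r^2 * mu^2 - r^2 + rn^2
  hit <- disc > 0 & mu < 0
  sq <- sqrt(pmax(disc, 0))
  s_entry <- ifelse(hit, -r * mu - sq, 0)
  chord <- ifelse(hit, 2 * sq, 0)
  list(s_entry = s_entry, chord = chord)
}

# entry distance and chord of rays P + t D through an ellipsoid with
# semi-axes abc (P outside the ellipsoid, |D| = 1)
.ellipsoid_chord <- function(p, d, abc) {
  a2 <- abc^2
  qa <- d[, 1]^2 / a2[1] + d[, 2]^2 / a2[2] + d[, 3]^2 / a2[3]
  qb <- 2 * (p[, 1] * d[, 1] / a2[1] + p[, 2] * d[, 2] / a2[2] +
             p[, 3] * d[, 3] / a2[3])
  qc <- p[, 1]^2 / a2[1] + p[, 2]^2 / a2[2] + p[, 3]^2 / a2[3] - 1
  disc <- qb^2 - 4 * qa * qc
  hit <- disc > 0
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-qb - sq) / (2 * qa)
  t2 <- (-qb + sq) / (2 * qa)
  hit <- hit & t2 > 0
  s_entry <- ifelse(hit, pmax(t1, 0), 0)
  chord <- ifelse(hit, t2 - pmax(t1, 0), 0)
  list(s_entry = s_entry, chord = chord)
}

#' Monte Carlo self-dose S value (membrane or cytoplasm source)
#'
#' Estimates the absorbed dose rate to the nucleus per unit parent
#' activity at chain equilibrium. Emission points are sampled uniformly in
#' the source compartment with isotropic directions; alpha particles
#' deposit energy along the chord intersecting the nucleus by
#' continuous-slowing-down integration of the embedded water
#' stopping-power parameterization, and electrons (mean beta plus
#' conversion/Auger) via the analytic Cole range-energy relation along
#' straight tracks.
#'
#' @param geometry A `floating_cell_geometry` or `attached_cell_geometry`.
#' @param source `"cell_membrane"` or `"cytoplasm"`.
#' @param chain A `decay_chain`.
#' @param n_histories Number of primary decays to simulate (default 1e5
#'   when the chain emits alphas, 1e6 otherwise; must be >= 1e4).
#' @param seed Integer seed (mandatory for reproducible runs).
#' @return Object of class `svalue`: list with `value` (Gy/(Bq s)),
#'   `mc_rel_err`, `absorbed_fraction`, `nuclide`, `source`,
#'   `geometry_label`, `n_histories`, `seed`, `converged` (relative
#'   standard error <= 0.5%; a warning is raised otherwise).
#' @export
self_svalue <- function(geometry, source = c("cell_membrane", "cytoplasm"),
                        chain, n_histories = NULL, seed = 1L) {
  source <- match.arg(source)
  em <- .charged_emission_table(chain)
  if (is.null(n_histories))
    n_histories <- if (any(em$particle == "alpha")) 1e5 else 1e6
  if (n_histories < 1e4) stop_domain("n_histories must be >= 1e4")
  n_histories <- as.integer(n_histories)
  label <- if (inherits(geometry, "floating_cell_geometry"))
    "floating" else "attached"
  m_kg <- nucleus_volume(geometry) * UM3_TO_KG
  abc_n <- if (label == "attached")
    c(geometry$a, geometry$b, geometry$c) else NULL

  s1 <- 0; s2 <- 0
  with_seed(seed, {
    left <- n_histories
    while (left > 0L) {
      m <- min(left, 250000L)
      pos <- .sample_positions(geometry, source, m)
      e_hist <- numeric(m)
      for (k in seq_len(nrow(em))) {
        if (pos$kind == "sphere") {
          mu <- stats::runif(m, -1, 1)
          ch <- .sphere_chord(pos$r, mu, geometry$nucleus_radius)
        } else {
          d <- .isotropic_directions(m)
          pn <- pos$p
          pn[, 3] <- pn[, 3] - (geometry$nucleus_offset %||% 0)
          ch <- .ellipsoid_chord(pn, d, abc_n)
        }
        en <- .sample_emission_energy(m, em$mev[k], em$q_mev[k])
        de <- chord_energy_deposit(en, ch$s_entry, ch$chord,
                                   em$particle[k])
        e_hist <- e_hist + em$ey[k] * de
      }
      s1 <- s1 + sum(e_hist)
      s2 <- s2 + sum(e_hist^2)
      left <- left - m
    }
  })
  mean_e <- s1 / n_histories
  var_e <- max(s2 / n_histories - mean_e^2, 0)
  rel_err <- if (mean_e > 0)
    sqrt(var_e / n_histories) / mean_e else NA_real_
  total_e <- sum(em$mev * em$ey)
  res <- structure(list(
    value = mean_e * MEV_TO_J / m_kg,
    mc_rel_err = rel_err,
    absorbed_fraction = if (total_e > 0) mean_e / total_e else 0,
    nuclide = chain$parent,
    source = source,
    geometry_label = label,
    n_histories = n_histories,
    seed = seed,
    converged = is.finite(rel_err) && rel_err <= 0.005
  ), class = "svalue")
  if (!isTRUE(res$converged))
    warning("S value did not reach 0.5% relative MC error (",
            signif(rel_err, 2), "); increase n_histories")
  res
}

#' @export
print.svalue <- function(x, ...) {
  cat(sprintf("<svalue> %s %s (%s): %.4g Gy/(Bq s), rel err %.2g%%\n",
              x$nuclide, x$source, x$geometry_label, x$value,
              100 * x$mc_rel_err))
  invisible(x)
}

#' Cross-dose lattice configuration
#'
#' Geometry of the suspension cross-dose estimate: identical spherical
#' cells placed at random in a cubic volume at a given occupancy
#' (cell-volume fraction).
#'
#' @param box_side Cube side in micrometres (default 500).
#' @param cell_radius Cell radius in micrometres (default 8).
#' @param nucleus_radius Nucleus radius in micrometres (default 4).
#' @param occupancy Cell volume fraction (default 2.7e-4, i.e. 0.027%).
#' @return A list of class `cross_dose_config`.
#' @export
cross_dose_config <- function(box_side = 500, cell_radius = 8,
                              nucleus_radius = 4, occupancy = 2.7e-4) {
  check_number(box_side, "box_side", lower = 0, allow_zero = FALSE)
  check_number(cell_radius, "cell_radius", lower = 0, allow_zero = FALSE)
  check_number(nucleus_radius, "nucleus_radius", lower = 0,
               allow_zero = FALSE)
  check_number(occupancy, "occupancy", lower = 0, upper = 0.1)
  if (nucleus_radius >= cell_radius)
    stop_domain("nucleus_radius must be below cell_radius")
  structure(list(box_side = box_side, cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius, occupancy = occupancy),
            class = "cross_dose_config")
}

#' Monte Carlo cross-dose S value from neighbouring cells
#'
#' Mean dose rate to a central cell's nucleus when every other cell in the
#' box carries 1 Bq of the nuclide (per-cell unit activity summed over all
#' neighbours; self-dose excluded), averaged over random cell placements.
#' Emission points are sampled uniformly over each neighbour's whole cell
#' volume (the cross dose is insensitive to membrane vs cytoplasm
#' localization at these distances). Directions are importance-sampled in
#' the cone subtending the central nucleus.
#'
#' @param config A [cross_dose_config()].
#' @param chain A `decay_chain`.
#' @param n_realizations Number of random placements to average (default 50).
#' @param seed Integer seed.
#' @param cone_samples Emission samples per neighbour per realization.
#' @return Object of class `cross_svalue_result`: `value` (Gy/(Bq s)),
#'   `se`, `n_cells`, `config`, `seed`.
#' @export
cross_svalue <- function(config, chain, n_realizations = 50, seed = 1L,
                         cone_samples = 2000) {
  stopifnot(inherits(config, "cross_dose_config"))
  v_cell <- 4 / 3 * pi * config$cell_radius^3
  v_box <- config$box_side^3
  n_cells <- round(config$occupancy * v_box / v_cell)
  m_kg <- 4 / 3 * pi * config$nucleus_radius^3 * UM3_TO_KG
  em <- .charged_emission_table(chain)
  out <- structure(list(value = 0, se = 0, n_cells = n_cells,
                        config = config, seed = seed,
                        normalization = "per-cell unit activity summed over neighbours"),
                   class = "cross_svalue_result")
  k_nb <- n_cells - 1L
  if (k_nb < 1L || nrow(em) == 0L) return(out)
  rn <- config$nucleus_radius
  half <- config$box_side / 2
  vals <- numeric(n_realizations)
  with_seed(seed, {
    for (rz in seq_len(n_realizations)) {
      centers <- matrix(0, 0, 3)
      while (nrow(centers) < k_nb) {
        m <- 2L * (k_nb - nrow(centers))
        cand <- matrix(stats::runif(3 * m, -half, half), ncol = 3)
        keep <- rowSums(cand^2) > (2 * config$cell_radius)^2
        centers <- rbind(centers, cand[keep, , drop = FALSE])
      }
      centers <- centers[seq_len(k_nb), , drop = FALSE]
      nK <- k_nb * cone_samples
      q <- centers[rep(seq_len(k_nb), each = cone_samples), , drop = FALSE] +
        .sample_ball(nK, config$cell_radius)
      dq <- sqrt(rowSums(q^2))
      cosmax <- sqrt(pmax(1 - (rn / dq)^2, 0))
      cost <- 1 - stats::runif(nK) * (1 - cosmax)
      sint <- sqrt(pmax(1 - cost^2, 0))
      phi <- stats::runif(nK, 0, 2 * pi)
      ax <- -q / dq
      h <- cbind(0, 0, rep(1, nK))
      swap <- abs(ax[, 3]) > 0.9
      h[swap, ] <- matrix(rep(c(1, 0, 0), sum(swap)), ncol = 3, byrow = TRUE)
      e1 <- cbind(ax[, 2] * h[, 3] - ax[, 3] * h[, 2],
                  ax[, 3] * h[, 1] - ax[, 1] * h[, 3],
                  ax[, 1] * h[, 2] - ax[, 2] * h[, 1])
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(ax[, 2] * e1[, 3] - ax[, 3] * e1[, 2],
                  ax[, 3] * e1[, 1] - ax[, 1] * e1[, 3],
                  ax[, 1] * e1[, 2] - ax[, 2] * e1[, 1])
      d <- ax * cost + (e1 * cos(phi) + e2 * sin(phi)) * sint
      b <- rowSums(q * d)
      disc <- b^2 - (dq^2 - rn^2)
      sq <- sqrt(pmax(disc, 0))
      s_entry <- pmax(-b - sq, 0)
      chord <- 2 * sq
      p_hit <- (1 - cosmax) / 2
      e_dep <- numeric(nK)
      for (k in seq_len(nrow(em))) {
        en <- .sample_emission_energy(nK, em$mev[k], em$q_mev[k])
        e_dep <- e_dep + em$ey[k] *
          chord_energy_deposit(en, s_entry, chord, em$particle[k])
      }
      vals[rz] <- sum(p_hit * e_dep) / cone_samples * MEV_TO_J / m_kg
    }
  })
  out$value <- mean(vals)
  out$se <- stats::sd(vals) / sqrt(n_realizations)
  out
}

#' Compute a full S-value table with the transport engine
#'
#' Runs [self_svalue()] over every combination of nuclide, set-up
#' (floating / attached), source compartment and size class in a geometry
#' configuration, and appends medium and (optionally) cross-dose rows,
#' mirroring the layout of a cellular S-value table.
#'
#' @param nuclides Character vector of parent nuclides.
#' @param geometry Geometry configuration as returned by
#'   [default_cell_geometry()].
#' @param n_histories Named list or single number of histories per run
#'   (default: engine defaults per nuclide).
#' @param seed Integer base seed; each run derives its own sub-seed.
#' @param include_medium,include_cross Append medium / cross rows.
#' @param cross_config A [cross_dose_config()] for the cross row
#'   (Lu-177 only; alpha-chain cross dose is negligible and reported as
#'   computed).
#' @param cross_realizations Placements for the cross-dose estimate.
#' @return `data.frame` with columns `nuclide`, `setup`, `source`,
#'   `size_class`, `s_value_gy_per_bq_s`, `mc_rel_err`, `n_histories`,
#'   `seed`.
#' @export
compute_svalue_table <- function(nuclides = c("Lu-177", "Ac-225"),
                                 geometry = default_cell_geometry(),
                                 n_histories = NULL,
                                 seed = 1L,
                                 include_medium = TRUE,
                                 include_cross = TRUE,
                                 cross_config = cross_dose_config(),
                                 cross_realizations = 50) {
  rows <- list()
  run <- 0L
  for (nuc in nuclides) {
    chain <- load_chain(nuc)
    nh <- if (is.list(n_histories)) n_histories[[nuc]] else n_histories
    for (setup in c("floating", "attached")) {
      for (size in c("minimum", "average", "maximum")) {
        geom <- geometry[[setup]][[size]]
        for (src in c("cell_membrane", "cytoplasm")) {
          run <- run + 1L
          sv <- self_svalue(geom, src, chain, n_histories = nh,
                            seed = seed + run)
          rows[[length(rows) + 1L]] <- data.frame(
            nuclide = nuc, setup = setup, source = src, size_class = size,
            s_value_gy_per_bq_s = sv$value, mc_rel_err = sv$mc_rel_err,
            n_histories = sv$n_histories, seed = sv$seed,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (include_medium) {
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nuc, setup = "medium", source = NA_character_,
        size_class = NA_character_,
        s_value_gy_per_bq_s = medium_svalue(chain),
        mc_rel_err = 0, n_histories = NA_integer_, seed = NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (include_cross && nuc == "Lu-177") {
      run <- run + 1L
      cs <- cross_svalue(cross_config, chain,
                         n_realizations = cross_realizations,
                         seed = seed + run)
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nuc, setup = "cross", source = NA_character_,
        size_class = NA_character_,
        s_value_gy_per_bq_s = cs$value,
        mc_rel_err = if (cs$value > 0) cs$se / cs$value else 0,
        n_histories = NA_integer_, seed = seed + run,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Look up one S value in a table
#'
#' @param table S-value `data.frame` from [compute_svalue_table()] or
#'   [reference_svalues()].
#' @param nuclide,setup Nuclide and set-up (`"floating"`, `"attached"`,
#'   `"medium"`, `"cross"`).
#' @param source,size_class Source compartment and size class (ignored for
#'   medium / cross rows).
#' @return The S value in Gy/(Bq s); errors when absent.
#' @export
lookup_svalue <- function(table, nuclide, setup, source = NA,
                          size_class = NA) {
  sel <- table$nuclide == nuclide & table$setup == setup
  if (!setup %in% c("medium", "cross")) {
    sel <- sel & table$source == source & table$size_class == size_class
  }
  v <- table$s_value_gy_per_bq_s[sel & !is.na(sel)]
  if (length(v) != 1L)
    stop_domain("no unique S value for ", nuclide, "/", setup, "/",
                source, "/", size_class)
  v
}
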