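# ---------------------------------------------------------------------------
# Embedded nuclear data
#
# Half-lives, mean emission energies and yields are versioned constants taken
# from a standard evaluated compilation (ICRP-107-like values). Beta spectra
# are represented by their mean energy; conversion and Auger electrons are
# lumped into a single mean energy per decay; photon lines are kept for
# bookkeeping only (photons are never transported to the nucleus).
# ---------------------------------------------------------------------------

# q_mev: beta endpoint energy (NA for non-beta emissions), used by the
# transport engine to sample the continuous spectrum; bookkeeping (medium
# S value, energy sums) always uses the mean energy `mev`.
.emissions <- function(class, mev, yield, q_mev = NA_real_) {
  stopifnot(length(class) == length(mev), length(mev) == length(yield))
  if (any(mev <= 0) || any(yield <= 0))
    stop_domain("emission energies and yields must be positive")
  bad <- setdiff(class, emission_classes())
  if (length(bad))
    stop_domain("unknown particle class: ", paste(bad, collapse = ", "))
  q_mev <- rep_len(q_mev, length(class))
  if (any(is.finite(q_mev) & q_mev <= mev))
    stop_domain("beta endpoint must exceed the mean energy")
  data.frame(class = class, mev = mev, yield = yield, q_mev = q_mev,
             stringsAsFactors = FALSE)
}

.step <- function(name, half_life_s, emissions, daughters) {
  list(name = name, half_life_s = half_life_s,
       emissions = emissions, daughters = daughters)
}

.no_emissions <- data.frame(class = character(), mev = numeric(),
                            yield = numeric(), q_mev = numeric(),
                            stringsAsFactors = FALSE)

#' Closed set of particle classes used in the emission tables
#'
#' @return Character vector of the four supported particle classes.
#' @export
emission_classes <- function() {
  c("alpha", "beta_mean", "conversion_auger_electron", "photon")
}

.build_chain <- function(parent) {
  day <- 86400
  if (parent == "Lu-177") {
    steps <- list(
      .step("Lu-177", 6.647 * day,
            .emissions(c("beta_mean", "conversion_auger_electron",
                         "conversion_auger_electron", "photon", "photon"),
                       c(0.13330, 0.11000, 0.00100, 0.20836, 0.11295),
                       c(1.0, 0.110, 1.6, 0.1041, 0.0617),
                       c(0.4981, NA, NA, NA, NA)),
            list(list(name = "Hf-177", fraction = 1.0))),
      .step("Hf-177", Inf, .no_emissions, list())
    )
  } else if (parent == "Ac-225") {
    steps <- list(
      .step("Ac-225", 9.92 * day,
            .emissions(c("alpha", "conversion_auger_electron", "photon"),
                       c(5.7900, 0.0180, 0.0120),
                       c(1.0, 1.0, 1.0)),
            list(list(name = "Fr-221", fraction = 1.0))),
      .step("Fr-221", 4.80 * 60,
            .emissions(c("alpha", "conversion_auger_electron", "photon"),
                       c(6.3010, 0.0100, 0.21810),
                       c(1.0, 1.0, 0.114)),
            list(list(name = "At-217", fraction = 1.0))),
      .step("At-217", 0.0323,
            .emissions("alpha", 7.0669, 1.0),
            list(list(name = "Bi-213", fraction = 1.0))),
      .step("Bi-213", 45.61 * 60,
            .emissions(c("beta_mean", "alpha",
                         "conversion_auger_electron", "photon"),
                       c(0.4350, 5.8700, 0.0100, 0.4402),
                       c(0.978, 0.022, 1.0, 0.259),
                       c(1.4230, NA, NA, NA)),
            list(list(name = "Po-213", fraction = 0.978),
                 list(name = "Tl-209", fraction = 0.022))),
      .step("Po-213", 4.2e-6,
            .emissions("alpha", 8.3760, 1.0),
            list(list(name = "Pb-209", fraction = 1.0))),
      .step("Tl-209", 2.162 * 60,
            .emissions(c("beta_mean", "photon"),
                       c(0.6590, 2.3300),
                       c(1.0, 1.0),
                       c(1.8330, NA)),
            list(list(name = "Pb-209", fraction = 1.0))),
      .step("Pb-209", 3.234 * 3600,
            .emissions("beta_mean", 0.1980, 1.0, 0.6440),
            list(list(name = "Bi-209", fraction = 1.0))),
      .step("Bi-209", Inf, .no_emissions, list())
    )
  } else {
    stop_domain("unsupported nuclide: '", parent,
                "' (supported parents: Lu-177, Ac-225)")
  }
  chain <- structure(list(parent = parent, steps = steps),
                     class = "decay_chain")
  validate_chain(chain)
  chain
}

#' Load an embedded decay chain
#'
#' Returns the full decay chain for a supported parent radionuclide,
#' including per-step emission tables (mean energies in MeV, yields per
#' decay) and branching fractions. The actinium-225 chain runs
#' Ac-225 -> Fr-221 -> At-217 -> Bi-213 -> (97.8% Po-213 | 2.2% Tl-209)
#' -> Pb-209 -> Bi-209 (stable) and carries exactly four alpha-emitting
#' transitions when weighted over branches; lutetium-177 decays directly
#' to stable Hf-177.
#'
#' @param parent Parent nuclide identifier, one of `"Lu-177"`, `"Ac-225"`.
#' @return An object of class `decay_chain`: a list with elements `parent`
#'   and `steps` (ordered parent-first).
#' @examples
#' ch <- load_chain("Ac-225")
#' alpha_emissions_per_decay(ch)  # 4
#' @export
load_chain <- function(parent) {
  if (!is.character(parent) || length(parent) != 1L)
    stop_domain("parent must be a single nuclide identifier string")
  .build_chain(parent)
}

#' @export
print.decay_chain <- function(x, ...) {
  cat("<decay_chain>", x$parent, "with", length(x$steps), "steps\n")
  for (s in x$steps) {
    hl <- if (is.finite(s$half_life_s)) sprintf("%.4g s", s$half_life_s)
          else "stable"
    cat(sprintf("  %-7s %-10s %d emissions\n", s$name, hl,
                nrow(s$emissions)))
  }
  invisible(x)
}

#' Validate decay-chain invariants
#'
#' Checks that every daughter reference resolves within the chain, that
#' branching fractions sum to one, that radioactive steps have positive
#' half-lives, and that a stable terminus has no emissions or daughters.
#'
#' @param chain A `decay_chain`.
#' @return The chain, invisibly; errors on violation.
#' @export
validate_chain <- function(chain) {
  stopifnot(inherits(chain, "decay_chain"))
  names_all <- vapply(chain$steps, `[[`, "", "name")
  for (s in chain$steps) {
    if (is.finite(s$half_life_s) && s$half_life_s <= 0)
      stop_domain(s$name, ": half-life must be positive")
    if (length(s$daughters)) {
      dn <- vapply(s$daughters, `[[`, "", "name")
      fr <- vapply(s$daughters, `[[`, 0, "fraction")
      if (!all(dn %in% names_all))
        stop_domain(s$name, ": daughter does not resolve within chain")
      if (abs(sum(fr) - 1) > 1e-9)
        stop_domain(s$name, ": branching fractions must sum to 1")
    } else {
      if (nrow(s$emissions) > 0)
        stop_domain(s$name, ": stable terminus must have no emissions")
    }
  }
  invisible(chain)
}

.decay_constants <- function(chain) {
  hl <- vapply(chain$steps, `[[`, 0, "half_life_s")
  ifelse(is.finite(hl), log(2) / hl, 0)
}

.step_names <- function(chain) vapply(chain$steps, `[[`, "", "name")

#' Branching weight of each chain member per parent decay
#'
#' The branching-weighted number of decays of each chain member per decay
#' of the parent, assuming the chain in equilibrium (product of branching
#' fractions along the path from the parent).
#'
#' @param chain A `decay_chain`.
#' @return Named numeric vector over chain members.
#' @export
branch_weights <- function(chain) {
  nm <- .step_names(chain)
  w <- stats::setNames(numeric(length(nm)), nm)
  w[chain$parent] <- 1
  for (s in chain$steps) {
    for (d in s$daughters) w[d$name] <- w[d$name] + w[s$name] * d$fraction
  }
  w
}

# Enumerate all linear paths from the parent, with cumulative branching.
.chain_paths <- function(chain) {
  nm <- .step_names(chain)
  idx <- stats::setNames(seq_along(nm), nm)
  res <- list()
  walk <- function(path, branch) {
    res[[length(res) + 1L]] <<- list(idx = path, branch = branch)
    s <- chain$steps[[path[length(path)]]]
    for (d in s$daughters) walk(c(path, idx[[d$name]]), branch * d$fraction)
  }
  walk(1L, 1)
  res
}

# Closed-form Bateman atom counts for one linear path with distinct decay
# constants (a zero constant for the stable terminus is allowed).
.bateman_path_atoms <- function(lambda, branch, n0, t) {
  n <- length(lambda)
  if (n == 1L) return(n0 * exp(-lambda[1L] * t))
  # nudge near-degenerate pairs apart to keep the formula well-conditioned
  lam <- lambda
  for (i in seq_len(n - 1L)) {
    close <- which(abs(lam - lam[i]) < 1e-12 * max(lam[i], 1e-30))
    close <- close[close > i]
    if (length(close)) lam[close] <- lam[close] * (1 + 1e-9)
  }
  pref <- n0 * branch * prod(lam[seq_len(n - 1L)])
  acc <- 0
  for (j in seq_len(n)) {
    denom <- prod(lam[-j] - lam[j])
    acc <- acc + exp(-lam[j] * t) / denom
  }
  pref * acc
}

.bateman <- function(chain, t, parent_activity_0, what = c("activity", "atoms")) {
  what <- match.arg(what)
  if (any(t < 0)) stop_domain("t must be non-negative")
  check_number(parent_activity_0, "parent_activity_0", lower = 0)
  lambda <- .decay_constants(chain)
  if (lambda[1L] == 0) stop_domain("parent must be radioactive")
  n0 <- parent_activity_0 / lambda[1L]
  nm <- .step_names(chain)
  out <- matrix(0, nrow = length(t), ncol = length(nm),
                dimnames = list(NULL, nm))
  for (p in .chain_paths(chain)) {
    iend <- p$idx[length(p$idx)]
    atoms <- .bateman_path_atoms(lambda[p$idx], p$branch, n0, t)
    if (length(p$idx) > 1L) atoms[t == 0] <- 0  # exact initial condition
    out[, iend] <- out[, iend] +
      if (what == "atoms") atoms else lambda[iend] * atoms
  }
  # guard against tiny round-off from the alternating coefficient sums
  out[abs(out) < 1e-12 * max(abs(out))] <- 0
  out[out < 0 & out > -1e-9 * max(abs(out))] <- 0
  if (length(t) == 1L) out[1L, ] else out
}

#' Bateman activities of all chain members
#'
#' Closed-form Bateman solution (with branching) for the activity of every
#' chain member at time `t`, starting from a pure parent source.
#'
#' @param chain A `decay_chain`.
#' @param t Time(s) since a pure parent source, in seconds (>= 0).
#' @param parent_activity_0 Parent activity at `t = 0`, in Bq.
#' @return Named numeric vector of activities (Bq) for scalar `t`, or a
#'   matrix (time x nuclide) for vector `t`.
#' @examples
#' ch <- load_chain("Ac-225")
#' a <- bateman_activities(ch, 30 * 60, 1000)
#' a[["Fr-221"]] / a[["Ac-225"]]  # ~0.987
#' @export
bateman_activities <- function(chain, t, parent_activity_0) {
  .bateman(chain, t, parent_activity_0, "activity")
}

#' Bateman atom counts of all chain members
#'
#' Companion atom-count solution to [bateman_activities()]; summing over
#' all members (including the stable terminus) conserves the initial
#' number of parent atoms.
#'
#' @inheritParams bateman_activities
#' @return Named numeric vector (or time x nuclide matrix) of atom counts.
#' @export
bateman_atoms <- function(chain, t, parent_activity_0) {
  .bateman(chain, t, parent_activity_0, "atoms")
}

#' Charged-particle (or photon) energy released per parent decay
#'
#' Branching-weighted sum over all chain steps of yield x mean energy for
#' the requested particle classes, assuming the chain in equilibrium, so
#' the result is MeV per parent decay.
#'
#' @param chain A `decay_chain`.
#' @param classes Character vector of particle classes
#'   (see [emission_classes()]).
#' @return Energy in MeV per parent decay.
#' @examples
#' charged_energy_per_decay(load_chain("Ac-225"), "alpha")  # ~27.5 MeV
#' @export
charged_energy_per_decay <- function(chain, classes) {
  if (!length(classes)) stop_domain("classes must be non-empty")
  bad <- setdiff(classes, emission_classes())
  if (length(bad))
    stop_domain("unknown particle class: ", paste(bad, collapse = ", "))
  w <- branch_weights(chain)
  total <- 0
  for (s in chain$steps) {
    em <- s$emissions
    keep <- em$class %in% classes
    if (any(keep))
      total <- total + w[[s$name]] * sum(em$mev[keep] * em$yield[keep])
  }
  total
}

#' Alpha emissions per parent decay
#'
#' @param chain A `decay_chain`.
#' @return Branching-weighted number of alpha particles emitted per parent
#'   decay (4 for the Ac-225 cascade, 0 for Lu-177).
#' @export
alpha_emissions_per_decay <- function(chain) {
  w <- branch_weights(chain)
  total <- 0
  for (s in chain$steps) {
    em <- s$emissions
    keep <- em$class == "alpha"
    if (any(keep)) total <- total + w[[s$name]] * sum(em$yield[keep])
  }
  total
}

#' Time for the first daughter to reach a given fraction of equilibrium
#'
#' For a parent -> daughter pair the activity ratio grows as
#' `1 - exp(-(lambda_d - lambda_p) t)` towards its transient-equilibrium
#' limit; this returns the time at which the ratio reaches `fraction` of
#' that limit. For Ac-225/Fr-221 the 98% time is about 27 minutes, which
#' motivates a 30-minute ingrowth wait before gamma counting.
#'
#' @param chain A `decay_chain` with at least one radioactive daughter.
#' @param fraction Fraction of the equilibrium activity ratio (default 0.98).
#' @return Time in seconds.
#' @export
daughter_equilibration_time <- function(chain, fraction = 0.98) {
  check_number(fraction, "fraction", lower = 0, upper = 1, allow_zero = FALSE)
  lambda <- .decay_constants(chain)
  if (length(lambda) < 2L || lambda[2L] == 0)
    stop_domain("chain has no radioactive daughter")
  -log(1 - fraction) / (lambda[2L] - lambda[1L])
}

# ---------------------------------------------------------------------------
# JSON serialization of chains
# ---------------------------------------------------------------------------

#' Serialize a decay chain to JSON
#'
#' Dialect: `{steps:[{name, half_life_s, emissions:[{class, mev, yield}],
#' daughters:[[name, fraction]]}]}`. Stable steps carry `half_life_s: null`.
#'
#' @param chain A `decay_chain`.
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
chain_to_json <- function(chain, path = NULL) {
  steps <- lapply(chain$steps, function(s) {
    list(
      name = s$name,
      half_life_s = if (is.finite(s$half_life_s)) s$half_life_s else NULL,
      emissions = lapply(seq_len(nrow(s$emissions)), function(i) {
        e <- s$emissions[i, ]
        out <- list(class = e$class, mev = e$mev, yield = e$yield)
        if (is.finite(e$q_mev)) out$q_mev <- e$q_mev
        out
      }),
      daughters = lapply(s$daughters, function(d)
        list(d$name, d$fraction))
    )
  })
  js <- jsonlite::toJSON(list(parent = chain$parent, steps = steps),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a decay chain from JSON
#'
#' @param json JSON string or path to a JSON file in the dialect written by
#'   [chain_to_json()].
#' @return A `decay_chain`.
#' @export
chain_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  steps <- lapply(x$steps, function(s) {
    em <- if (length(s$emissions)) {
      data.frame(
        class = vapply(s$emissions, `[[`, "", "class"),
        mev = vapply(s$emissions, `[[`, 0, "mev"),
        yield = vapply(s$emissions, `[[`, 0, "yield"),
        q_mev = vapply(s$emissions, function(e)
          e$q_mev %||% NA_real_, 0),
        stringsAsFactors = FALSE)
    } else .no_emissions
    .step(s$name,
          if (is.null(s$half_life_s)) Inf else s$half_life_s,
          em,
          lapply(s$daughters, function(d)
            list(name = d[[1L]], fraction = d[[2L]])))
  })
  chain <- structure(list(parent = x$parent, steps = steps),
                     class = "decay_chain")
  validate_chain(chain)
  chain
}
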