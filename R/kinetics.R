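# ---------------------------------------------------------------------------
# Cellular activity kinetics: instant-uptake bound activity, membrane /
# internal partition, biological clearance fitting, and time-integrated
# activity (cumulated activity) per experimental phase.
# ---------------------------------------------------------------------------

#' Bound activity per cell after instant uptake
#'
#' Converts an added activity concentration and a measured uptake (percent
#' of added activity per 100,000 cells) into the bound activity of a
#' single cell. The total bound activity scales with the cell number, so
#' the per-cell value is independent of it:
#' `A_cell = concentration x volume x (uptake/100) / 1e5`.
#'
#' @param concentration_bq_per_ml Added activity concentration (Bq/mL).
#' @param volume_ml Incubation volume (mL).
#' @param uptake_pct_per_1e5_cells Uptake in %AA per 100,000 cells.
#' @param n_cells Number of cells in the tube (> 0; used for validation).
#' @return Bound activity per cell in Bq.
#' @examples
#' bound_activity_per_cell(0.4e6, 1, 1.87, 1e5)  # 0.0748 Bq/cell
#' @export
bound_activity_per_cell <- function(concentration_bq_per_ml, volume_ml,
                                    uptake_pct_per_1e5_cells,
                                    n_cells = 1e5) {
  check_number(concentration_bq_per_ml, "concentration", lower = 0)
  check_number(volume_ml, "volume_ml", lower = 0)
  check_number(uptake_pct_per_1e5_cells, "uptake", lower = 0)
  if (!is.finite(n_cells) || n_cells <= 0)
    stop_domain("n_cells must be positive")
  concentration_bq_per_ml * volume_ml *
    (uptake_pct_per_1e5_cells / 100) / 1e5
}

#' Membrane / internalized partition model
#'
#' Constant ratio between the membrane-bound and the internalized fraction
#' of cell-bound radioligand.
#'
#' @param membrane_to_internal_ratio Ratio of membrane-bound to
#'   internalized activity (default 0.76).
#' @return List of class `partition_model` with `membrane` and `internal`
#'   fractions (which sum to 1 exactly) and the `ratio`.
#' @export
partition_model <- function(membrane_to_internal_ratio = 0.76) {
  check_number(membrane_to_internal_ratio, "ratio", lower = 0)
  r <- membrane_to_internal_ratio
  structure(list(membrane = r / (1 + r), internal = 1 / (1 + r),
                 ratio = r),
            class = "partition_model")
}

#' Exponential-plus-plateau cellular clearance model
#'
#' Whole-cell retention after the end of incubation:
#' `r(t) = p + (1 - p) exp(-ln 2 t / T_bio)`, with `r(0) = 1`, a fast
#' component clearing with biological half-life `T_bio` and a retained
#' plateau fraction `p`.
#'
#' @param plateau_fraction Plateau fraction `p` in `[0, 1]`.
#' @param biological_half_life_h Biological half-life of the fast
#'   component, hours (> 0).
#' @return List of class `clearance_model`.
#' @export
clearance_model <- function(plateau_fraction, biological_half_life_h) {
  check_number(plateau_fraction, "plateau_fraction", lower = 0, upper = 1)
  check_number(biological_half_life_h, "biological_half_life_h", lower = 0,
               allow_zero = FALSE)
  structure(list(plateau_fraction = plateau_fraction,
                 biological_half_life_h = biological_half_life_h),
            class = "clearance_model")
}

#' Retained fraction predicted by a clearance model
#'
#' @param model A `clearance_model`.
#' @param t_h Time after end of incubation, hours (vectorized).
#' @return Retained fraction of the initial bound activity.
#' @export
retained_fraction <- function(model, t_h) {
  stopifnot(inherits(model, "clearance_model"))
  p <- model$plateau_fraction
  p + (1 - p) * exp(-log(2) * t_h / model$biological_half_life_h)
}

#' Fit the exponential-plus-plateau clearance model to excretion data
#'
#' Least-squares fit of `r(t) = p + (1 - p) exp(-ln 2 t / T)` to measured
#' retained fractions (all replicates pooled).
#'
#' @param times_h Time points in hours (>= 4 points including t = 0).
#' @param retained Retained fractions in `[0, 1.1]`, same length.
#' @return A `clearance_model` with additional fields `plateau_se`,
#'   `half_life_se`, `r_squared`, `flagged` (TRUE for degenerate data with
#'   no measurable clearance, in which case the half-life is `NA`).
#' @examples
#' t <- c(0, 4, 24, 48, 120)
#' r <- 0.41 + 0.59 * exp(-log(2) * t / 2.3)
#' fit_clearance(rep(t, 3), rep(r, 3))
#' @export
fit_clearance <- function(times_h, retained) {
  if (length(times_h) != length(retained))
    stop_domain("times_h and retained must have equal length")
  if (length(unique(times_h)) < 4L || !any(times_h == 0))
    stop_domain("need >= 4 time points including t = 0")
  if (any(retained < 0) || any(retained > 1.1))
    stop_domain("retained fractions must lie in [0, 1.1]")
  flat <- diff(range(retained)) < 1e-6
  if (flat) {
    m <- clearance_model(min(mean(retained), 1), 1)
    m$biological_half_life_h <- NA_real_
    m$plateau_se <- NA_real_
    m$half_life_se <- NA_real_
    m$r_squared <- NA_real_
    m$flagged <- TRUE
    return(m)
  }
  df <- data.frame(time_h = times_h, ret = retained)
  p0 <- max(min(mean(retained[times_h == max(times_h)]), 0.95), 0.01)
  t0 <- max(stats::median(times_h[times_h > 0]) / 4, 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ret ~ p + (1 - p) * exp(-log(2) * time_h / tb),
      data = df, start = list(p = p0, tb = t0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_domain("clearance fit failed to converge: ",
                  conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["p"]] < 0 || cf[["p"]] > 1 || cf[["tb"]] <= 0)
    stop_domain("clearance fit converged outside the physical domain ",
                "(p = ", signif(cf[["p"]], 3), ", T = ",
                signif(cf[["tb"]], 3), " h)")
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((retained - mean(retained))^2)
  m <- clearance_model(unname(cf[["p"]]), unname(cf[["tb"]]))
  m$plateau_se <- unname(se[1])
  m$half_life_se <- unname(se[2])
  m$r_squared <- r2
  m$flagged <- (1 - cf[["p"]]) < 0.02 ||
    (is.finite(se[2]) && se[2] > 10 * cf[["tb"]])
  m
}

#' Time-integrated activity (cumulated activity)
#'
#' Closed-form integral of `A0 exp(-lambda_p t) r(t)` from 0 to
#' `duration_h`, where `r(t)` is the biological retention (identically 1
#' when `clearance` is `NULL`). Both decay routes commute, so with
#' `lambda = lambda_p + lambda_b` the fast component integrates to
#' `(1 - p)(1 - exp(-lambda T))/lambda` and the plateau to
#' `p (1 - exp(-lambda_p T))/lambda_p`.
#'
#' @param a0_bq Activity at the start of the phase (Bq).
#' @param physical_half_life_h Physical half-life in hours (may be `Inf`).
#' @param clearance A `clearance_model`, or `NULL` for no biological
#'   clearance.
#' @param duration_h Phase duration in hours (>= 0).
#' @return Time-integrated activity in Bq s.
#' @export
time_integrated_activity <- function(a0_bq, physical_half_life_h,
                                     clearance = NULL, duration_h) {
  check_number(a0_bq, "a0_bq", lower = 0)
  check_number(duration_h, "duration_h", lower = 0)
  if (!(is.numeric(physical_half_life_h) && length(physical_half_life_h) == 1L &&
        (is.finite(physical_half_life_h) || is.infinite(physical_half_life_h))) ||
      physical_half_life_h <= 0)
    stop_domain("physical_half_life_h must be positive (possibly Inf)")
  lam_p <- if (is.finite(physical_half_life_h))
    log(2) / physical_half_life_h else 0
  term <- function(rate, T) if (rate > 0) (1 - exp(-rate * T)) / rate else T
  if (is.null(clearance)) {
    tia_h <- a0_bq * term(lam_p, duration_h)
  } else {
    stopifnot(inherits(clearance, "clearance_model"))
    p <- clearance$plateau_fraction
    lam_b <- log(2) / clearance$biological_half_life_h
    tia_h <- a0_bq * ((1 - p) * term(lam_p + lam_b, duration_h) +
                      p * term(lam_p, duration_h))
  }
  tia_h * HOUR_S
}
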