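# ---------------------------------------------------------------------------
# Binding assays: uptake quantification (%AA per 100,000 cells) and
# one-site competitive displacement IC50 fitting.
# ---------------------------------------------------------------------------

#' Uptake as percent of added activity per 100,000 cells
#'
#' Converts gamma-counter lysate counts into %AA/100,000 cells using a
#' counted standard that represents a known fraction of the added
#' activity: `%AA = 100 * lysate / (standard / standard_fraction) *
#' (1e5 / cell_count)`.
#'
#' @param lysate_counts Counts in the cell lysate.
#' @param standard_counts Counts in the standard aliquot (> 0).
#' @param standard_fraction_of_added Fraction of the added activity the
#'   standard represents (e.g. 100 uL of 1.5 mL = 1/15).
#' @param cell_count Number of cells in the well.
#' @return Uptake in %AA per 100,000 cells (vectorized over
#'   `lysate_counts`).
#' @export
uptake_percent <- function(lysate_counts, standard_counts,
                           standard_fraction_of_added, cell_count) {
  if (any(lysate_counts < 0)) stop_domain("counts must be non-negative")
  check_number(standard_counts, "standard_counts", lower = 0,
               allow_zero = FALSE)
  check_number(standard_fraction_of_added, "standard_fraction_of_added",
               lower = 0, upper = 1, allow_zero = FALSE)
  check_number(cell_count, "cell_count", lower = 0, allow_zero = FALSE)
  added <- standard_counts / standard_fraction_of_added
  100 * (lysate_counts / added) * (1e5 / cell_count)
}

#' Fit a one-site competitive displacement curve (IC50)
#'
#' Least-squares fit of the one-site competition sigmoid
#' `bound(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill)` on
#' log10-transformed concentrations. The bound signal is normalized so
#' that the mean signal at the lowest competitor concentration defines
#' 100%, which makes the fit invariant to multiplicative rescaling of the
#' raw signal. A flat curve (dynamic range below `min_span`) or an IC50
#' outside the tested concentration span is returned flagged, with no
#' usable IC50.
#'
#' @param concentration_m Competitor concentrations in mol/L (>= 6 values
#'   spanning >= 4 decades).
#' @param bound Bound signal (raw or normalized), same length.
#' @param fix_hill Fix the Hill slope at 1 instead of fitting it.
#' @param min_span Minimum relative displacement required to attempt a fit
#'   (default 0.2).
#' @return Object of class `ic50_fit`: `ic50_m`, `ci95_m` (length-2),
#'   `hill`, `r_squared`, `flagged`, `normalized` data.
#' @examples
#' cc <- 10^seq(-13, -6, length.out = 8)
#' b <- 1 / (1 + cc / 1.53e-8)
#' fit_ic50(cc, b)$ic50_m
#' @export
fit_ic50 <- function(concentration_m, bound, fix_hill = FALSE,
                     min_span = 0.2) {
  if (length(concentration_m) != length(bound))
    stop_domain("concentration_m and bound must have equal length")
  if (any(concentration_m <= 0))
    stop_domain("concentrations must be positive")
  uc <- sort(unique(concentration_m))
  if (length(uc) < 6L || log10(max(uc) / min(uc)) < 4)
    stop_domain("need >= 6 concentrations spanning >= 4 decades")
  norm <- mean(bound[concentration_m == min(uc)])
  if (norm <= 0) stop_domain("signal at lowest concentration must be > 0")
  y <- bound / norm
  df <- data.frame(lx = log10(concentration_m), y = y)
  flagged_out <- function(reason) {
    structure(list(ic50_m = NA_real_, ci95_m = c(NA_real_, NA_real_),
                   hill = NA_real_, r_squared = NA_real_,
                   flagged = TRUE, reason = reason,
                   data = df), class = "ic50_fit")
  }
  span <- (max(y) - min(y)) / max(y)
  if (span < min_span) return(flagged_out("flat curve: no displacement"))
  li0 <- df$lx[which.min(abs(y - (max(y) + min(y)) / 2))]
  fit <- tryCatch({
    if (fix_hill) {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(lx - li)),
        data = df, start = list(top = 1, bottom = min(y), li = li0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(h * (lx - li))),
        data = df,
        start = list(top = 1, bottom = min(y), li = li0, h = 1),
        lower = c(-Inf, -Inf, -16, 0.2), upper = c(Inf, Inf, 0, 5),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(flagged_out("fit did not converge"))
  cf <- stats::coef(fit)
  li <- cf[["li"]]
  se_li <- tryCatch(sqrt(diag(stats::vcov(fit)))[["li"]],
                    error = function(e) NA_real_)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  ic50 <- 10^li
  out_of_range <- ic50 < min(uc) || ic50 > max(uc)
  structure(list(
    ic50_m = ic50,
    ci95_m = if (is.finite(se_li))
      10^(li + c(-1.96, 1.96) * se_li) else c(NA_real_, NA_real_),
    hill = if (fix_hill) 1 else cf[["h"]],
    r_squared = r2,
    flagged = out_of_range,
    reason = if (out_of_range) "IC50 outside tested range" else NA_character_,
    data = df), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$flagged) {
    cat("<ic50_fit> flagged:", x$reason, "\n")
  } else {
    cat(sprintf("<ic50_fit> IC50 = %.3g M (95%% CI %.3g-%.3g), hill %.2f, R^2 %.4f\n",
                x$ic50_m, x$ci95_m[1], x$ci95_m[2], x$hill, x$r_squared))
  }
  invisible(x)
}
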