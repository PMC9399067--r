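# ---------------------------------------------------------------------------
# Clonogenic dose response: survival fractions with Poisson counting
# errors, weighted log-linear fitting of the radiosensitivity slope alpha,
# and RBE with first-order error propagation.
# ---------------------------------------------------------------------------

#' Survival fractions from colony counts
#'
#' Normalizes mean colony counts per condition to the untreated control:
#' `SF = mean(treated) / mean(untreated)`, with the standard deviation
#' from Poisson counting statistics propagated through the ratio,
#' `sd = SF sqrt(1/mean(treated) + 1/mean(untreated))`. Conditions with
#' zero colonies get `SF = 0`, `sd = NA` and a one-sided 95% upper bound
#' (`3 / n_wells` expected colonies).
#'
#' @param colonies Integer vector of per-well colony counts.
#' @param condition Vector identifying the condition of each well.
#' @param untreated Value of `condition` labelling the untreated control.
#' @return `data.frame` with one row per treated condition: `condition`,
#'   `mean_colonies`, `n_wells`, `survival_fraction`, `sd`, `sf_upper95`.
#' @examples
#' survival_fractions(c(110, 112, 108, 220, 221, 219),
#'                    c("d1", "d1", "d1", "0", "0", "0"), untreated = "0")
#' @export
survival_fractions <- function(colonies, condition, untreated = "0") {
  if (length(colonies) != length(condition))
    stop_domain("colonies and condition must have equal length")
  if (any(colonies < 0)) stop_domain("colony counts must be non-negative")
  cond <- as.character(condition)
  if (!any(cond == untreated))
    stop_domain("no untreated control wells found")
  mu_u <- mean(colonies[cond == untreated])
  if (mu_u <= 0) stop_domain("untreated mean colony count is zero; ",
                             "cannot normalize")
  treated <- setdiff(unique(cond), untreated)
  rows <- lapply(treated, function(lab) {
    x <- colonies[cond == lab]
    mu <- mean(x)
    sf <- mu / mu_u
    if (mu > 0) {
      sdv <- sf * sqrt(1 / mu + 1 / mu_u)
      up <- NA_real_
    } else {
      sdv <- NA_real_
      up <- (3 / length(x)) / mu_u  # 95% upper bound for a zero Poisson sum
    }
    data.frame(condition = lab, mean_colonies = mu, n_wells = length(x),
               survival_fraction = sf, sd = sdv, sf_upper95 = up,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the log-linear radiosensitivity slope alpha
#'
#' Weighted least squares of `ln(SF) = -alpha D` through the origin
#' (SF(0) = 1 by normalization), with weights equal to the inverse
#' variance of `ln(SF)` derived from the Poisson standard deviations
#' (`var(ln SF) = (sd/SF)^2`). Points with `SF = 0` cannot be
#' log-transformed and are dropped with a warning; points flagged
#' `excluded` are dropped when `exclude_flagged` is `TRUE`. An optional
#' quadratic term (`- beta D^2`) can be added but is off by default, since
#' the assay is described by the pure log-linear model.
#'
#' @param points `data.frame` with columns `dose` (Gy),
#'   `survival_fraction`, optional `sd` and logical `excluded`.
#' @param exclude_flagged Drop points with `excluded = TRUE` (default).
#' @param include_beta Also fit a quadratic (linear-quadratic) term.
#' @return Object of class `dose_response_fit`: `alpha` (1/Gy),
#'   `alpha_se`, `r_squared` (on the ln scale), `n_points`, `beta`/
#'   `beta_se` when requested, and the fitted `points`.
#' @export
fit_alpha <- function(points, exclude_flagged = TRUE,
                      include_beta = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("dose", "survival_fraction") %in% names(points)))
  pts <- points
  if (exclude_flagged && "excluded" %in% names(pts))
    pts <- pts[!pts$excluded %in% TRUE, , drop = FALSE]
  pts <- pts[pts$dose > 0, , drop = FALSE]
  zero <- pts$survival_fraction <= 0
  if (any(zero)) {
    warning(sum(zero), " point(s) with SF = 0 dropped from the ln fit")
    pts <- pts[!zero, , drop = FALSE]
  }
  if (nrow(pts) < 3L)
    stop_domain("need >= 3 usable points with dose > 0")
  y <- log(pts$survival_fraction)
  known_var <- "sd" %in% names(pts) && any(is.finite(pts$sd)) &&
    any(pts$sd[is.finite(pts$sd)] > 0)
  if (!known_var) {
    w <- rep(1, nrow(pts))
  } else {
    v <- (pts$sd / pts$survival_fraction)^2
    v[!is.finite(v) | v <= 0] <- min(v[is.finite(v) & v > 0])
    w <- 1 / v
  }
  if (include_beta) {
    fit <- stats::lm(y ~ 0 + dose + I(dose^2), data = pts, weights = w)
    cf <- stats::coef(fit)
    x <- cbind(pts$dose, pts$dose^2)
    se <- if (known_var) {
      # the Poisson variances are known, not estimated: GLS covariance
      sqrt(diag(solve(crossprod(x * sqrt(w)))))
    } else sqrt(diag(stats::vcov(fit)))
    alpha <- -cf[[1]]; alpha_se <- se[[1]]
    beta <- -cf[[2]]; beta_se <- se[[2]]
  } else {
    fit <- stats::lm(y ~ 0 + dose, data = pts, weights = w)
    alpha <- -stats::coef(fit)[[1]]
    alpha_se <- if (known_var) {
      1 / sqrt(sum(w * pts$dose^2))
    } else sqrt(diag(stats::vcov(fit)))[[1]]
    beta <- NULL; beta_se <- NULL
  }
  res <- stats::residuals(fit)
  r2 <- 1 - sum(w * res^2) / sum(w * y^2)
  structure(list(alpha = alpha, alpha_se = alpha_se,
                 beta = beta, beta_se = beta_se,
                 r_squared = r2, n_points = nrow(pts),
                 points = pts),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> alpha = %.4g +/- %.2g 1/Gy (R^2 = %.4f, n = %d)\n",
              x$alpha, x$alpha_se, x$r_squared, x$n_points))
  if (!is.null(x$beta))
    cat(sprintf("  beta = %.4g +/- %.2g 1/Gy^2\n", x$beta, x$beta_se))
  invisible(x)
}

#' Plot a clonogenic dose-response fit
#'
#' Survival fractions on a log scale against absorbed dose, with the
#' fitted exponential.
#'
#' @param x A `dose_response_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dose_response_fit <- function(x, ...) {
  p <- x$points
  graphics::plot(p$dose, p$survival_fraction, log = "y",
                 xlab = "Absorbed dose to nucleus (Gy)",
                 ylab = "Survival fraction", ...)
  d <- seq(0, max(p$dose), length.out = 100)
  graphics::lines(d, exp(-x$alpha * d))
  invisible(x)
}

#' Relative biological effectiveness from two dose-response fits
#'
#' `RBE = alpha_test / alpha_reference`, with first-order (delta-method)
#' propagation of the two standard errors:
#' `se = RBE sqrt((se_t/alpha_t)^2 + (se_r/alpha_r)^2)`.
#'
#' @param fit_test,fit_reference `dose_response_fit` objects (or lists
#'   with `alpha` and `alpha_se`), test (high-LET) and reference
#'   radiation respectively.
#' @return Object of class `rbe_result`: `rbe`, `rbe_se`, and the two
#'   alpha estimates.
#' @examples
#' rbe(list(alpha = 0.67, alpha_se = 0.06),
#'     list(alpha = 0.16, alpha_se = 0.01))
#' @export
rbe <- function(fit_test, fit_reference) {
  at <- fit_test$alpha; st <- fit_test$alpha_se
  ar <- fit_reference$alpha; sr <- fit_reference$alpha_se
  if (is.null(at) || is.null(ar)) stop_domain("fits must carry alpha")
  if (ar <= 0) stop_domain("reference alpha must be positive")
  r <- at / ar
  se <- r * sqrt((st / at)^2 + (sr / ar)^2)
  structure(list(rbe = r, rbe_se = se, alpha_test = at,
                 alpha_reference = ar),
            class = "rbe_result")
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("<rbe_result> RBE = %.3g +/- %.2g (alpha %.3g vs %.3g 1/Gy)\n",
              x$rbe, x$rbe_se, x$alpha_test, x$alpha_reference))
  invisible(x)
}
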