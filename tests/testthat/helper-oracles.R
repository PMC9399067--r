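# Independent numerical oracles used across tests.

# Stiff ODE integration of a decay chain (independent of the closed-form
# Bateman implementation).
ode_chain_activities <- function(chain, times, parent_activity_0,
                                 rtol = 1e-12) {
  nm <- vapply(chain$steps, `[[`, "", "name")
  hl <- vapply(chain$steps, `[[`, 0, "half_life_s")
  lam <- ifelse(is.finite(hl), log(2) / hl, 0)
  n <- length(nm)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, i] <- -lam[i]
    for (d in chain$steps[[i]]$daughters) {
      j <- which(nm == d$name)
      m[j, i] <- m[j, i] + d$fraction * lam[i]
    }
  }
  n0 <- c(parent_activity_0 / lam[1], rep(0, n - 1))
  sol <- deSolve::ode(n0, c(0, times), function(t, y, p) list(m %*% y),
                      NULL, method = "lsoda", rtol = rtol, atol = 1e-25)
  act <- sol[-1, -1, drop = FALSE] * rep(lam, each = length(times))
  colnames(act) <- nm
  act
}

# Adaptive-quadrature time-integrated activity (Bq s), independent of the
# closed form.
quadrature_tia <- function(a0, t_phys_h, clearance, duration_h) {
  lam_p <- if (is.finite(t_phys_h)) log(2) / t_phys_h else 0
  f <- function(t) {
    r <- if (is.null(clearance)) 1 else retained_fraction(clearance, t)
    a0 * exp(-lam_p * t) * r
  }
  3600 * stats::integrate(f, 0, duration_h, rel.tol = 1e-12,
                          abs.tol = 0)$value
}

# Greedy nearest-centre matching of detections to ground truth.
match_detections <- function(det_xy, truth_xy, max_dist) {
  used <- rep(FALSE, nrow(truth_xy))
  match <- rep(NA_integer_, nrow(det_xy))
  for (i in seq_len(nrow(det_xy))) {
    d2 <- (truth_xy[, 1] - det_xy[i, 1])^2 + (truth_xy[, 2] - det_xy[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) {
      match[i] <- j
      used[j] <- TRUE
    }
  }
  match
}
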