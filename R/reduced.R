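# Operations specific to the three-stimulus / two-weight reduction:
# equilibrium sweeps in the conservation constant C, the isola of
# additional equilibria, Hopf thresholds from the 3x3 Jacobian, and the
# period-doubling of the stable cycle. Stimuli are (1,0), (cos a, sin a),
# (cos b, sin b) with equal probabilities.

# equilibrium conditions in (v1, v2) only: theta is eliminated by
# theta = mean(v^2), v3 by the linear constraint
.reduced_F2 <- function(alpha, beta, C) {
  e <- three_stimulus_constraint(alpha, beta)
  g12 <- cos(alpha); g13 <- cos(beta); g23 <- cos(alpha - beta)
  G12 <- matrix(c(1, g12, g12, 1, g13, g23), 2, 3)
  function(u) {
    v3 <- (C - e[1] * u[1] - e[2] * u[2]) / e[3]
    v <- c(u[1], u[2], v3)
    th <- mean(v^2)
    as.vector(G12 %*% (v * (v - th) / 3))
  }
}

#' Equilibria of the reduced three-stimulus system
#'
#' Multi-start Newton search for the equilibria at a given value of the
#' conservation constant C. The search is performed in (v1, v2) with theta
#' eliminated through its equilibrium value; optional warm starts (e.g. the
#' roots found at a neighboring C) make continuation-style sweeps cheap and
#' robust near folds, where basins of attraction shrink.
#'
#' @inheritParams reduce_three_stimuli
#' @param n_starts random starts for the Newton search.
#' @param box bounding box for starts, as `c(lo, hi)` applied to both
#'   response coordinates.
#' @param warm optional matrix of (v1, v2) warm starts.
#' @param seed RNG seed for the start grid.
#' @param tol_dedup root-separation tolerance. Coarser than the generic
#'   default because near C = 0 the degenerate origin spawns a cluster of
#'   numerically converged pseudo-roots that must collapse to one, while
#'   genuine roots stay far better separated than 1e-4 away from folds.
#' @return Matrix with one equilibrium `(v1, v2, theta)` per row.
#' @export
reduced_equilibria <- function(alpha, beta, C, n_starts = 200L,
                               box = c(-4, 6), warm = NULL, seed = 1L,
                               tol_dedup = 1e-4) {
  F2 <- .reduced_F2(alpha, beta, C)
  roots <- find_equilibria(F2, rep(box[1], 2), rep(box[2], 2),
                           n_starts = n_starts, seed = seed, warm = warm,
                           tol_dedup = tol_dedup)
  if (nrow(roots) == 0L) return(matrix(numeric(0), 0, 3))
  e <- three_stimulus_constraint(alpha, beta)
  th <- apply(roots, 1, function(u) {
    v3 <- (C - e[1] * u[1] - e[2] * u[2]) / e[3]
    mean(c(u, v3)^2)
  })
  out <- cbind(roots, th)
  colnames(out) <- c("v1", "v2", "theta")
  out
}

#' Fold boundaries of the isola of additional equilibria
#'
#' Sweeps the conservation constant over `scan`, counting equilibria with
#' warm-started multi-start root finding, then bisects each 1 <-> 3
#' transition of the count to locate the two folds bounding the isola.
#'
#' @inheritParams reduced_equilibria
#' @param scan C values for the coarse scan; must bracket the isola.
#' @param tol bisection tolerance on C.
#' @param seed RNG seed for the multi-start grids.
#' @return Named vector `c(lower, upper)`.
#' @export
isola_bounds <- function(alpha, beta, scan = seq(-0.5, 4.5, by = 0.25),
                         tol = 1e-3, n_starts = 200L, seed = 1L) {
  # coarse scan (warm-started) until the extra equilibria are seen
  warm <- NULL
  counts <- integer(length(scan))
  roots_at <- vector("list", length(scan))
  for (i in seq_along(scan)) {
    r <- reduced_equilibria(alpha, beta, scan[i], n_starts = n_starts,
                            warm = warm, seed = seed)
    counts[i] <- nrow(r)
    roots_at[[i]] <- r
    warm <- .isola_warm(r)
  }
  if (!any(counts >= 3L))
    stop("no isola found in the scan range (equilibrium count never ",
         "changes 1 <-> 3)")
  # anchor in the interior, then walk each way with warm continuation:
  # the bracket never relies on a cold multi-start having found the
  # nearly merged pair near a fold
  i0 <- which(counts >= 3L)[ceiling(sum(counts >= 3L) / 2)]
  step <- if (length(scan) > 1) min(diff(scan)) else 0.25
  walk <- function(dir) {
    C_in <- scan[i0]
    warm <- .isola_warm(roots_at[[i0]])
    repeat {
      C_try <- C_in + dir * step
      r <- reduced_equilibria(alpha, beta, C_try, n_starts = n_starts,
                              warm = warm, seed = seed)
      if (nrow(r) >= 3L) {
        C_in <- C_try
        warm <- .isola_warm(r)
      } else {
        lo_in <- C_in; hi_out <- C_try
        break
      }
      if (abs(C_in - scan[i0]) > 100 * step)
        stop("isola boundary not found while walking the count")
    }
    # bisect between the last inside and first outside point; inside
    # evaluations refresh the warm pair
    while (abs(hi_out - lo_in) > tol) {
      mid <- (lo_in + hi_out) / 2
      r <- reduced_equilibria(alpha, beta, mid, n_starts = n_starts,
                              warm = warm, seed = seed)
      if (nrow(r) >= 3L) {
        lo_in <- mid
        warm <- .isola_warm(r)
      } else hi_out <- mid
    }
    (lo_in + hi_out) / 2
  }
  c(lower = walk(-1), upper = walk(+1))
}

# warm starts from roots, thickened with a deterministic cloud of
# perturbations at several scales and directions, so that nearly merged
# root pairs near a fold are still found regardless of the random grid
.isola_warm <- function(r) {
  if (is.null(r) || nrow(r) == 0L) return(NULL)
  u <- r[, 1:2, drop = FALSE]
  dirs <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  out <- u
  for (s in c(0.02, 0.08, 0.2))
    for (k in seq_len(nrow(dirs)))
      out <- rbind(out, u + matrix(s * dirs[k, ], nrow(u), 2, byrow = TRUE))
  out
}

# characteristic coefficients of the reduced 3x3 Jacobian are affine in
# s = 1/tau (only the theta row scales); solve the Routh-Hurwitz residual
# quadratic in s for Hopf candidates
.hopf_taus_affine <- function(jac_of_s) {
  coefs <- function(s) {
    J <- jac_of_s(s)
    c(A0 = -det(J),
      A1 = det(J[1:2, 1:2]) + det(J[c(1, 3), c(1, 3)]) +
        det(J[2:3, 2:3]),
      A2 = -sum(diag(J)))
  }
  c1 <- coefs(1); c2 <- coefs(2)
  sl <- c2 - c1
  ic <- c1 - sl
  qa <- sl[["A1"]] * sl[["A2"]]
  qb <- sl[["A1"]] * ic[["A2"]] + ic[["A1"]] * sl[["A2"]] - sl[["A0"]]
  qc <- ic[["A1"]] * ic[["A2"]] - ic[["A0"]]
  ss <- numeric(0)
  if (abs(qa) < 1e-13) {
    if (abs(qb) > 1e-13) ss <- -qc / qb
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc >= 0) ss <- (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)
  }
  ss <- ss[is.finite(ss) & ss > 1e-9]
  if (!length(ss)) return(numeric(0))
  taus <- 1 / ss
  ok <- vapply(taus, function(tt) all(ic + sl / tt > 1e-10), logical(1))
  sort(taus[ok])
}

#' Hopf thresholds at an equilibrium of the reduced system
#'
#' Candidate time-scale ratios at which the Routh-Hurwitz residual of the
#' 3x3 Jacobian vanishes with all characteristic coefficients positive
#' (i.e. a purely imaginary pair crosses the axis).
#'
#' @inheritParams reduce_three_stimuli
#' @param equilibrium `(v1, v2)` or `(v1, v2, theta)` of the equilibrium.
#' @return Sorted numeric vector of Hopf tau values (possibly empty).
#' @export
reduced_hopf_taus <- function(alpha, beta, C, equilibrium) {
  u <- equilibrium[1:2]
  jac_of_s <- function(s) {
    sys <- reduce_three_stimuli(alpha, beta, C, tau = 1 / s)
    e <- sys$e
    v3 <- (C - e[1] * u[1] - e[2] * u[2]) / e[3]
    th <- mean(c(u, v3)^2)
    numeric_jacobian(sys$rhs, c(u, th))
  }
  .hopf_taus_affine(jac_of_s)
}

#' Minimal Hopf threshold over the equilibrium branches
#'
#' Sweeps the conservation constant over a grid, locating all equilibria at
#' each C (warm-started from the previous grid point) and collecting the
#' Hopf tau candidates on every branch; returns the overall minimum, below
#' which no Hopf bifurcation exists anywhere on the diagram.
#'
#' @inheritParams reduced_equilibria
#' @param C_grid grid of conservation-constant values to sweep.
#' @param refine number of local refinement passes around the running
#'   minimum (each pass shrinks the grid step tenfold).
#' @param seed RNG seed for the multi-start grids.
#' @return A list with `tau_min`, `C_at_min`, and the sweep table
#'   `data.frame(C, tau)` of per-C minima.
#' @export
reduced_min_hopf_tau <- function(alpha, beta,
                                 C_grid = seq(-4, 5, by = 0.1),
                                 refine = 2L, n_starts = 60L, seed = 1L) {
  sweep_min <- function(grid, warm0 = NULL) {
    warm <- warm0
    tau_c <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
      eqs <- reduced_equilibria(alpha, beta, grid[i], n_starts = n_starts,
                                warm = warm, seed = seed)
      warm <- .isola_warm(eqs)
      taus <- numeric(0)
      for (j in seq_len(nrow(eqs)))
        taus <- c(taus, reduced_hopf_taus(alpha, beta, grid[i], eqs[j, 1:2]))
      if (length(taus)) tau_c[i] <- min(taus)
    }
    data.frame(C = grid, tau = tau_c)
  }
  tab <- sweep_min(C_grid)
  best <- tab[which.min(tab$tau), ]
  step <- if (length(C_grid) > 1) min(diff(C_grid)) else 0.1
  for (r in seq_len(refine)) {
    step <- step / 10
    grid <- seq(best$C - 10 * step, best$C + 10 * step, by = step)
    loc <- sweep_min(grid)
    if (all(is.na(loc$tau))) break
    best <- loc[which.min(loc$tau), ]
  }
  list(tau_min = best$tau, C_at_min = best$C, sweep = tab)
}

#' Period-doubling point of the stable cycle at fixed tau
#'
#' At a fixed time-scale ratio, locates the conservation-constant value at
#' which the attracting limit cycle of the reduced system undergoes a
#' period-doubling bifurcation, by bisecting on the sign of (most negative
#' real Floquet multiplier + 1).
#'
#' @inheritParams reduce_three_stimuli
#' @param C_range length-2 interval bracketing the period doubling (the
#'   multiplier must be above -1 at the lower end and below -1 at the
#'   upper end).
#' @param tol bisection tolerance on C.
#' @param y0 initial state used to reach the attractor.
#' @return A list with `C` (the PD location), `multiplier_lo`,
#'   `multiplier_hi` at the bracketing ends, and `history` of the bisection.
#' @export
reduced_period_doubling_C <- function(alpha, beta, tau, C_range,
                                      tol = 1e-3, y0 = c(1.05, 0.95, 0.9)) {
  indicator <- function(C) {
    sys <- reduce_three_stimuli(alpha, beta, C, tau = tau)
    cyc <- find_limit_cycle(sys, y0, transient = 500, t_observe = 120,
                            max_period = 60, max_iterates = 1L,
                            shoot_anyway = TRUE)
    if (is.null(cyc))
      stop("no simple limit cycle located at C = ", format(C),
           " (", attr(cyc, "diagnostic"), ")")
    cyc <- floquet_multipliers(sys, cyc)
    mu <- cyc$floquet
    re <- Re(mu[abs(Im(mu)) < 1e-6 * pmax(Mod(mu), 1)])
    min(re)
  }
  lo <- C_range[1]; hi <- C_range[2]
  mlo <- indicator(lo); mhi <- indicator(hi)
  if ((mlo + 1) * (mhi + 1) > 0)
    stop("C_range does not bracket a period doubling: multipliers ",
         format(mlo, digits = 4), " and ", format(mhi, digits = 4))
  hist <- data.frame(C = c(lo, hi), multiplier = c(mlo, mhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    mm <- indicator(mid)
    hist <- rbind(hist, data.frame(C = mid, multiplier = mm))
    if ((mm + 1) * (mlo + 1) > 0) { lo <- mid; mlo <- mm } else hi <- mid
  }
  list(C = (lo + hi) / 2, multiplier_lo = mlo, multiplier_hi = mhi,
       history = hist)
}
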