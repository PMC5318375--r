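#' Fixed points of the two-stimulus mean field
#'
#' For non-collinear stimuli and rho in (0,1) the averaged system has
#' exactly four equilibria in (v1, v2, theta): the origin, the two selective
#' states and the symmetric non-selective state. They depend only on the
#' presentation probabilities, not on the stimulus geometry.
#'
#' @param rho probability of presenting the first stimulus, in (0,1).
#' @return A named list of numeric triples `c(v1, v2, theta)`: `origin`,
#'   `z1` (selective for stimulus 1), `z2` (selective for stimulus 2),
#'   `symmetric`.
#' @examples
#' fixed_points_two_stimuli(0.5)$z1  # (2, 0, 2)
#' @export
fixed_points_two_stimuli <- function(rho) {
  if (!is.numeric(rho) || rho <= 0 || rho >= 1)
    stop("rho must lie strictly between 0 and 1")
  list(
    origin = c(0, 0, 0),
    z1 = c(1 / rho, 0, 1 / rho),
    z2 = c(0, 1 / (1 - rho), 1 / (1 - rho)),
    symmetric = c(1, 1, 1)
  )
}

#' Characteristic-polynomial coefficients at the selective equilibria
#'
#' Closed forms for the cubic characteristic polynomial
#' \eqn{\lambda^3 + A_2 \lambda^2 + A_1 \lambda + A_0} of the linearization
#' at the selective equilibria, in terms of a = |x2|^2, b = x1 . x2,
#' c = rho/(1-rho) and tau = tau_theta/tau_w (with |x1| = 1, tau_w = 1).
#' Differentiating the averaged equations at z2 = (0, 1/(1-rho), 1/(1-rho))
#' gives A_0 = c(a-b^2)/tau, A_1 = (a+c)/tau + c(b^2-a),
#' A_2 = 1/tau + c - a; at z1 = (1/rho, 0, 1/rho) the same computation
#' yields the analogous forms with the probability ratio inverted
#' (c replaced by 1/c), the two coinciding at equal probabilities. Both are
#' verified against the numeric Jacobian in the test suite. The constant
#' coefficient is strictly positive in either case, so no zero-eigenvalue
#' bifurcation can occur: stability is lost only through a Hopf
#' bifurcation.
#'
#' @param params a [two_stimulus_params()].
#' @param tau time-scale ratio, positive.
#' @return Named numeric vector `c(A0, A1, A2)`.
#' @export
charpoly_z1 <- function(params, tau) {
  stopifnot(inherits(params, "bcm_two_stimulus_params"), tau > 0)
  a <- params$a; b <- params$b; k <- 1 / params$c
  c(A0 = k * (a - b^2) / tau,
    A1 = (1 + a * k) / tau + k * (b^2 - a),
    A2 = 1 / tau + a * k - 1)
}

#' @rdname charpoly_z1
#' @export
charpoly_z2 <- function(params, tau) {
  stopifnot(inherits(params, "bcm_two_stimulus_params"), tau > 0)
  a <- params$a; b <- params$b; cc <- params$c
  c(A0 = cc * (a - b^2) / tau,
    A1 = (a + cc) / tau + cc * (b^2 - a),
    A2 = 1 / tau + cc - a)
}

# Routh-Hurwitz residual quadratics in tau (tau^2 * R_j). Stability holds
# for small tau; the Hopf point is the first downward crossing of Q.
# .q_r1 is called with the inverted ratio 1/c for z1 (see charpoly_z1).
.q_r1 <- function(a, b, cc) {
  c(q2 = cc * (a - b^2) * (1 - a * cc),
    q1 = -(1 + 2 * a * cc - a^2 * cc^2 - 2 * b^2 * cc),
    q0 = 1 + a * cc)
}
.q_r2 <- function(a, b, cc) {
  c(q2 = cc * (a - b^2) * (a - cc),
    q1 = 2 * cc * (b^2 - a) + cc^2 - a^2,
    q0 = a + cc)
}

# smallest positive root at which the quadratic crosses from + to -
.first_downward_root <- function(q) {
  q2 <- q[[1]]; q1 <- q[[2]]; q0 <- q[[3]]
  if (abs(q2) < 1e-12) {            # degenerate linear case (a = c)
    if (q1 >= 0) return(NA_real_)   # never crosses downward
    r <- -q0 / q1
    return(if (r > 0) r else NA_real_)
  }
  disc <- q1^2 - 4 * q2 * q0
  if (disc < 0) return(NA_real_)
  roots <- sort((-q1 + c(-1, 1) * sqrt(disc)) / (2 * q2))
  for (r in roots) {
    if (r > 0 && (2 * q2 * r + q1) < 0) return(r)
  }
  NA_real_
}

#' Critical time-scale ratio for the Hopf bifurcation of a selective state
#'
#' Solves the Routh-Hurwitz residual quadratic for the equilibrium selective
#' to stimulus 1 (`hopf_tau_z1`) or stimulus 2 (`hopf_tau_z2`). The returned
#' tau is the smallest positive root at which the residual crosses from
#' positive to negative — the first loss of stability as tau grows. The
#' degenerate case where the quadratic's leading coefficient vanishes
#' (a = c, for either equilibrium) is handled as a linear equation. In the
#' standard equal-amplitude, equal-probability case (a = c = 1) the value
#' reduces to 1/(1 - b^2).
#'
#' @param a squared norm of the second stimulus (first is a unit vector).
#' @param b inner product of the stimuli.
#' @param c probability ratio rho/(1-rho).
#' @return The critical ratio tau, or `NA` when the equilibrium is stable
#'   for all tau (no downward crossing).
#' @examples
#' hopf_tau_z1(1, cos(1), 1)  # 1/(1 - cos(1)^2) = 1.412...
#' @export
hopf_tau_z1 <- function(a, b, c) {
  p <- two_stimulus_params(a, b, c)
  .first_downward_root(.q_r1(p$a, p$b, 1 / p$c))
}

#' @rdname hopf_tau_z1
#' @export
hopf_tau_z2 <- function(a, b, c) {
  p <- two_stimulus_params(a, b, c)
  .first_downward_root(.q_r2(p$a, p$b, p$c))
}

#' Linear stability of a selective equilibrium
#'
#' Full Routh-Hurwitz verdict for z1 or z2: stable iff all three
#' characteristic coefficients are positive and A1 A2 - A0 > 0. Near the
#' first Hopf crossing the residual is the binding condition; at larger tau
#' a coefficient itself can turn negative, and this function checks all of
#' them. Ties within `tol` of a sign boundary are resolved as stable.
#'
#' @param which `"z1"` or `"z2"`.
#' @inheritParams hopf_tau_z1
#' @param tau time-scale ratio.
#' @param tol boundary tolerance on the sign tests.
#' @return Logical flag.
#' @export
selective_equilibrium_stable <- function(which = c("z1", "z2"), a, b, c, tau,
                                         tol = 1e-6) {
  which <- match.arg(which)
  p <- two_stimulus_params(a, b, c)
  A <- if (which == "z1") charpoly_z1(p, tau) else charpoly_z2(p, tau)
  R <- A[["A1"]] * A[["A2"]] - A[["A0"]]
  all(A > -tol) && R > -tol
}

#' Stability report for the two-stimulus equilibria
#'
#' Convenience wrapper assembling, for each equilibrium of the two-stimulus
#' mean field, the characteristic coefficients, the Routh-Hurwitz residual,
#' the stability flag and (for the selective states) the critical Hopf tau.
#'
#' @inheritParams hopf_tau_z1
#' @param tau time-scale ratio at which stability is evaluated.
#' @return A list of per-equilibrium reports, class `"bcm_stability_report"`.
#' @export
stability_report <- function(a, b, c, tau) {
  p <- two_stimulus_params(a, b, c)
  rho <- c / (1 + c)
  rep_z <- function(which) {
    A <- if (which == "z1") charpoly_z1(p, tau) else charpoly_z2(p, tau)
    list(equilibrium = which,
         coefficients = A,
         residual = unname(A["A1"] * A["A2"] - A["A0"]),
         stable = selective_equilibrium_stable(which, a, b, c, tau),
         hopf_tau = if (which == "z1") hopf_tau_z1(a, b, c)
                    else hopf_tau_z2(a, b, c))
  }
  out <- list(
    origin = list(equilibrium = "origin", stable = FALSE,
                  note = "nonlinearly unstable (center-manifold escape)"),
    z1 = rep_z("z1"),
    z2 = rep_z("z2"),
    symmetric = list(
      equilibrium = "symmetric",
      stable = FALSE,
      note = sprintf(
        "constant characteristic coefficient rho(1-rho)(b^2-a)/tau = %.6g < 0",
        rho * (1 - rho) * (b^2 - a) / tau))
  )
  structure(out, class = "bcm_stability_report", tau = tau,
            params = list(a = a, b = b, c = c))
}

#' @export
print.bcm_stability_report <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Stability report (a = %g, b = %g, c = %g, tau = %g)\n",
              p$a, p$b, p$c, attr(x, "tau")))
  for (r in x) {
    cat(sprintf(" %-10s stable: %-5s", r$equilibrium, r$stable))
    if (!is.null(r$hopf_tau))
      cat(sprintf("  hopf tau: %s",
                  if (is.na(r$hopf_tau)) "none" else format(r$hopf_tau, digits = 6)))
    cat("\n")
  }
  invisible(x)
}

#' Hopf thresholds of the two-neuron laterally inhibited network
#'
#' For two mutually inhibiting neurons (inhibition strength gamma) driven by
#' unit-vector stimuli at angle alpha with equal probability, the symmetric
#' selective equilibrium loses stability at
#' \eqn{\tau_H^s = (1-\gamma)/(1-\cos^2\alpha)} (through a symmetry-breaking
#' Hopf) and the antisymmetric one at
#' \eqn{\tau_H^a = (1-\gamma\cos\alpha)/(1-\cos^2\alpha)}. At gamma = 0 both
#' reduce to the single-neuron value 1/(1-cos^2 alpha).
#'
#' @param gamma inhibition strength in [0, 1).
#' @param alpha stimulus angle in radians, not 0 or pi.
#' @return Named vector `c(sym = tau_H_s, anti = tau_H_a)`.
#' @export
network_hopf_taus <- function(gamma, alpha) {
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  s2 <- 1 - cos(alpha)^2
  if (s2 < 1e-12) stop("alpha must not be 0 or pi (collinear stimuli)")
  c(sym = (1 - gamma) / s2, anti = (1 - gamma * cos(alpha)) / s2)
}

# 3x3 block of the symmetric-equilibrium linearization, a_j in {g-h, g+h}
.network_block <- function(aj, beta, tau) {
  matrix(c(aj, beta * aj, 2 / tau,
           -beta * aj, -aj, 0,
           -aj, -beta * aj, -1 / tau), 3, 3)
}

#' Block factorization of the symmetric-equilibrium linearization
#'
#' The 6x6 linearization of the two-neuron network at the symmetric
#' selective equilibrium is block symmetric, so its spectrum is the union of
#' the spectra of two 3x3 blocks of common shape: `M1` with amplitude
#' a1 = g - h governs in-phase perturbations and `M2` with a2 = g + h
#' governs anti-phase ones (g = 1/(1-gamma^2), h = gamma/(1-gamma^2)).
#' Since a2 > a1, the first instability arises in the M2 block: a
#' symmetry-breaking Hopf to out-of-phase oscillations.
#'
#' @inheritParams network_hopf_taus
#' @param tau time-scale ratio.
#' @return A list with `M1`, `M2`, `Ms` (the full 6x6 matrix), `eigen1`,
#'   `eigen2` and `eigen_full`.
#' @export
block_eigen_split <- function(gamma, alpha, tau) {
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  g <- 1 / (1 - gamma^2); h <- gamma / (1 - gamma^2)
  beta <- cos(alpha)
  M1 <- .network_block(g - h, beta, tau)
  M2 <- .network_block(g + h, beta, tau)
  Gb <- .network_block(g, beta, tau)
  Hb <- .network_block(h, beta, tau)
  Hb[3, ] <- 0                                  # theta rows do not couple
  Ms <- rbind(cbind(Gb, -Hb), cbind(-Hb, Gb))
  list(M1 = M1, M2 = M2, Ms = Ms,
       eigen1 = eigen(M1, only.values = TRUE)$values,
       eigen2 = eigen(M2, only.values = TRUE)$values,
       eigen_full = eigen(Ms, only.values = TRUE)$values)
}

#' Partially selective network equilibria are saddles
#'
#' At rho = 1/2 the equilibria where one neuron sits at the non-selective
#' state (1,1,1) and the other at a selective state have characteristic
#' constant coefficient
#' \eqn{a_0 = -(g^2-h^2)^2 (\beta^2-1)^2 / (4 \tau^2) < 0}: the product of
#' the six eigenvalues is negative, so eigenvalues have mixed signs and the
#' point is a saddle.
#'
#' @inheritParams block_eigen_split
#' @return A list with `a0` (the closed-form coefficient) and `saddle`
#'   (logical, `a0 < 0`).
#' @export
partial_equilibrium_is_saddle <- function(gamma, alpha, tau) {
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  g <- 1 / (1 - gamma^2); h <- gamma / (1 - gamma^2)
  beta <- cos(alpha)
  a0 <- -(g^2 - h^2)^2 * (beta^2 - 1)^2 / (4 * tau^2)
  list(a0 = a0, saddle = a0 < 0)
}

#' Steady-state activities under all-to-all lateral inhibition
#'
#' For N neurons with partial (feedforward) activities s and uniform mutual
#' inhibition gamma, the net activities solve G v = s with G the matrix with
#' unit diagonal and gamma off-diagonal. The closed form is
#' \deqn{v_i = \frac{s_i}{1-\gamma} -
#'       \frac{\gamma}{(1-\gamma)(1+\gamma(N-1))} \sum_j s_j.}
#' G is singular at gamma = 1 and gamma = -1/(N-1).
#'
#' @param s numeric vector of partial activities.
#' @param gamma inhibition strength.
#' @return Numeric vector of net activities, same length as `s`.
#' @export
inhibition_steady_state <- function(s, gamma) {
  N <- length(s)
  if (N < 1L) stop("s must be nonempty")
  if (abs(1 - gamma) < 1e-12 || (N > 1L && abs(1 + gamma * (N - 1)) < 1e-12))
    stop("inhibition matrix G is singular at gamma = 1 or gamma = -1/(N-1)")
  s / (1 - gamma) - gamma * sum(s) / ((1 - gamma) * (1 + gamma * (N - 1)))
}
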