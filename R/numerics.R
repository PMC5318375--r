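.bcm_env <- new.env(parent = emptyenv())

#' Diagnostic from the last failed cycle search
#'
#' When [find_limit_cycle()] returns `NULL`, a short explanation (settled to
#' an equilibrium, no recurrence, refinement failure, ...) is recorded and
#' can be retrieved here.
#'
#' @return Character string, or `NULL` if no failure has been recorded.
#' @export
last_cycle_diagnostic <- function() {
  if (exists("cycle_diagnostic", .bcm_env)) .bcm_env$cycle_diagnostic else NULL
}

.no_cycle <- function(why) {
  assign("cycle_diagnostic", why, envir = .bcm_env)
  NULL
}

#' Central-difference Jacobian
#'
#' Second-order finite-difference Jacobian with the step scaled to the state
#' magnitude component-wise.
#'
#' @param f function mapping a numeric vector to a numeric vector.
#' @param x point of evaluation.
#' @param step optional scalar or vector of steps; default
#'   `eps^(1/3) * pmax(|x|, 1)`.
#' @return The Jacobian matrix of `f` at `x`.
#' @export
numeric_jacobian <- function(f, x, step = NULL) {
  n <- length(x)
  f0 <- f(x)
  if (any(!is.finite(f0))) stop("rhs is not finite at the evaluation point")
  if (is.null(step)) step <- .Machine$double.eps^(1 / 3) * pmax(abs(x), 1)
  step <- rep_len(step, n)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + step[j]; xm[j] <- xm[j] - step[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * step[j])
  }
  J
}

# extra undamped Newton sweeps: near a degenerate root (e.g. the origin of
# the response equations, which carries a double zero eigenvalue) plain
# Newton converges only linearly, leaving a cloud of near-roots that all
# pass the residual test; polishing collapses the cloud onto the root so
# deduplication sees one equilibrium. Isolated roots are unaffected.
.polish <- function(f, x, steps = 50L, cap = 0.1) {
  for (i in seq_len(steps)) {
    fx <- f(x)
    if (any(!is.finite(fx))) break
    J <- numeric_jacobian(f, x)
    dx <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(dx)) break
    nd <- sqrt(sum(dx^2))
    if (nd > cap) break
    x <- x - dx
    if (nd < 1e-15) break
  }
  x
}

# damped Newton for square root-finding; returns NULL on failure
.newton <- function(f, x0, tol = 1e-12, maxit = 80L, cap = 5) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (any(!is.finite(fx))) return(NULL)
    if (sqrt(sum(fx^2)) < tol) return(x)
    J <- numeric_jacobian(f, x)
    dx <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    nd <- sqrt(sum(dx^2))
    if (nd > cap) dx <- dx * cap / nd
    x <- x - dx
  }
  if (sqrt(sum(f(x)^2)) < tol * 100) x else NULL
}

#' Multi-start equilibrium search
#'
#' Finds equilibria of a vector field by damped Newton iteration from a
#' seeded set of random starting points in a box, deduplicating converged
#' roots and verifying the residual.
#'
#' @param rhs function of the numeric state returning the time derivative,
#'   or a `bcm_system`.
#' @param lower,upper numeric vectors bounding the start box.
#' @param n_starts number of random starts.
#' @param seed RNG seed for the start grid.
#' @param warm optional matrix of additional starting points (one per row),
#'   tried before the random grid — useful for continuation in a parameter.
#' @param tol_dedup distance below which two roots are considered identical.
#' @param tol_res residual norm below which a root is accepted.
#' @return A matrix with one equilibrium per row (possibly 0 rows).
#' @export
find_equilibria <- function(rhs, lower, upper, n_starts = 200L, seed = 1L,
                            warm = NULL, tol_dedup = 1e-6, tol_res = 1e-9) {
  if (inherits(rhs, "bcm_system")) rhs <- rhs$rhs
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)))
  d <- length(lower)
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * d, rep(lower, each = n_starts),
                                rep(upper, each = n_starts)), n_starts, d)
  if (!is.null(warm)) starts <- rbind(as.matrix(warm), starts)
  roots <- matrix(numeric(0), 0, d)
  for (i in seq_len(nrow(starts))) {
    r <- .newton(rhs, starts[i, ], tol = tol_res * 1e-2)
    if (is.null(r)) next
    r <- .polish(rhs, r)
    if (sqrt(sum(rhs(r)^2)) >= tol_res) next
    if (nrow(roots) == 0L ||
        min(sqrt(rowSums((roots - matrix(r, nrow(roots), d, byrow = TRUE))^2))) >
          tol_dedup)
      roots <- rbind(roots, r)
  }
  rownames(roots) <- NULL
  roots
}

# leading eigenvalue real part among complex-conjugate pairs
.leading_complex_re <- function(J, imag_tol = 1e-8) {
  ev <- eigen(J, only.values = TRUE)$values
  cpx <- ev[abs(Im(ev)) > imag_tol]
  if (!length(cpx)) return(NA_real_)
  max(Re(cpx))
}

#' Bisection for a Hopf bifurcation in a one-parameter family
#'
#' Tracks an equilibrium of `make_rhs(tau)` across the parameter range by
#' Newton continuation and bisects on the real part of the leading complex
#' eigenvalue pair of the numerical Jacobian. Errors if the leading pair
#' does not change sign over the range, or if a zero eigenvalue is detected
#' (which would signal a steady-state bifurcation instead).
#'
#' @param make_rhs function of the parameter returning an rhs function.
#' @param y_guess starting guess for the equilibrium at the lower parameter.
#' @param range length-2 numeric parameter interval.
#' @param tol bisection tolerance on the leading real part.
#' @param det_tol determinant magnitude below which a zero eigenvalue is
#'   reported.
#' @return A list of class `"bcm_bifurcation_point"` with `kind = "HB"`,
#'   `parameter`, `state`, and `eigenvalues` at the located point.
#' @export
hopf_bisect <- function(make_rhs, y_guess, range, tol = 1e-8,
                        det_tol = 1e-10) {
  probe <- function(tau, guess) {
    rhs <- make_rhs(tau)
    eq <- .newton(rhs, guess)
    if (is.null(eq)) stop("lost the equilibrium during continuation at tau = ",
                          format(tau))
    J <- numeric_jacobian(rhs, eq)
    if (abs(det(J)) < det_tol)
      stop("zero-eigenvalue crossing detected at tau = ", format(tau),
           " (not a Hopf bifurcation)")
    list(eq = eq, re = .leading_complex_re(J), J = J)
  }
  lo <- range[1]; hi <- range[2]
  plo <- probe(lo, y_guess)
  phi <- probe(hi, plo$eq)
  if (is.na(plo$re) || is.na(phi$re) || sign(plo$re) == sign(phi$re))
    stop("leading complex eigenvalue pair does not change sign over the range")
  guess <- plo$eq
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- probe(mid, guess)
    guess <- pm$eq
    if (abs(pm$re) < tol || (hi - lo) < 1e-13) break
    if (sign(pm$re) == sign(plo$re)) { lo <- mid; plo <- pm } else hi <- mid
  }
  structure(list(kind = "HB", parameter = mid, state = pm$eq,
                 eigenvalues = eigen(pm$J, only.values = TRUE)$values),
            class = "bcm_bifurcation_point")
}

#' @export
print.bcm_bifurcation_point <- function(x, ...) {
  cat(sprintf("%s at parameter %.8g\n", x$kind, x$parameter))
  if (!is.null(x$state))
    cat(" state:", format(x$state, digits = 6), "\n")
  invisible(x)
}

# one return of the Poincare map through the plane y[ci] = value
# (increasing), starting on the section; returns crossing state and time
.poincare_return <- function(rhs, y, ci, value, tmax = 200, t_off = 0.25,
                             rtol = 1e-10, atol = 1e-12) {
  f <- function(t, y, p) list(rhs(y))
  root <- function(t, y, p) y[ci] - value
  s0 <- deSolve::ode(y, c(0, t_off), f, NULL, method = "lsoda", maxsteps = 100000,
                     rtol = rtol, atol = atol)
  ycur <- as.numeric(s0[nrow(s0), -1]); tcur <- t_off
  for (k in 1:12) {
    sol <- deSolve::ode(ycur, c(0, tmax), f, NULL, method = "lsodar", maxsteps = 100000,
                        rtol = rtol, atol = atol, rootfun = root)
    tr <- attr(sol, "troot")
    if (is.null(tr) || !length(tr)) return(NULL)
    yr <- as.numeric(sol[nrow(sol), -1])
    tcur <- tcur + tr[1]
    if (rhs(yr)[ci] > 0) return(list(y = yr, t = tcur))
    s1 <- deSolve::ode(yr, c(0, 0.05), f, NULL, method = "lsoda", maxsteps = 100000,
                       rtol = rtol, atol = atol)
    ycur <- as.numeric(s1[nrow(s1), -1]); tcur <- tcur + 0.05
  }
  NULL
}

#' Locate a limit cycle by return-map convergence
#'
#' Integrates past a transient, detects recurrence on a Poincare plane
#' placed at the midrange of the most active coordinate, and refines the
#' cycle with Newton iteration on the (possibly iterated) return map until
#' the state recurs within `recur_tol`. Period-doubled orbits are handled by
#' composing the map up to `max_iterates` times.
#'
#' @param rhs vector field (function of the state) or `bcm_system`.
#' @param y0 initial state.
#' @param transient time to discard before looking for recurrence.
#' @param t_observe observation window used to detect the cycle.
#' @param max_period upper bound on the period searched for.
#' @param max_iterates maximum return-map iterates (1 finds a simple cycle,
#'   2 a period-doubled one, ...).
#' @param shoot_anyway attempt Newton shooting on the single-iterate return
#'   map even when the attractor shows no recurrence. This locates a mildly
#'   unstable simple cycle embedded in a period-doubled attractor (used when
#'   bisecting a period-doubling point); leave FALSE to treat
#'   non-recurrent motion as "no cycle".
#' @param recur_tol recurrence tolerance after Newton refinement.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `"bcm_cycle"` (list with `y0` on the section,
#'   `period`, `samples` — states over one period —, `section` = c(index,
#'   value), `iterates`), or `NULL` with a `"diagnostic"` attribute if no
#'   recurrence was found (equilibrium, quasi-periodic or chaotic motion).
#' @export
find_limit_cycle <- function(rhs, y0, transient = 200, t_observe = 200,
                             max_period = 100, max_iterates = 4L,
                             shoot_anyway = FALSE,
                             recur_tol = 1e-6, rtol = 1e-9, atol = 1e-11) {
  if (inherits(rhs, "bcm_system")) rhs <- rhs$rhs
  f <- function(t, y, p) list(rhs(y))
  tr <- deSolve::ode(y0, c(0, transient), f, NULL, method = "lsoda", maxsteps = 100000,
                     rtol = rtol, atol = atol)
  y1 <- as.numeric(tr[nrow(tr), -1])
  ts <- seq(0, t_observe, by = min(0.02, max_period / 500))
  sol <- deSolve::ode(y1, ts, f, NULL, method = "lsoda", maxsteps = 100000,
                      rtol = rtol, atol = atol)
  Y <- unname(as.matrix(sol[, -1, drop = FALSE]))
  amp <- apply(Y, 2, function(col) diff(range(col)))
  if (max(amp) < 1e-7)
    return(.no_cycle("trajectory settles to an equilibrium"))
  ci <- which.max(amp)
  value <- mean(range(Y[, ci]))
  x <- Y[, ci]
  idx <- which(x[-length(x)] < value & x[-1] >= value)
  if (length(idx) < 3L)
    return(.no_cycle("fewer than 3 section crossings"))
  cross <- t(vapply(idx, function(i) {
    a <- (value - x[i]) / (x[i + 1] - x[i])
    (1 - a) * Y[i, ] + a * Y[i + 1, ]
  }, numeric(ncol(Y))))
  tcross <- sol[idx, 1] + (value - x[idx]) / (x[idx + 1] - x[idx]) *
    (sol[idx + 1, 1] - sol[idx, 1])
  nc <- nrow(cross)
  scale <- max(amp)
  k_found <- NA_integer_
  for (k in seq_len(min(max_iterates, nc - 1L))) {
    if (nc > k && sqrt(sum((cross[nc, ] - cross[nc - k, ])^2)) < 1e-2 * scale) {
      k_found <- k; break
    }
  }
  if (is.na(k_found)) {
    if (!shoot_anyway)
      return(.no_cycle("no return-map recurrence (quasi-periodic or chaotic motion?)"))
    k_found <- 1L
  }
  # Newton on the k-iterated return map in the section coordinates
  free <- setdiff(seq_len(ncol(Y)), ci)
  mapk <- function(u) {
    y <- numeric(ncol(Y)); y[ci] <- value; y[free] <- u
    tt <- 0
    for (i in seq_len(k_found)) {
      r <- .poincare_return(rhs, y, ci, value, tmax = max_period,
                            rtol = rtol, atol = atol)
      if (is.null(r)) return(NULL)
      y <- r$y; tt <- tt + r$t
    }
    list(u = y[free], T = tt)
  }
  u <- cross[nc, free]
  period <- NA_real_
  for (it in 1:30) {
    r0 <- mapk(u)
    if (is.null(r0)) break
    Fv <- r0$u - u
    period <- r0$T
    if (sqrt(sum(Fv^2)) < recur_tol) break
    h <- 1e-7 * pmax(abs(u), 1)
    J <- matrix(0, length(u), length(u))
    ok <- TRUE
    for (j in seq_along(u)) {
      up <- u; up[j] <- up[j] + h[j]
      rp <- mapk(up)
      if (is.null(rp)) { ok <- FALSE; break }
      J[, j] <- ((rp$u - up) - Fv) / h[j]
    }
    if (!ok) break
    du <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(du)) break
    u <- u - du
  }
  if (!is.finite(period))
    return(.no_cycle("return-map refinement failed"))
  rfin <- mapk(u)
  if (is.null(rfin) || sqrt(sum((rfin$u - u)^2)) > recur_tol * 100)
    return(.no_cycle("return map did not converge to a closed orbit"))
  ystart <- numeric(ncol(Y)); ystart[ci] <- value; ystart[free] <- u
  tsamp <- seq(0, period, length.out = 201L)
  samples <- deSolve::ode(ystart, tsamp, f, NULL, method = "lsoda", maxsteps = 100000,
                          rtol = rtol, atol = atol)
  structure(
    list(y0 = ystart, period = period,
         samples = unname(as.matrix(samples)),
         section = c(index = ci, value = value), iterates = k_found,
         floquet = NULL, stable = NA),
    class = "bcm_cycle"
  )
}

#' @export
print.bcm_cycle <- function(x, ...) {
  cat(sprintf("Limit cycle: period %.6g (%d return-map iterate%s)\n",
              x$period, x$iterates, if (x$iterates > 1) "s" else ""))
  if (!is.null(x$floquet))
    cat(" Floquet multipliers:", format(x$floquet, digits = 5), "\n")
  invisible(x)
}

#' Floquet multipliers of a limit cycle
#'
#' Integrates the variational equations along one period to obtain the
#' monodromy matrix; its eigenvalues are the Floquet multipliers. One
#' multiplier is always (numerically) +1, along the flow; the cycle is
#' stable when all others lie inside the unit circle. A period-doubling
#' bifurcation corresponds to a real multiplier crossing -1, a torus
#' bifurcation to a complex pair crossing the unit circle.
#'
#' @param rhs vector field or `bcm_system`.
#' @param cycle a `bcm_cycle` from [find_limit_cycle()].
#' @param rtol,atol integrator tolerances.
#' @param trivial_tol tolerance for identifying the trivial multiplier.
#' @return The cycle with `floquet` (complex multipliers, decreasing
#'   modulus), `stable`, and `trivial_error` (distance of the trivial
#'   multiplier from +1) filled in.
#' @export
floquet_multipliers <- function(rhs, cycle, rtol = 1e-10, atol = 1e-12,
                                trivial_tol = 1e-3) {
  if (inherits(rhs, "bcm_system")) rhs <- rhs$rhs
  stopifnot(inherits(cycle, "bcm_cycle"))
  n <- length(cycle$y0)
  f <- function(t, y, p) {
    x <- y[seq_len(n)]
    Phi <- matrix(y[-seq_len(n)], n, n)
    J <- numeric_jacobian(rhs, x)
    list(c(rhs(x), as.vector(J %*% Phi)))
  }
  sol <- deSolve::ode(c(cycle$y0, as.vector(diag(n))), c(0, cycle$period),
                      f, NULL, method = "lsoda", maxsteps = 100000, rtol = rtol, atol = atol)
  M <- matrix(as.numeric(sol[nrow(sol), -seq_len(n + 1L)]), n, n)
  mu <- eigen(M, only.values = TRUE)$values
  mu <- mu[order(-Mod(mu))]
  i_triv <- which.min(Mod(mu - 1))
  triv_err <- Mod(mu[i_triv] - 1)
  if (triv_err > trivial_tol)
    warning("trivial Floquet multiplier deviates from 1 by ",
            format(triv_err, digits = 3), "; monodromy may be ill-conditioned")
  nontrivial <- mu[-i_triv]
  cycle$floquet <- mu
  cycle$trivial_error <- triv_err
  cycle$stable <- all(Mod(nontrivial) < 1)
  cycle
}

#' Natural-parameter continuation of a stable limit cycle
#'
#' Steps a parameter across `par_seq`, re-locating the attracting cycle at
#' each value from the previous cycle's state (naive natural continuation;
#' unstable branch segments are not followed). Emits bifurcation events:
#' `PD` when a real Floquet multiplier crosses -1, `TR` when a complex pair
#' crosses the unit circle, `LP/end` when the branch terminates (with the
#' boundary refined by bisection on cycle existence), and `HC` candidates
#' when the period exceeds `hc_period` while the orbit comes within
#' `hc_dist` of the supplied saddle point.
#'
#' @param make_rhs function of the parameter returning an rhs function.
#' @param par_seq increasing or decreasing sequence of parameter values.
#' @param y0 state from which the first cycle is grown.
#' @param transient,t_observe,max_period passed to [find_limit_cycle()].
#' @param floquet logical: compute Floquet multipliers along the branch.
#' @param saddle optional equilibrium used for homoclinic-candidate tests.
#' @param hc_period,hc_dist thresholds for the HC candidate call.
#' @param refine_end logical: bisect the parameter at which the branch ends.
#' @param end_tol bisection tolerance for the branch end.
#' @return A list of class `"bcm_branch"`: `branch` (data.frame with
#'   parameter, period, amplitude, stable), `events` (list of
#'   `bcm_bifurcation_point`), `cycles` (list of `bcm_cycle`).
#' @export
continue_cycle <- function(make_rhs, par_seq, y0, transient = 300,
                           t_observe = 200, max_period = 100,
                           floquet = FALSE, saddle = NULL,
                           hc_period = 1000, hc_dist = 1e-2,
                           refine_end = TRUE, end_tol = 1e-3) {
  events <- list()
  rows <- list()
  cycles <- list()
  ycur <- y0
  prev <- NULL
  last_par <- NA_real_
  i_end <- NA_integer_
  for (i in seq_along(par_seq)) {
    p <- par_seq[i]
    cyc <- find_limit_cycle(make_rhs(p), ycur, transient = transient,
                            t_observe = t_observe, max_period = max_period)
    if (is.null(cyc)) { i_end <- i; break }
    if (floquet) cyc <- floquet_multipliers(make_rhs(p), cyc)
    amp <- diff(range(cyc$samples[, 1 + cyc$section["index"]]))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, period = cyc$period, amplitude = amp,
      iterates = cyc$iterates,
      stable = if (floquet) cyc$stable else NA)
    cycles[[length(cycles) + 1L]] <- cyc
    if (floquet && !is.null(prev) && !is.null(prev$floquet)) {
      nt_now <- cyc$floquet[-which.min(Mod(cyc$floquet - 1))]
      nt_prev <- prev$floquet[-which.min(Mod(prev$floquet - 1))]
      re_now <- suppressWarnings(min(Re(nt_now[abs(Im(nt_now)) < 1e-8])))
      re_prev <- suppressWarnings(min(Re(nt_prev[abs(Im(nt_prev)) < 1e-8])))
      if (is.finite(re_now) && is.finite(re_prev) &&
          (re_prev + 1) * (re_now + 1) < 0)
        events[[length(events) + 1L]] <- structure(
          list(kind = "PD", parameter = p, state = cyc$y0),
          class = "bcm_bifurcation_point")
      cpx_now <- nt_now[abs(Im(nt_now)) >= 1e-8]
      cpx_prev <- nt_prev[abs(Im(nt_prev)) >= 1e-8]
      if (length(cpx_now) && length(cpx_prev) &&
          (max(Mod(cpx_prev)) - 1) * (max(Mod(cpx_now)) - 1) < 0)
        events[[length(events) + 1L]] <- structure(
          list(kind = "TR", parameter = p, state = cyc$y0),
          class = "bcm_bifurcation_point")
    }
    if (!is.null(saddle) && cyc$period > hc_period) {
      dmin <- min(sqrt(rowSums(
        (cyc$samples[, -1, drop = FALSE] -
           matrix(saddle, nrow(cyc$samples), length(saddle), byrow = TRUE))^2)))
      if (dmin < hc_dist)
        events[[length(events) + 1L]] <- structure(
          list(kind = "HC", parameter = p, state = cyc$y0,
               min_saddle_distance = dmin),
          class = "bcm_bifurcation_point")
    }
    prev <- cyc
    ycur <- cyc$y0
    last_par <- p
  }
  if (!is.na(i_end) && !is.null(prev) && refine_end) {
    lo <- last_par; hi <- par_seq[i_end]
    ygood <- prev$y0
    while (abs(hi - lo) > end_tol) {
      mid <- (lo + hi) / 2
      cyc <- find_limit_cycle(make_rhs(mid), ygood, transient = transient,
                              t_observe = t_observe, max_period = max_period)
      if (is.null(cyc)) hi <- mid else { lo <- mid; ygood <- cyc$y0 }
    }
    events[[length(events) + 1L]] <- structure(
      list(kind = "LP/end", parameter = (lo + hi) / 2, state = ygood),
      class = "bcm_bifurcation_point")
  }
  structure(list(branch = do.call(rbind, rows), events = events,
                 cycles = cycles),
            class = "bcm_branch")
}

#' @export
print.bcm_branch <- function(x, ...) {
  nb <- if (is.null(x$branch)) 0L else nrow(x$branch)
  cat("Cycle branch:", nb, "converged parameter values\n")
  for (ev in x$events)
    cat(sprintf("  event %s at parameter %.6g\n", ev$kind, ev$parameter))
  invisible(x)
}

#' Poincare section of a computed trajectory
#'
#' Linear-interpolated states where a trajectory crosses the plane
#' `coordinate = value` in the requested direction.
#'
#' @param trajectory a `bcm_trajectory`, or a matrix whose first column is
#'   time.
#' @param coordinate index of the section coordinate (among the state
#'   columns, i.e. 1 refers to the first state variable).
#' @param value section level.
#' @param direction `"increasing"` (default) or `"decreasing"`.
#' @return Matrix of crossing rows `(t, state...)`; zero rows if none.
#' @export
poincare_section <- function(trajectory, coordinate, value,
                             direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  M <- as.matrix(trajectory)
  x <- M[, coordinate + 1L]
  if (direction == "increasing")
    idx <- which(x[-length(x)] < value & x[-1] >= value)
  else
    idx <- which(x[-length(x)] > value & x[-1] <= value)
  if (!length(idx)) return(M[0, , drop = FALSE])
  out <- t(vapply(idx, function(i) {
    a <- (value - x[i]) / (x[i + 1] - x[i])
    (1 - a) * M[i, ] + a * M[i + 1, ]
  }, numeric(ncol(M))))
  colnames(out) <- colnames(M)
  out
}

#' Maximal Lyapunov exponent (tangent-vector growth)
#'
#' Classic two-trajectory-free estimate: integrates the variational
#' equation for one tangent vector alongside the state, renormalizing every
#' `dt` time units and averaging the log growth rates over segments. The
#' standard error over segments is reported alongside; a chaos call should
#' require the estimate to exceed zero by several standard errors.
#'
#' @param rhs vector field or `bcm_system`.
#' @param y0 initial state.
#' @param transient time discarded before measuring.
#' @param nseg number of renormalization segments.
#' @param dt segment length (time units).
#' @param rtol,atol integrator tolerances.
#' @param blowup abort threshold.
#' @return A list with `lambda` (per unit time), `se`, `nseg`, `dt`.
#' @export
max_lyapunov <- function(rhs, y0, transient = 300, nseg = 300L, dt = 2,
                         rtol = 1e-9, atol = 1e-11, blowup = 1e6) {
  if (inherits(rhs, "bcm_system")) rhs <- rhs$rhs
  n <- length(y0)
  fstate <- function(t, y, p) list(rhs(y))
  fvar <- function(t, y, p) {
    x <- y[seq_len(n)]
    d <- y[-seq_len(n)]
    list(c(rhs(x), as.vector(numeric_jacobian(rhs, x) %*% d)))
  }
  s <- deSolve::ode(y0, c(0, transient), fstate, NULL, method = "lsoda", maxsteps = 100000,
                    rtol = rtol, atol = atol)
  x <- as.numeric(s[nrow(s), -1])
  d <- rep(0, n); d[1] <- 1
  lams <- numeric(nseg)
  for (i in seq_len(nseg)) {
    sol <- deSolve::ode(c(x, d), c(0, dt), fvar, NULL, method = "lsoda", maxsteps = 100000,
                        rtol = rtol, atol = atol)
    z <- as.numeric(sol[nrow(sol), -1])
    x <- z[seq_len(n)]; d <- z[-seq_len(n)]
    if (max(abs(x)) > blowup) stop("trajectory became unbounded")
    nd <- sqrt(sum(d^2))
    lams[i] <- log(nd) / dt
    d <- d / nd
  }
  list(lambda = mean(lams), se = stats::sd(lams) / sqrt(nseg),
       nseg = nseg, dt = dt)
}

#' Relative selectivity across the time-scale ratio
#'
#' The relative-selectivity statistic normalizes the late-time minimum gap
#' between the two responses, \eqn{d(\tau) = \min_{t \ge t_0} |v_1 - v_2|},
#' by its maximum over the tau grid, so RS lies in [0, 1]. The onset time
#' t_0 is operationalized as a transient-discard fraction of the run.
#'
#' @param ensemble a two-stimulus [stimulus_ensemble()].
#' @param taus grid of time-scale ratios.
#' @param y0 initial state `c(v1, v2, theta)`.
#' @param T integration time per tau.
#' @param window trailing fraction of the run used for the minimum gap.
#' @param dt output step.
#' @return A data.frame with columns `tau`, `d`, `rs`, `converged`;
#'   non-convergent (unbounded) runs carry `converged = FALSE` and are
#'   excluded from the normalization.
#' @export
relative_selectivity <- function(ensemble, taus, y0 = c(2.05, 0.02, 2),
                                 T = 600, window = 0.5, dt = 0.05) {
  stopifnot(ensemble$m == 2L)
  d <- rep(NA_real_, length(taus))
  conv <- rep(TRUE, length(taus))
  for (i in seq_along(taus)) {
    sys <- bcm_meanfield(ensemble, bcm_rule(1, taus[i]))
    tr <- integrate_system(sys, y0, T, dt = dt)
    if (isTRUE(attr(tr, "unbounded"))) { conv[i] <- FALSE; next }
    late <- tr$t >= (1 - window) * max(tr$t)
    d[i] <- min(abs(tr$v1[late] - tr$v2[late]))
  }
  dmax <- max(d[conv], na.rm = TRUE)
  data.frame(tau = taus, d = d, rs = d / dmax, converged = conv)
}
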