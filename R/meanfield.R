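#' Mean-field right-hand side in response space
#'
#' When the stimulus switches rapidly relative to the weight and threshold
#' time scales, the stochastic rule averages to a deterministic system for
#' the responses \eqn{v_k = w \cdot x^{(k)}}:
#' \deqn{\tau_w \dot v_k = \sum_l p_l \, G_{kl} \, v_l (v_l - \theta), \qquad
#'       \tau_\theta \dot\theta = \sum_l p_l v_l^2 - \theta,}
#' with G the Gram matrix of the stimuli. The dynamics depend on the stimuli
#' only through G and the probabilities.
#'
#' @param v response vector (length m).
#' @param theta threshold (scalar).
#' @param ensemble a [stimulus_ensemble()].
#' @param rule a [bcm_rule()].
#' @return A list with components `dv` and `dtheta`.
#' @export
meanfield_rhs <- function(v, theta, ensemble, rule) {
  if (length(v) != ensemble$m)
    stop("state has ", length(v), " responses but the ensemble has m = ",
         ensemble$m)
  ph <- ensemble$probs * rule$phi(v, theta)
  list(
    dv = as.vector(ensemble$gram %*% ph) / rule$tau_w,
    dtheta = (sum(ensemble$probs * v^2) - theta) / rule$tau_theta
  )
}

#' Weight-space right-hand side for a single presented stimulus
#'
#' The unaveraged rule while one stimulus x is held fixed:
#' \eqn{\tau_w \dot w = v x (v - \theta)} with \eqn{v = w \cdot x}, and
#' \eqn{\tau_\theta \dot\theta = v^2 - \theta}.
#'
#' @param w weight vector.
#' @param theta threshold.
#' @param x the active stimulus vector, same dimension as `w`.
#' @param rule a [bcm_rule()].
#' @return A list with components `dw` and `dtheta`.
#' @export
weight_rhs <- function(w, theta, x, rule) {
  if (length(w) != length(x))
    stop("weight dimension ", length(w), " does not match stimulus dimension ",
         length(x))
  v <- sum(w * x)
  list(dw = v * x * (v - theta) / rule$tau_w,
       dtheta = (v^2 - theta) / rule$tau_theta)
}

#' Averaged mean-field system in response space
#'
#' Packages the response-space vector field as a `bcm_system` suitable for
#' [integrate_system()], [find_equilibria()] and the bifurcation tools. The
#' state is `c(v_1, ..., v_m, theta)`.
#'
#' @inheritParams meanfield_rhs
#' @return An object of class `"bcm_system"` with fields `rhs` (a function
#'   of the numeric state), `dim`, `labels`, `ensemble`, `rule`.
#' @examples
#' ens <- stimulus_ensemble(list(c(1, 0), c(0, 1)))
#' sys <- bcm_meanfield(ens, bcm_rule(1, 1.1))
#' sys$rhs(c(2, 0, 2))  # selective fixed point: all zero
#' @export
bcm_meanfield <- function(ensemble, rule) {
  m <- ensemble$m
  gram <- ensemble$gram
  probs <- ensemble$probs
  tau_w <- rule$tau_w
  tau_theta <- rule$tau_theta
  rhs <- function(y) {
    v <- y[seq_len(m)]
    theta <- y[m + 1L]
    ph <- probs * v * (v - theta)
    c(as.vector(gram %*% ph) / tau_w,
      (sum(probs * v^2) - theta) / tau_theta)
  }
  structure(
    list(rhs = rhs, dim = m + 1L,
         labels = c(paste0("v", seq_len(m)), "theta"),
         ensemble = ensemble, rule = rule, kind = "meanfield"),
    class = "bcm_system"
  )
}

#' Mean-field system expressed in weight space
#'
#' Only available when the stimulus matrix X is square and invertible, in
#' which case the weight and response formulations are equivalent via
#' v = X w. Provided mainly as an independent cross-check of the
#' response-space equations.
#'
#' @inheritParams meanfield_rhs
#' @return A `bcm_system` over the state `c(w_1, ..., w_n, theta)`.
#' @export
bcm_meanfield_weights <- function(ensemble, rule) {
  X <- ensemble$X
  if (nrow(X) != ncol(X))
    stop("weight-space form requires a square stimulus matrix (m = n)")
  if (abs(det(X)) < 1e-12)
    stop("stimulus matrix is singular; weight space is not equivalent")
  probs <- ensemble$probs
  tau_w <- rule$tau_w
  tau_theta <- rule$tau_theta
  n <- ncol(X)
  rhs <- function(y) {
    w <- y[seq_len(n)]
    theta <- y[n + 1L]
    v <- as.vector(X %*% w)
    ph <- probs * v * (v - theta)
    c(as.vector(crossprod(X, ph)) / tau_w,
      (sum(probs * v^2) - theta) / tau_theta)
  }
  structure(
    list(rhs = rhs, dim = n + 1L,
         labels = c(paste0("w", seq_len(n)), "theta"),
         ensemble = ensemble, rule = rule, kind = "meanfield_weights"),
    class = "bcm_system"
  )
}

#' Integrate a bcm_system
#'
#' Adaptive integration (deSolve's lsoda) with a blow-up guard: for large
#' time-scale ratios solutions can escape to infinity in finite time, so
#' integration stops and flags the trajectory as unbounded once any state
#' component exceeds `blowup`.
#'
#' @param system a `bcm_system`.
#' @param y0 initial state, length `system$dim`.
#' @param times output times (numeric vector) or a single final time, in
#'   which case a grid of step `dt` is used.
#' @param dt output step when `times` is scalar.
#' @param rtol,atol integrator tolerances.
#' @param blowup magnitude at which the solution is declared unbounded.
#' @return A data.frame of class `"bcm_trajectory"` with column `t` followed
#'   by the state variables; attribute `"unbounded"` is TRUE if the guard
#'   tripped.
#' @export
integrate_system <- function(system, y0, times, dt = 0.1,
                             rtol = 1e-8, atol = 1e-10, blowup = 1e6) {
  stopifnot(inherits(system, "bcm_system"))
  if (length(y0) != system$dim)
    stop("initial state has length ", length(y0), ", expected ", system$dim)
  if (length(times) == 1L) times <- seq(0, times, by = dt)
  f <- function(t, y, p) list(system$rhs(y))
  guard <- function(t, y, p) max(abs(y)) - blowup
  sol <- deSolve::ode(y0, times, f, NULL, method = "lsodar", maxsteps = 100000,
                      rtol = rtol, atol = atol, rootfun = guard)
  out <- as.data.frame(unclass(sol))
  names(out) <- c("t", system$labels)
  unbounded <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  structure(out, class = c("bcm_trajectory", "data.frame"),
            unbounded = unbounded, labels = system$labels)
}

#' @export
print.bcm_system <- function(x, ...) {
  cat("BCM system (", x$kind, "), dim ", x$dim, ": ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.bcm_trajectory <- function(x, vars = NULL, ...) {
  labs <- attr(x, "labels")
  if (is.null(vars)) vars <- labs[grep("^v", labs)]
  if (!length(vars)) vars <- labs
  graphics::matplot(x$t, as.matrix(x[, vars, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time", ylab = "response", ...)
  graphics::legend("topright", legend = vars, col = seq_along(vars), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Reduced system for three stimuli driving two weights
#'
#' With three planar stimuli (1,0), (cos a, sin a), (cos b, sin b) presented
#' with equal probability, the three responses satisfy one linear constraint
#' e . v = C, where e spans the left null space of the stimulus matrix, and
#' the dynamics reduce to (v1, v2, theta) after eliminating
#' v3 = (C - e1 v1 - e2 v2)/e3. The Gram entries are c12 = cos(a),
#' c13 = cos(b), c23 = cos(a - b).
#'
#' The null-space coefficients used are e = (sin(a) sin(b - a),
#' -sin(a) sin(b), sin(a)^2), scaled so the third entry is sin(a)^2; the
#' conservation of e . v along trajectories is checked in the test suite.
#'
#' @param alpha,beta stimulus angles (radians); `sin(alpha)` must be nonzero
#'   so that v3 can be eliminated.
#' @param C value of the conserved quantity e . v, set by the initial
#'   condition.
#' @param tau time-scale ratio tau_theta/tau_w (tau_w is scaled to 1).
#' @return A `bcm_system` over `c(v1, v2, theta)`, with extra fields `e`
#'   (the constraint coefficients), `C`, `gram3`, and `lift`, a function
#'   mapping the reduced state to the full `c(v1, v2, v3, theta)`.
#' @export
reduce_three_stimuli <- function(alpha, beta, C, tau = 1) {
  e <- three_stimulus_constraint(alpha, beta)
  if (abs(e[3]) < 1e-10)
    stop("sin(alpha)^2 is (numerically) zero: cannot eliminate v3; ",
         "eliminate a different coordinate")
  g12 <- cos(alpha); g13 <- cos(beta); g23 <- cos(alpha - beta)
  G <- matrix(c(1, g12, g13, g12, 1, g23, g13, g23, 1), 3, 3)
  G12 <- G[1:2, ]
  rhs <- function(y) {
    v3 <- (C - e[1] * y[1] - e[2] * y[2]) / e[3]
    v <- c(y[1], y[2], v3)
    ph <- v * (v - y[3])
    c(as.vector(G12 %*% ph) / 3, (mean(v^2) - y[3]) / tau)
  }
  lift <- function(y) {
    v3 <- (C - e[1] * y[1] - e[2] * y[2]) / e[3]
    c(y[1], y[2], v3, y[3])
  }
  structure(
    list(rhs = rhs, dim = 3L, labels = c("v1", "v2", "theta"),
         e = e, C = C, tau = tau, alpha = alpha, beta = beta, gram3 = G,
         lift = lift, kind = "reduced3"),
    class = "bcm_system"
  )
}

#' Constraint coefficients of the three-stimulus reduction
#'
#' The left null vector of the stimulus matrix with rows (1,0),
#' (cos a, sin a), (cos b, sin b), scaled so its third entry is sin(a)^2.
#'
#' @inheritParams reduce_three_stimuli
#' @return Numeric vector `e` of length 3 with `t(e) %*% X = 0`.
#' @export
three_stimulus_constraint <- function(alpha, beta) {
  c(sin(alpha) * sin(beta - alpha), -sin(alpha) * sin(beta), sin(alpha)^2)
}
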