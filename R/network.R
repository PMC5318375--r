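#' Parameters of the two-neuron laterally inhibited BCM network
#'
#' Two neurons a and b receive a common two-stimulus ensemble and inhibit
#' each other with strength gamma. The lateral interaction is algebraic
#' (responses sit at the steady state of the fast relaxation dynamics), so
#' the mean field involves only g = 1/(1-gamma^2) and h = gamma/(1-gamma^2).
#'
#' @param gamma inhibition strength in (0, 1); gamma = 0 decouples the
#'   neurons.
#' @param ensemble a two-stimulus [stimulus_ensemble()].
#' @param rule a [bcm_rule()].
#' @return A list of class `"bcm_network_params"` with `gamma`, `g`, `h`,
#'   `rho` (probability of stimulus 1), and the ensemble and rule.
#' @export
network_params <- function(gamma, ensemble, rule = bcm_rule()) {
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  stopifnot(inherits(ensemble, "bcm_ensemble"), ensemble$m == 2L)
  structure(
    list(gamma = gamma, g = 1 / (1 - gamma^2), h = gamma / (1 - gamma^2),
         rho = ensemble$probs[1], ensemble = ensemble, rule = rule),
    class = "bcm_network_params"
  )
}

#' Right-hand side of the two-neuron network mean field
#'
#' The averaged dynamics of the six-dimensional state ordered as
#' `(v_a1, v_a2, theta_a, v_b1, v_b2, theta_b)`: each neuron's responses
#' are driven by its own plasticity through g and by the partner's through
#' -h, while each threshold tracks its own mean squared response. The
#' equations are equivariant under swapping the two neurons.
#'
#' @param state numeric state of length 6, ordered as above.
#' @param params a [network_params()].
#' @return Numeric derivative of length 6.
#' @export
network_meanfield_rhs <- function(state, params) {
  stopifnot(inherits(params, "bcm_network_params"), length(state) == 6L)
  G <- params$ensemble$gram
  rho <- params$rho
  p <- c(rho, 1 - rho)
  g <- params$g; h <- params$h
  tau_w <- params$rule$tau_w; tau_th <- params$rule$tau_theta
  va <- state[1:2]; tha <- state[3]
  vb <- state[4:5]; thb <- state[6]
  pha <- p * va * (va - tha)
  phb <- p * vb * (vb - thb)
  dva <- (g * as.vector(G %*% pha) - h * as.vector(G %*% phb)) / tau_w
  dvb <- (g * as.vector(G %*% phb) - h * as.vector(G %*% pha)) / tau_w
  c(dva, (sum(p * va^2) - tha) / tau_th,
    dvb, (sum(p * vb^2) - thb) / tau_th)
}

#' Network mean field as a bcm_system
#'
#' @param params a [network_params()].
#' @return A `bcm_system` over the six-dimensional network state.
#' @export
bcm_network <- function(params) {
  stopifnot(inherits(params, "bcm_network_params"))
  structure(
    list(rhs = function(y) network_meanfield_rhs(y, params), dim = 6L,
         labels = c("v_a1", "v_a2", "theta_a", "v_b1", "v_b2", "theta_b"),
         params = params, kind = "network"),
    class = "bcm_system"
  )
}

#' Fixed points of the network mean field
#'
#' The equilibrium conditions decouple per neuron, so every combination of
#' the four single-neuron options (origin, selective-1, selective-2,
#' symmetric) is an equilibrium of the network. All 16 combinations are
#' returned, labeled; they include the fully symmetric and fully
#' antisymmetric selective states and the partially selective points.
#'
#' @param rho probability of the first stimulus, in (0, 1).
#' @return A named list of numeric states of length 6; names are
#'   `"<option a>+<option b>"` with options `origin`, `z1`, `z2`, `sym`.
#' @export
network_fixed_points <- function(rho) {
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly between 0 and 1")
  opts <- list(origin = c(0, 0, 0),
               z1 = c(1 / rho, 0, 1 / rho),
               z2 = c(0, 1 / (1 - rho), 1 / (1 - rho)),
               sym = c(1, 1, 1))
  out <- list()
  for (na in names(opts)) for (nb in names(opts))
    out[[paste(na, nb, sep = "+")]] <- c(opts[[na]], opts[[nb]])
  out
}

# swap the two neurons of a network state
.swap_state <- function(y) c(y[4:6], y[1:3])

#' Classify the long-run network regime by simulation
#'
#' Coarse, simulation-based classification of the network attractor:
#' proximity to a stable equilibrium, cycle detection, the symmetry of the
#' per-neuron selectivity, a positive Lyapunov exponent, or collapse to the
#' origin ("a spike and then silence" at large tau).
#'
#' @param params a [network_params()].
#' @param y0 initial state; default perturbs the symmetric selective state
#'   without any special symmetry.
#' @param T simulation time.
#' @param lyapunov logical: distinguish quasi-periodic from chaotic motion
#'   with a tangent-vector exponent (slower).
#' @return A list with `label` (one of `"stable-selective"`,
#'   `"selective-oscillation"`, `"non-selective-oscillation"`,
#'   `"quasi-periodic/chaotic"`, `"collapsed-to-origin"`, `"unclassified"`)
#'   and diagnostics.
#' @export
classify_network_regime <- function(params, y0 = NULL, T = 2000,
                                    lyapunov = FALSE) {
  sys <- bcm_network(params)
  rho <- params$rho
  if (is.null(y0)) y0 <- c(1 / rho, 0, 1 / rho, 1 / rho, 0, 1 / rho) +
      c(0.13, 0.07, -0.05, -0.11, 0.05, 0.08)
  tr <- integrate_system(sys, y0, T, dt = 0.25)
  diag <- list()
  if (isTRUE(attr(tr, "unbounded")))
    return(list(label = "unbounded", diagnostics = diag))
  late <- tr[tr$t > 0.75 * T, -1, drop = FALSE]
  Y <- as.matrix(late)
  vmax <- max(abs(Y[, c(1, 2, 4, 5)]))
  diag$vmax_late <- vmax
  if (vmax < 0.05)
    return(list(label = "collapsed-to-origin", diagnostics = diag))
  amp <- apply(Y, 2, function(col) diff(range(col)))
  diag$max_amplitude <- max(amp)
  sel_a <- abs(mean(Y[, 1]) - mean(Y[, 2]))
  sel_b <- abs(mean(Y[, 4]) - mean(Y[, 5]))
  selective <- min(sel_a, sel_b) > 0.5
  diag$selectivity_gap <- c(a = sel_a, b = sel_b)
  if (max(amp) < 1e-3) {
    label <- if (selective) "stable-selective" else "unclassified"
    return(list(label = label, diagnostics = diag))
  }
  cyc <- find_limit_cycle(sys, as.numeric(Y[nrow(Y), ]), transient = 100,
                          t_observe = 300, max_period = 200)
  diag$cycle_found <- !is.null(cyc)
  if (is.null(cyc)) {
    if (lyapunov) {
      ly <- max_lyapunov(sys, as.numeric(Y[nrow(Y), ]), transient = 50,
                         nseg = 200L, dt = 2)
      diag$lyapunov <- ly
    }
    return(list(label = "quasi-periodic/chaotic", diagnostics = diag))
  }
  label <- if (selective) "selective-oscillation" else
    "non-selective-oscillation"
  list(label = label, diagnostics = diag, cycle = cyc)
}
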