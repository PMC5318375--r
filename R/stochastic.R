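#' Markov stimulus-switching process
#'
#' Stimulus presentation is modeled as a Markov jump process: the active
#' stimulus is held for an exponentially distributed time with rate `rate`,
#' then the next stimulus is drawn from `probs` (independent resampling, so
#' the stationary occupancy equals `probs` for any number of stimuli).
#'
#' @param rate switching rate (events per unit time), positive.
#' @param probs stationary selection probabilities; defaults to the
#'   ensemble's probabilities at simulation time.
#' @param seed integer seed used by [simulate_switching()].
#' @return An object of class `"bcm_switching"`.
#' @export
switching_process <- function(rate, probs = NULL, seed = 1L) {
  stopifnot(rate > 0)
  if (!is.null(probs)) {
    if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-8)
      stop("probs must be positive and sum to 1")
  }
  structure(list(rate = rate, probs = probs, seed = as.integer(seed)),
            class = "bcm_switching")
}

#' Hybrid simulation of the unaveraged BCM rule
#'
#' Simulates the weight-space rule with the stimulus switching as a Markov
#' jump process. Between switches the deterministic flow for the active
#' stimulus is integrated with a classical fixed-step RK4 scheme whose step
#' never exceeds `hmax`; integration restarts exactly at each switching time
#' so discontinuities in the forcing are handled event-exactly. The run is
#' fully reproducible from the process seed.
#'
#' @param ensemble a [stimulus_ensemble()].
#' @param rule a [bcm_rule()].
#' @param process a [switching_process()]; if its `probs` is NULL the
#'   ensemble probabilities are used. The initial stimulus is drawn from the
#'   same distribution.
#' @param w0 initial weights (length n).
#' @param theta0 initial threshold.
#' @param T total simulated time.
#' @param hmax maximum RK4 step between switches.
#' @param blowup abort threshold on any weight/threshold magnitude.
#' @return An object of class `"bcm_hybrid"`: a list with `t` (switch
#'   times, starting at 0), `w` (matrix of weights at those times), `theta`,
#'   `stimulus` (index active on the interval starting at each time),
#'   `v` (matrix of per-stimulus responses w . x^(k)), `seed`, and
#'   `unbounded` flag.
#' @examples
#' ens <- stimulus_ensemble(list(c(1, 0), c(0, 1)))
#' tr <- simulate_switching(ens, bcm_rule(25, 25 * 0.25),
#'                          switching_process(5, seed = 7),
#'                          w0 = c(0.1, 0.2), theta0 = 0.1, T = 50)
#' occupancy(tr)
#' @export
simulate_switching <- function(ensemble, rule, process, w0, theta0, T,
                               hmax = 0.02, blowup = 1e6) {
  stopifnot(inherits(ensemble, "bcm_ensemble"), inherits(rule, "bcm_rule"),
            inherits(process, "bcm_switching"), T > 0)
  if (length(w0) != ensemble$n)
    stop("w0 has length ", length(w0), " but stimuli have dimension ",
         ensemble$n)
  probs <- if (is.null(process$probs)) ensemble$probs else process$probs
  if (length(probs) != ensemble$m)
    stop("process probabilities do not match the ensemble size")
  X <- ensemble$X
  tau_w <- rule$tau_w
  tau_theta <- rule$tau_theta
  lam <- process$rate

  set.seed(process$seed)
  m <- ensemble$m
  k <- sample.int(m, 1L, prob = probs)
  w <- as.numeric(w0); th <- as.numeric(theta0); t <- 0
  # grow-by-doubling record buffers
  cap <- 1024L
  ts <- numeric(cap); W <- matrix(0, cap, ensemble$n)
  TH <- numeric(cap); K <- integer(cap)
  np <- 1L
  ts[1L] <- 0; W[1L, ] <- w; TH[1L] <- th; K[1L] <- k
  unbounded <- FALSE

  while (t < T) {
    dt <- min(stats::rexp(1L, lam), T - t)
    x <- X[k, ]
    nst <- max(1L, ceiling(dt / hmax)); h <- dt / nst
    for (i in seq_len(nst)) {
      # RK4 on (w, theta) with the active stimulus held fixed
      v1 <- sum(w * x)
      k1w <- v1 * x * (v1 - th) / tau_w; k1t <- (v1^2 - th) / tau_theta
      w2 <- w + h / 2 * k1w; t2 <- th + h / 2 * k1t; v2 <- sum(w2 * x)
      k2w <- v2 * x * (v2 - t2) / tau_w; k2t <- (v2^2 - t2) / tau_theta
      w3 <- w + h / 2 * k2w; t3 <- th + h / 2 * k2t; v3 <- sum(w3 * x)
      k3w <- v3 * x * (v3 - t3) / tau_w; k3t <- (v3^2 - t3) / tau_theta
      w4 <- w + h * k3w; t4 <- th + h * k3t; v4 <- sum(w4 * x)
      k4w <- v4 * x * (v4 - t4) / tau_w; k4t <- (v4^2 - t4) / tau_theta
      w <- w + h / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
      th <- th + h / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    }
    t <- t + dt
    k <- sample.int(m, 1L, prob = probs)
    if (np == cap) {
      cap <- cap * 2L
      ts <- c(ts, numeric(cap / 2L)); TH <- c(TH, numeric(cap / 2L))
      K <- c(K, integer(cap / 2L)); W <- rbind(W, matrix(0, cap / 2L, ensemble$n))
    }
    np <- np + 1L
    ts[np] <- t; W[np, ] <- w; TH[np] <- th; K[np] <- k
    if (max(abs(c(w, th))) > blowup) { unbounded <- TRUE; break }
  }
  idx <- seq_len(np)
  Wm <- W[idx, , drop = FALSE]
  structure(
    list(t = ts[idx], w = Wm, theta = TH[idx], stimulus = K[idx],
         v = Wm %*% t(X), seed = process$seed, rate = lam, probs = probs,
         unbounded = unbounded, ensemble = ensemble, rule = rule),
    class = "bcm_hybrid"
  )
}

#' Empirical stimulus occupancy of a hybrid trajectory
#'
#' Time-weighted fraction of the run during which each stimulus was active.
#'
#' @param trajectory a `bcm_hybrid` from [simulate_switching()].
#' @return Numeric vector of fractions, one per stimulus, summing to 1.
#' @export
occupancy <- function(trajectory) {
  stopifnot(inherits(trajectory, "bcm_hybrid"))
  t <- trajectory$t
  if (length(t) < 2L) stop("trajectory has no switching intervals")
  dt <- diff(t)
  k <- trajectory$stimulus[-length(t)]
  m <- ncol(trajectory$v)
  out <- vapply(seq_len(m), function(j) sum(dt[k == j]), numeric(1))
  out / sum(out)
}

#' Late-time selectivity summary
#'
#' Judges selectivity from the oscillation ranges of the per-stimulus
#' responses over a trailing window, after discarding the transient. The
#' neuron is called selective when the dominant response is high (mean above
#' `high_min`, on the response scale 1/p of the selective fixed points) and
#' its range is separated from every other response's range by more than
#' `gap_min`. It is called steady when the dominant response's range is
#' narrower than `steady_width`; otherwise it oscillates.
#'
#' @param trajectory a `bcm_hybrid` or `bcm_trajectory`.
#' @param window fraction of the run to keep, counted from the end
#'   (default 0.5: discard the first half as transient).
#' @param gap_min minimal gap between response ranges to call them disjoint.
#' @param high_min minimal mean of the dominant response.
#' @param steady_width range width below which the dominant response counts
#'   as steady rather than oscillating.
#' @return A list with `means`, `ranges` (2 x m matrix), `selective`,
#'   `steady`, `dominant` (index) and `label` (one of
#'   "selective-steady", "selective-oscillation", "non-selective").
#' @export
selectivity_summary <- function(trajectory, window = 0.5, gap_min = 0.1,
                                high_min = 1, steady_width = 1) {
  if (inherits(trajectory, "bcm_hybrid")) {
    t <- trajectory$t; V <- trajectory$v
  } else if (inherits(trajectory, "bcm_trajectory")) {
    t <- trajectory$t
    V <- as.matrix(trajectory[, grep("^v", names(trajectory)), drop = FALSE])
  } else stop("unsupported trajectory object")
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  keep <- t >= (1 - window) * max(t)
  if (sum(keep) < 2L) stop("selectivity window is empty")
  V <- V[keep, , drop = FALSE]
  means <- colMeans(V)
  ranges <- apply(V, 2, range)
  dom <- which.max(means)
  others <- setdiff(seq_len(ncol(V)), dom)
  gap <- if (length(others)) min(ranges[1, dom] - ranges[2, others]) else Inf
  selective <- means[dom] >= high_min && gap > gap_min
  steady <- (ranges[2, dom] - ranges[1, dom]) < steady_width
  label <- if (!selective) "non-selective"
           else if (steady) "selective-steady" else "selective-oscillation"
  list(means = means, ranges = ranges, selective = selective, steady = steady,
       dominant = dom, gap = gap, label = label)
}

#' @export
print.bcm_hybrid <- function(x, ...) {
  cat("Hybrid BCM trajectory:", length(x$t), "switch events over",
      format(max(x$t), digits = 5), "time units; rate =", x$rate,
      "; seed =", x$seed, "\n")
  if (x$unbounded) cat("  [flagged unbounded]\n")
  invisible(x)
}
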