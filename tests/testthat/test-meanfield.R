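test_that("the four two-stimulus fixed points annihilate the mean-field rhs", {
  set.seed(31)
  for (i in 1:50) {
    p <- random_abc()
    ens <- ensemble_from_abc(p$a, p$b, p$c)
    rule <- bcm_rule(1, runif(1, 0.2, 3))
    fps <- fixed_points_two_stimuli(ens$probs[1])
    for (fp in fps) {
      d <- meanfield_rhs(fp[1:2], fp[3], ens, rule)
      expect_lt(max(abs(c(d$dv, d$dtheta))), 1e-12)
    }
  }
})

test_that("response-space rhs equals the pushforward of the weight-space rhs", {
  set.seed(32)
  for (i in 1:20) {
    ens <- stimulus_ensemble(list(rnorm(2), rnorm(2)),
                             probs = { p <- runif(1, 0.2, 0.8); c(p, 1 - p) })
    rule <- bcm_rule(runif(1, 0.5, 3), runif(1, 0.5, 3))
    w <- rnorm(2); th <- runif(1, 0, 2)
    v <- as.vector(ens$X %*% w)
    # averaged weight equation assembled from the per-stimulus rule
    d1 <- weight_rhs(w, th, ens$X[1, ], rule)
    d2 <- weight_rhs(w, th, ens$X[2, ], rule)
    dw <- ens$probs[1] * d1$dw + ens$probs[2] * d2$dw
    dv_expected <- as.vector(ens$X %*% dw)
    d <- meanfield_rhs(v, th, ens, rule)
    expect_equal(d$dv, dv_expected, tolerance = 1e-12)
    expect_equal(d$dtheta,
                 ens$probs[1] * d1$dtheta + ens$probs[2] * d2$dtheta,
                 tolerance = 1e-12)
  }
})

test_that("weight rhs vanishes when the response sits at threshold or at zero", {
  rule <- bcm_rule(2, 1)
  x <- c(0.6, 0.8)
  w <- c(1, 1)
  th <- sum(w * x)               # v = theta
  expect_equal(weight_rhs(w, th, x, rule)$dw, c(0, 0))
  d0 <- weight_rhs(c(0, 0), 0.7, x, rule)
  expect_equal(d0$dw, c(0, 0))
  expect_equal(d0$dtheta, -0.7 / rule$tau_theta)
  expect_error(weight_rhs(c(1, 2, 3), 1, x, rule), "dimension")
})

test_that("an Euler step of the weight flow converges at first order", {
  rule <- bcm_rule(1, 1)
  x <- c(0.3, -1.1)
  y0 <- c(0.4, -0.2, 0.5)
  flow_err <- function(h) {
    sys <- bcm_meanfield_weights(stimulus_ensemble(list(x, c(1, 0.2))), rule)
    tr <- integrate_system(sys, y0, c(0, h), rtol = 1e-12, atol = 1e-14)
    exact <- as.numeric(tr[nrow(tr), -1])
    d <- sys$rhs(y0)
    sqrt(sum((y0 + h * d - exact)^2))
  }
  e1 <- flow_err(0.02); e2 <- flow_err(0.01)
  # halving the step cuts the local Euler error about 4x (O(h^2) local)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("the response dynamics depend on stimuli only through the gram data", {
  set.seed(33)
  for (i in 1:10) {
    X <- matrix(rnorm(6), 3, 2)
    R <- rot2(runif(1, 0, 2 * pi))
    probs <- { p <- runif(3); p / sum(p) }
    e1 <- stimulus_ensemble(X, probs)
    e2 <- stimulus_ensemble(X %*% R, probs)
    rule <- bcm_rule(1, 1.3)
    y <- c(rnorm(3), runif(1))
    expect_equal(bcm_meanfield(e1, rule)$rhs(y),
                 bcm_meanfield(e2, rule)$rhs(y), tolerance = 1e-10)
  }
})

test_that("null-space functionals are conserved along mean-field trajectories", {
  set.seed(34)
  X <- matrix(rnorm(10), 5, 2)
  probs <- { p <- runif(5); p / sum(p) }
  ens <- stimulus_ensemble(X, probs)
  sys <- bcm_meanfield(ens, bcm_rule(1, 1.2))
  q <- conserved_basis(ens)
  y0 <- c(rnorm(5, sd = 0.5), 0.2)
  tr <- integrate_system(sys, y0, 100, dt = 0.5, rtol = 1e-9, atol = 1e-12)
  V <- as.matrix(tr[, 2:6])
  for (j in seq_len(ncol(q))) {
    drift <- max(abs(V %*% q[, j] - sum(y0[1:5] * q[, j])))
    expect_lt(drift, 1e-6)
  }
})

test_that("the origin repels the expanding cone of small responses", {
  # center-manifold instability: for b >= 0, small states with nonnegative
  # responses leave a 1e-2 ball (the origin does keep stable directions,
  # so signed perturbations need not escape)
  set.seed(35)
  p <- random_abc(); p$b <- abs(p$b)
  ens <- ensemble_from_abc(p$a, p$b, p$c)
  sys <- bcm_meanfield(ens, bcm_rule(1, 0.8))
  escaped <- logical(20)
  for (i in seq_along(escaped)) {
    u <- abs(rnorm(3)); u <- u / sqrt(sum(u^2)) * 1e-3
    f <- function(t, y, pp) list(sys$rhs(y))
    root <- function(t, y, pp) sqrt(sum(y^2)) - 1e-2
    sol <- deSolve::ode(u, c(0, 5e4), f, NULL, method = "lsodar",
                        rtol = 1e-10, atol = 1e-14, rootfun = root,
                        maxsteps = 100000)
    escaped[i] <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot"))
  }
  expect_true(all(escaped))
})

test_that("three-stimulus reduction is consistent with the full system", {
  al <- 0.92; be <- 2.5
  sys <- reduce_three_stimuli(al, be, C = 1, tau = 1.2)
  # gram entries of the reduction
  expect_equal(sys$gram3[1, 2], cos(al))
  expect_equal(sys$gram3[1, 3], cos(be))
  expect_equal(sys$gram3[2, 3], cos(al - be))
  # lifted trajectory stays on the constraint plane
  tr <- integrate_system(sys, c(1.1, 0.8, 0.6), 50, dt = 0.1,
                         rtol = 1e-10, atol = 1e-12)
  e <- sys$e
  lifted <- t(apply(as.matrix(tr[, 2:4]), 1, sys$lift))
  expect_lt(max(abs(lifted[, 1:3] %*% e - 1)), 1e-8)
  # the full 3-response mean field from consistent data matches the
  # reduced integration after projection
  X <- rbind(c(1, 0), c(cos(al), sin(al)), c(cos(be), sin(be)))
  full <- bcm_meanfield(stimulus_ensemble(X), bcm_rule(1, 1.2))
  y0full <- sys$lift(c(1.1, 0.8, 0.6))
  y0full <- c(y0full[1:3], y0full[4])
  trf <- integrate_system(full, y0full, 50, dt = 0.1,
                          rtol = 1e-10, atol = 1e-12)
  expect_equal(as.matrix(tr[, c("v1", "v2", "theta")]),
               as.matrix(trf[, c("v1", "v2", "theta")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  # degenerate elimination is refused
  expect_error(reduce_three_stimuli(pi, 2.5, C = 1), "eliminate")
})

test_that("integration flags finite-time blow-up at large tau", {
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
  sys <- bcm_meanfield(ens, bcm_rule(1, 5))
  tr <- integrate_system(sys, c(3, 0.5, 0.2), 200)
  expect_true(attr(tr, "unbounded"))
  expect_lt(max(tr$t), 200)
})
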