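test_that("numeric jacobian is exact on linear maps and second order otherwise", {
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  expect_equal(numeric_jacobian(function(x) as.vector(A %*% x), c(0.3, -1)),
               A, tolerance = 1e-10)
  # cubic test function with known derivative: halving the step cuts the
  # error about 4x
  f <- function(x) c(x[1]^3, x[1] * x[2]^2)
  Jexact <- function(x) matrix(c(3 * x[1]^2, x[2]^2, 0, 2 * x[1] * x[2]), 2, 2)
  x <- c(0.7, 1.3)
  e1 <- max(abs(numeric_jacobian(f, x, step = 0.1) - Jexact(x)))
  e2 <- max(abs(numeric_jacobian(f, x, step = 0.05) - Jexact(x)))
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)
  expect_error(numeric_jacobian(function(x) c(NaN, 1), c(1, 1)), "finite")
})

test_that("multi-start search recovers exactly the four two-stimulus equilibria", {
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
  sys <- bcm_meanfield(ens, bcm_rule(1, 0.9))
  eq <- find_equilibria(sys, rep(-1, 3), rep(3, 3), n_starts = 250, seed = 2)
  expect_equal(nrow(eq), 4L)
  fps <- fixed_points_two_stimuli(0.5)
  for (fp in fps) {
    d <- apply(eq, 1, function(r) sqrt(sum((r - fp)^2)))
    expect_lt(min(d), 1e-7)
  }
})

test_that("equilibrium counts of the reduced system track the isola", {
  expect_equal(nrow(reduced_equilibria(0.92, 2.5, -5)), 1L)
  expect_equal(nrow(reduced_equilibria(0.92, 2.5, 1)), 3L)
  expect_equal(nrow(reduced_equilibria(0.92, 2.5, 5)), 1L)
})

test_that("hopf bisection agrees with the closed form for the standard case", {
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
  mk <- function(tau) bcm_meanfield(ens, bcm_rule(1, tau))$rhs
  hb <- hopf_bisect(mk, c(2.01, 0.01, 1.99), c(1.2, 1.6))
  expect_equal(hb$parameter, 1 / (1 - cos(1)^2), tolerance = 1e-6)
  expect_gt(max(abs(Im(hb$eigenvalues))), 0.1)
  expect_error(hopf_bisect(mk, c(2.01, 0.01, 1.99), c(0.2, 0.6)),
               "does not change sign")
})

test_that("limit-cycle location respects invariant sets and the Hopf onset", {
  # orthogonal stimuli: v2 = 0 is invariant, the cycle lives in the
  # (v1, theta) plane
  ensA <- stimulus_ensemble(list(c(1, 0), c(0, 1)))
  sysA <- bcm_meanfield(ensA, bcm_rule(1, 1.1))
  cyc <- find_limit_cycle(sysA, c(0.1, 0, 0), transient = 300,
                          t_observe = 100, max_period = 50)
  expect_false(is.null(cyc))
  expect_lt(max(abs(cyc$samples[, 3])), 1e-8)
  # below the Hopf the trajectory spirals into the focus: no cycle
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
  sysF <- bcm_meanfield(ens, bcm_rule(1, 1.3))
  expect_null(find_limit_cycle(sysF, c(2.05, 0.02, 2), transient = 600,
                               t_observe = 100, max_period = 50))
  expect_match(last_cycle_diagnostic(), "equilibrium")
  # square-root amplitude growth just above the Hopf
  tc <- 1 / (1 - cos(1)^2)
  mk <- function(tau) bcm_meanfield(ens, bcm_rule(1, tau))$rhs
  amp <- sapply(c(0.02, 0.08), function(d) {
    cyc <- find_limit_cycle(mk(tc + d), c(2.05, 0.02, 2), transient = 600,
                            t_observe = 100, max_period = 60)
    diff(range(cyc$samples[, 2]))
  })
  expo <- log(amp[2] / amp[1]) / log(4)
  expect_gt(expo, 0.4)
  expect_lt(expo, 0.6)
})

test_that("floquet multipliers certify cycle stability", {
  ensA <- stimulus_ensemble(list(c(1, 0), c(0, 1)))
  sysA <- bcm_meanfield(ensA, bcm_rule(1, 1.1))
  cyc <- find_limit_cycle(sysA, c(0.1, 0, 0), transient = 300,
                          t_observe = 100, max_period = 50)
  cyc <- floquet_multipliers(sysA, cyc)
  mu <- cyc$floquet
  expect_lt(min(Mod(mu - 1)), 1e-3)           # trivial multiplier
  expect_true(all(Mod(mu[-which.min(Mod(mu - 1))]) < 1))
  expect_true(cyc$stable)
})

test_that("continued cycles match freshly found cycles near the Hopf", {
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
  mk <- function(tau) bcm_meanfield(ens, bcm_rule(1, tau))$rhs
  br <- continue_cycle(mk, c(1.5, 1.55, 1.6), y0 = c(2.05, 0.02, 2),
                       transient = 500, t_observe = 120, max_period = 60,
                       refine_end = FALSE)
  expect_equal(nrow(br$branch), 3L)
  fresh <- find_limit_cycle(mk(1.6), c(2.05, 0.02, 2), transient = 500,
                            t_observe = 120, max_period = 60)
  expect_equal(br$branch$period[3], fresh$period, tolerance = 1e-5)
})

test_that("poincare sections interpolate crossings and expose period doubling", {
  # synthetic sinusoid: crossings at known phases
  t <- seq(0, 20, by = 0.01)
  tr <- cbind(t = t, a = sin(t), b = cos(t))
  cr <- poincare_section(tr, 1, 0, "increasing")
  expect_equal(nrow(cr), 3L)           # upward zero crossings of sin on (0,20]
  expect_equal(cr[, "b"], rep(1, 3), tolerance = 1e-4)
  # period-1 attractor of the reduced system: crossing states agree
  sys1 <- reduce_three_stimuli(0.92, 2.5, C = 0.15, tau = 1.6)
  tr1 <- integrate_system(sys1, c(1.05, 0.95, 0.9), seq(0, 1400, by = 0.02),
                          rtol = 1e-9, atol = 1e-11)
  cr1 <- poincare_section(tr1[tr1$t > 1200, ], 2, 2, "increasing")
  th1 <- cr1[, "theta"]
  expect_gt(length(th1), 5)
  expect_lt(diff(range(tail(th1, 4))), 1e-4)
  # past the period doubling: two alternating crossing values
  sys2 <- reduce_three_stimuli(0.92, 2.5, C = 0.185, tau = 1.6)
  tr2 <- integrate_system(sys2, c(1.05, 0.95, 0.9), seq(0, 1400, by = 0.02),
                          rtol = 1e-9, atol = 1e-11)
  th2 <- poincare_section(tr2[tr2$t > 1000, ], 2, 2, "increasing")[, "theta"]
  n <- length(th2)
  expect_gt(abs(th2[n] - th2[n - 1]), 1e-2)
  expect_lt(abs(th2[n] - th2[n - 2]), 1e-3)
})

test_that("lyapunov exponents separate equilibria, cycles and chaos", {
  # stable equilibrium: strongly negative
  sysE <- reduce_three_stimuli(0.92, 2.5, C = -5, tau = 1)
  lyE <- max_lyapunov(sysE, c(0.5, 0.5, 0.5), transient = 200, nseg = 150,
                      dt = 2)
  expect_lt(lyE$lambda, -0.1)
  # stable limit cycle: zero within noise
  sysA <- bcm_meanfield(stimulus_ensemble(list(c(1, 0), c(0, 1))),
                        bcm_rule(1, 1.1))
  lyC <- max_lyapunov(sysA, c(0.1, 0, 0), transient = 300, nseg = 400, dt = 2)
  expect_lt(abs(lyC$lambda), max(2 * lyC$se, 0.02))
})

test_that("relative selectivity is normalized and decays past the Hopf", {
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
  rs <- relative_selectivity(ens, c(0.5, 1.0, 1.9, 2.5))
  expect_true(all(rs$rs >= 0 & rs$rs <= 1, na.rm = TRUE))
  expect_equal(max(rs$rs, na.rm = TRUE), 1)
  # flat at the maximum below the critical ratio (1.412), decaying beyond
  expect_equal(rs$rs[1], 1, tolerance = 1e-6)
  expect_equal(rs$rs[2], 1, tolerance = 1e-6)
  expect_lt(rs$rs[3], 0.5)
  expect_gt(rs$rs[3], rs$rs[4])
  # identical responses give zero gap hence zero RS
  ensS <- stimulus_ensemble(list(c(1, 0), c(0, 1)))
  rsS <- relative_selectivity(ensS, c(0.5, 1.1), y0 = c(1.2, 1.2, 0.8))
  expect_equal(rsS$d[1], 0, tolerance = 1e-8)
})
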