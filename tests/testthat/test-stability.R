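test_that("closed-form characteristic coefficients match the numeric Jacobian", {
  set.seed(41)
  for (i in 1:100) {
    p <- random_abc()
    tau <- runif(1, 0.2, 3)
    prm <- two_stimulus_params(p$a, p$b, p$c)
    ens <- ensemble_from_abc(p$a, p$b, p$c)
    sys <- bcm_meanfield(ens, bcm_rule(1, tau))
    fps <- fixed_points_two_stimuli(ens$probs[1])
    A1 <- charpoly3(numeric_jacobian(sys$rhs, fps$z1))
    expect_equal(unname(A1), unname(charpoly_z1(prm, tau)), tolerance = 1e-7)
    A2 <- charpoly3(numeric_jacobian(sys$rhs, fps$z2))
    expect_equal(unname(A2), unname(charpoly_z2(prm, tau)), tolerance = 1e-7)
    # the constant coefficient never vanishes: no steady-state bifurcation
    expect_gt(A1[["A0"]], 0)
    expect_gt(A2[["A0"]], 0)
  }
  # analytic Jacobian at z1 agrees row by row with the numeric one
  p <- list(a = 1.3, b = 0.7, c = 1.8); tau <- 0.9
  ens <- ensemble_from_abc(p$a, p$b, p$c)
  sys <- bcm_meanfield(ens, bcm_rule(1, tau))
  Jn <- numeric_jacobian(sys$rhs, fixed_points_two_stimuli(ens$probs[1])$z1)
  expect_equal(Jn, analytic_J_z1(p$a, p$b, p$c, tau), tolerance = 1e-6)
})

test_that("special-case coefficients simplify as expected when a = c = 1", {
  tau <- 0.7
  A <- charpoly_z1(two_stimulus_params(1, 0.4, 1), tau)
  expect_equal(A[["A2"]], 1 / tau)
  expect_equal(A[["A0"]], (1 - 0.4^2) / tau)
})

test_that("Hopf thresholds solve the residual quadratics", {
  # standard case reduces to 1/(1 - b^2)
  expect_equal(hopf_tau_z1(1, cos(1), 1), 1 / (1 - cos(1)^2), tolerance = 1e-12)
  expect_equal(hopf_tau_z2(1, cos(1), 1), 1 / (1 - cos(1)^2), tolerance = 1e-12)
  expect_equal(hopf_tau_z1(1, 0, 1), 1)
  # unequal amplitudes: independent quadratic-formula oracle
  a <- 2.25; b <- 1.5 * cos(1); cc <- 1
  q2 <- cc * (a - b^2) * (1 - a * cc)
  q1 <- -(1 + 2 * a * cc - a^2 * cc^2 - 2 * b^2 * cc)
  q0 <- 1 + a * cc
  r1 <- min((-q1 + c(-1, 1) * sqrt(q1^2 - 4 * q2 * q0)) / (2 * q2))
  # (leading coefficient is negative here: the smaller root is the +/- one)
  roots1 <- sort((-q1 + c(-1, 1) * sqrt(q1^2 - 4 * q2 * q0)) / (2 * q2))
  roots1 <- roots1[roots1 > 0]
  expect_equal(hopf_tau_z1(a, b, cc), min(roots1), tolerance = 1e-10)
  p2 <- cc * (a - b^2) * (a - cc)
  p1 <- 2 * cc * (b^2 - a) + cc^2 - a^2
  p0 <- a + cc
  roots2 <- sort((-p1 + c(-1, 1) * sqrt(p1^2 - 4 * p2 * p0)) / (2 * p2))
  expect_equal(hopf_tau_z2(a, b, cc), min(roots2[roots2 > 0]),
               tolerance = 1e-10)
  # degenerate linear case: the tau^2 coefficient vanishes when a = c
  tz1 <- hopf_tau_z1(2, 0.5, 2)
  tz2 <- hopf_tau_z2(2, 0.5, 2)
  for (ex in list(list(t = tz1, which = "z1", a = 2, b = 0.5, cc = 2),
                  list(t = tz2, which = "z2", a = 2, b = 0.5, cc = 2))) {
    ens <- ensemble_from_abc(ex$a, ex$b, ex$cc)
    fp <- fixed_points_two_stimuli(ens$probs[1])[[ex$which]]
    re_at <- function(tt) {
      sys <- bcm_meanfield(ens, bcm_rule(1, tt))
      ev <- eigen(numeric_jacobian(sys$rhs, fp), only.values = TRUE)$values
      max(Re(ev[abs(Im(ev)) > 1e-8]))
    }
    expect_lt(re_at(ex$t * 0.98), 0)
    expect_gt(re_at(ex$t * 1.02), 0)
  }
})

test_that("Routh-Hurwitz verdicts agree with numeric eigenvalues", {
  set.seed(43)
  checked <- 0L
  for (i in 1:200) {
    p <- random_abc()
    tau <- runif(1, 0.1, 4)
    ens <- ensemble_from_abc(p$a, p$b, p$c)
    sys <- bcm_meanfield(ens, bcm_rule(1, tau))
    fps <- fixed_points_two_stimuli(ens$probs[1])
    for (which in c("z1", "z2")) {
      mre <- max_re_eig(sys$rhs, fps[[which]])
      if (abs(mre) < 1e-6) next        # too close to the boundary to call
      expect_identical(selective_equilibrium_stable(which, p$a, p$b, p$c, tau),
                       mre < 0)
      checked <- checked + 1L
    }
    # stability always holds as tau -> 0+
    expect_true(selective_equilibrium_stable("z1", p$a, p$b, p$c, 1e-3))
    expect_true(selective_equilibrium_stable("z2", p$a, p$b, p$c, 1e-3))
  }
  expect_gt(checked, 300)
  # equal amplitudes, equal probabilities: both stable iff tau < 1/(1-b^2)
  b <- cos(1)
  expect_true(selective_equilibrium_stable("z1", 1, b, 1, 1.3))
  expect_true(selective_equilibrium_stable("z2", 1, b, 1, 1.3))
  expect_false(selective_equilibrium_stable("z1", 1, b, 1, 1.5))
})

test_that("stability report flags the non-selective equilibria as unstable", {
  rep <- stability_report(1, cos(1), 1, tau = 1.0)
  expect_false(rep$origin$stable)
  expect_false(rep$symmetric$stable)
  expect_true(rep$z1$stable)
  expect_equal(rep$z1$hopf_tau, 1 / (1 - cos(1)^2), tolerance = 1e-10)
})

test_that("network Hopf thresholds obey the closed forms", {
  al <- 0.7709
  # decoupled network recovers the single-neuron threshold
  t0 <- network_hopf_taus(0, al)
  expect_equal(unname(t0["sym"]), 1 / (1 - cos(al)^2), tolerance = 1e-12)
  expect_equal(unname(t0["sym"]), unname(t0["anti"]))
  # the symmetric threshold is linear in gamma with negative slope
  g <- c(0.1, 0.3, 0.5)
  ts <- sapply(g, function(gg) network_hopf_taus(gg, al)["sym"])
  expect_equal(diff(ts, differences = 2), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(diff(ts)[1], 0)
  # acute angles: the symmetric equilibrium destabilizes first
  expect_lt(network_hopf_taus(0.25, al)["sym"],
            network_hopf_taus(0.25, al)["anti"])
  expect_error(network_hopf_taus(0.25, 0), "alpha")
  expect_error(network_hopf_taus(1.2, al), "gamma")
})

test_that("network Hopf thresholds match bisection on the 6x6 spectrum", {
  al <- 0.7709; gam <- 0.25
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(al), sin(al))))
  make_net <- function(tau) {
    bcm_network(network_params(gam, ens, bcm_rule(1, tau)))$rhs
  }
  taus <- network_hopf_taus(gam, al)
  hb_sym <- hopf_bisect(make_net, c(2, 0, 2, 2, 0, 2) + 1e-9,
                        unname(taus["sym"]) + c(-0.3, 0.3))
  expect_equal(hb_sym$parameter, unname(taus["sym"]), tolerance = 1e-4)
  hb_anti <- hopf_bisect(make_net, c(2, 0, 2, 0, 2, 2) + 1e-9,
                         unname(taus["anti"]) + c(-0.3, 0.3))
  expect_equal(hb_anti$parameter, unname(taus["anti"]), tolerance = 1e-4)
})

test_that("the block factorization carries the full network spectrum", {
  set.seed(44)
  for (i in 1:50) {
    gam <- runif(1, 0.05, 0.9)
    al <- runif(1, 0.3, 2.8)
    tau <- runif(1, 0.3, 3)
    bs <- block_eigen_split(gam, al, tau)
    u <- c(bs$eigen1, bs$eigen2)
    expect_equal(sort(Re(u)), sort(Re(bs$eigen_full)), tolerance = 1e-8)
    expect_equal(sort(abs(Im(u))), sort(abs(Im(bs$eigen_full))),
                 tolerance = 1e-8)
  }
  # gamma = 0: the two blocks coincide
  bs <- block_eigen_split(0, 1, 1.2)
  expect_equal(bs$M1, bs$M2)
  # between the two block thresholds only the symmetry-breaking block is
  # unstable
  al <- 0.7709; gam <- 0.3
  s2 <- 1 - cos(al)^2
  a1 <- (1 - gam) / ((1 - gam^2))    # g - h
  tau_mid <- 0.5 * (network_hopf_taus(gam, al)["sym"] + 1 / (a1 * s2))
  bs <- block_eigen_split(gam, al, unname(tau_mid))
  expect_gt(max(Re(bs$eigen2)), 0)
  expect_lt(max(Re(bs$eigen1)), 0)
})

test_that("partially selective network equilibria are saddles", {
  set.seed(45)
  for (i in 1:100) {
    gam <- runif(1, 0.02, 0.9)
    al <- runif(1, 0.2, 2.9)
    tau <- runif(1, 0.2, 3)
    r <- partial_equilibrium_is_saddle(gam, al, tau)
    expect_lt(r$a0, 0)
    expect_true(r$saddle)
  }
  # a0 equals the determinant of the numeric 6x6 Jacobian at (1,1,1,2,0,2)
  gam <- 0.3; al <- 0.7709; tau <- 1.1
  ens <- stimulus_ensemble(list(c(1, 0), c(cos(al), sin(al))))
  rhs <- bcm_network(network_params(gam, ens, bcm_rule(1, tau)))$rhs
  J <- numeric_jacobian(rhs, c(1, 1, 1, 2, 0, 2))
  expect_equal(det(J), partial_equilibrium_is_saddle(gam, al, tau)$a0,
               tolerance = 1e-6)
  # gamma = 0 reduces to the single-neuron product form
  r0 <- partial_equilibrium_is_saddle(0, al, tau)
  expect_equal(r0$a0, -(1 - cos(al)^2)^2 / (4 * tau^2), tolerance = 1e-12)
})

test_that("lateral-inhibition steady state matches a direct linear solve", {
  s <- c(1.2, 0.4)
  gam <- 0.3
  v <- inhibition_steady_state(s, gam)
  expect_equal(v[1], (s[1] - gam * s[2]) / (1 - gam^2), tolerance = 1e-12)
  expect_equal(inhibition_steady_state(s, 0), s)
  set.seed(46)
  s <- rnorm(7)
  G <- matrix(0.3, 7, 7); diag(G) <- 1
  expect_equal(inhibition_steady_state(s, 0.3), solve(G, s),
               tolerance = 1e-10)
  expect_error(inhibition_steady_state(s, 1), "singular")
  expect_error(inhibition_steady_state(s, -1 / 6), "singular")
})

test_that("the fast relaxation to the inhibition steady state is stable", {
  # jacobian of dv/dt = -v + s - gamma * sum_{j != i} v_j has eigenvalues
  # gamma - 1 (N-1 times) and -(1 + (N-1) gamma)
  for (N in c(2, 5, 9)) {
    gam <- 0.35
    M <- matrix(-gam, N, N); diag(M) <- -1
    ev <- sort(eigen(M, only.values = TRUE)$values)
    expect_equal(ev[1], -(1 + (N - 1) * gam), tolerance = 1e-12)
    expect_equal(ev[-1], rep(gam - 1, N - 1), tolerance = 1e-12)
    expect_true(all(ev < 0))
  }
})
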