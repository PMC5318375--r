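# bcmdyn

Dynamical-systems analysis of the Bienenstock–Cooper–Munro (BCM) rule for
synaptic plasticity, for computational neuroscientists and applied
dynamicists who want the rule's oscillatory and chaotic regimes — not just
its classical selective fixed points — as runnable, testable code.

The BCM rule couples Hebbian weight modification to a sliding homeostatic
threshold:

    tau_w  dw/dt     = v x (v - theta),      v = w . x
    tau_th dtheta/dt = v^2 - theta

where `x` is the current input pattern, `v` the linear response and
`theta` a low-pass filter of `v^2`. When patterns from a finite ensemble
`{x^(k)}` with probabilities `p_k` switch rapidly (a Markov jump process),
the rule averages to a deterministic system for the responses
`v_k = w . x^(k)`:

    tau_w  dv_k/dt     = sum_l p_l (x^(k) . x^(l)) v_l (v_l - theta)
    tau_th dtheta/dt   = sum_l p_l v_l^2 - theta

Everything in the phase portrait hinges on the time-scale ratio
`tau = tau_th / tau_w`. For fast homeostasis (small `tau`) the selective
states `v_k = 1/p_k` are stable; as `tau` grows they lose stability
through Hopf bifurcations whose thresholds are known in closed form
(Routh–Hurwitz), and beyond them the package tracks limit cycles, folds,
period doublings (Floquet multipliers), Poincaré sections, homoclinic
candidates, chaos (maximal Lyapunov exponents), conserved quantities when
stimuli outnumber weights, and the symmetry-breaking bifurcations of a
two-neuron laterally inhibited network.

The package provides, per module:

* `simulate_switching()` — event-exact hybrid simulation of the unaveraged
  rule with Markov stimulus switching; `occupancy()`,
  `selectivity_summary()`.
* `bcm_meanfield()`, `reduce_three_stimuli()`, `conserved_basis()` — the
  averaged systems and the constraint reduction when `m > n`.
* `hopf_tau_z1()`, `hopf_tau_z2()`, `selective_equilibrium_stable()`,
  `network_hopf_taus()`, `block_eigen_split()`,
  `inhibition_steady_state()` — closed-form stability theory.
* `find_equilibria()`, `hopf_bisect()`, `find_limit_cycle()`,
  `floquet_multipliers()`, `continue_cycle()`, `poincare_section()`,
  `max_lyapunov()`, `isola_bounds()`, `reduced_min_hopf_tau()`,
  `reduced_period_doubling_C()`, `relative_selectivity()` — numerics.
* `load_preset()` / `run_bcm()` — ready-made parameter sets for the worked
  scenarios, CSV/JSON outputs; `inst/scripts/bcm` is a thin command-line
  front end (`presets`, `simulate`, `stability`, `bifurcate`, `lyapunov`).

## A worked example

Two unit stimuli at angle 1 presented with equal probability:

```r
library(bcmdyn)
ens <- stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
stability_report(1, cos(1), 1, tau = 1.2)
#> Stability report (a = 1, b = 0.540302, c = 1, tau = 1.2)
#>  origin     stable: FALSE
#>  z1         stable: TRUE   hopf tau: 1.41228
#>  z2         stable: TRUE   hopf tau: 1.41228
#>  symmetric  stable: FALSE
```

At `tau = 1.2` both selective equilibria (response 2 to the preferred
stimulus, 0 to the other) are stable; they destabilize at
`tau = 1/(1 - cos(1)^2) = 1.412`. Past the Hopf point a stable limit
cycle appears:

```r
sys <- bcm_meanfield(ens, bcm_rule(1, 1.6))
cyc <- floquet_multipliers(sys, find_limit_cycle(sys, c(2.05, 0.02, 2),
                                                 transient = 400))
cyc
#> Limit cycle: period 9.84992 (1 return-map iterate)
#>  Floquet multipliers: 0.9999997 0.3181657 0.0066641
```

The trivial multiplier sits at 1 and the others inside the unit circle:
the oscillation is attracting. The unaveraged stochastic rule reproduces
the fast-homeostasis selectivity:

```r
tr <- simulate_switching(ens, bcm_rule(25, 25 * 0.25),
                         switching_process(5, seed = 1),
                         w0 = c(0.1, 0.2), theta0 = 0.15, T = 4000)
s <- selectivity_summary(tr, window = 0.25)
s$label; round(s$means, 3)
#> [1] "selective-steady"
#> [1] 0.005 1.973
```

The neuron locked onto the second stimulus (mean response 1.973, the
other near 0) and holds it steadily. See the vignette
(`vignettes/bcm-dynamics.Rmd`) for the model assumptions, the
three-stimulus reduction with its conserved quantity, the network theory,
and every numerical convention (tolerances, section placement, chaos
criteria).

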