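---
title: "Dynamics of the BCM learning rule: models, stability theory and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of the BCM learning rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcmdyn)
```

## The model

The Bienenstock–Cooper–Munro (BCM) rule describes activity-dependent
synaptic modification for a linear neuron. With weights $w \in R^n$, an
input pattern $x$, response $v = w \cdot x$ and a sliding homeostatic
threshold $\theta$, the differential form of the rule is

$$\tau_w \,\dot w = v\, x\, (v - \theta), \qquad
  \tau_\theta \,\dot\theta = v^2 - \theta .$$

The nonlinearity $\phi(v;\theta) = v(v-\theta)$ depresses weights when the
response is below threshold and potentiates them above it, while $\theta$
low-pass filters the squared response. The exponent in the threshold
equation is fixed at 2 throughout this package. Two time scales enter:
$\tau_w$ for the weights and $\tau_\theta$ for homeostasis; for the
deterministic phase portrait only their ratio
$\tau = \tau_\theta/\tau_w$ matters. Time is treated as dimensionless — a
"second" in the stochastic examples is simply the unit in which the
switching rate and $\tau_w$ are quoted.

Stimuli arrive as a finite ensemble $\{x^{(k)}\}$ with presentation
probabilities $p_k$ (`stimulus_ensemble()`). When the presentation
process is fast compared with $\tau_w$ and $\tau_\theta$, averaging over
the stimulus process yields a closed deterministic system for the
responses $v_k = w \cdot x^{(k)}$:

$$\tau_w\, \dot v_k = \sum_l p_l\, G_{kl}\, v_l (v_l - \theta), \qquad
  \tau_\theta\, \dot\theta = \sum_l p_l v_l^2 - \theta,$$

with $G_{kl} = x^{(k)} \cdot x^{(l)}$ the Gram matrix. The response-space
form is the canonical representation here (`bcm_meanfield()`): it depends
on the stimuli only through $G$ and $p$, so rotating all stimuli together
changes nothing, and its fixed points depend only on the probabilities.
The weight-space form is kept (`bcm_meanfield_weights()`) solely as an
independent cross-check where the stimulus matrix is square and
invertible.

## The stochastic simulator

`simulate_switching()` implements the unaveraged rule as a hybrid
(piecewise-deterministic) process. The active stimulus is held for an
exponential time with the configured rate; at each event the next stimulus
is drawn independently from the presentation probabilities, which makes
the stationary occupancy equal to those probabilities for any ensemble
size (for two stimuli this is one of several Markov embeddings with the
right stationary law; we use the same independent-resampling embedding for
all $m$). The initial stimulus is drawn from the same law, and recorded
with the seed in the run metadata. Between switches the deterministic flow
is integrated with a fixed-step classical Runge–Kutta scheme whose step
never exceeds `hmax` (default 0.02 time units), restarting exactly at each
switching time so that the discontinuous forcing is handled event-exactly
rather than smuggled through an adaptive solver's error control. Runs are
bit-for-bit reproducible from the seed.

What this generator emulates is the idealized experiment in which a neuron
sees a rapid random stream drawn from a small fixed set of patterns; what
it does not emulate is anything about real sensory statistics — stimulus
correlations in time, drifting ensembles, input noise within a
presentation, or nonlinear transfer. Conclusions from passing tests are
therefore about the mathematical model, not about cortex.

The selectivity of a run is judged from the late-time per-stimulus
response ranges (`selectivity_summary()`), after discarding a transient
(default: the first half). The conventions, chosen once on the natural
response scale of the selective fixed points ($v = 1/p_k$, i.e. 2 for
equal probabilities): the neuron is *selective* when its dominant mean
response exceeds 1 and its range clears every other response's range by
more than 0.1; it is *steady* when the dominant range is narrower than 1
(half the fixed-point response), otherwise *oscillating*. These absolute
thresholds deliberately avoid relative measures, which misclassify the
collapsed near-zero states seen at large $\tau$ as "selective" merely
because tiny numbers are well separated.

## Stability theory for one neuron with two stimuli

After rescaling time so that $|x^{(1)}| = 1$, three numbers control the
linear algebra: $a = |x^{(2)}|^2$, $b = x^{(1)} \cdot x^{(2)}$ and the
probability ratio $c = \rho/(1-\rho)$. The four equilibria are the origin,
the symmetric state $(1,1,1)$ and the two selective states
$z_1 = (1/\rho, 0, 1/\rho)$, $z_2 = (0, 1/(1-\rho), 1/(1-\rho))$.

Differentiating the averaged equations at $z_2$ gives a cubic
characteristic polynomial with coefficients
$A_0 = c(a-b^2)/\tau$, $A_1 = (a+c)/\tau + c(b^2-a)$,
$A_2 = 1/\tau + c - a$; the same computation at $z_1$ yields the analogous
forms with the probability ratio inverted ($c \to 1/c$), the two agreeing
at equal probabilities. Both sets are verified against finite-difference
Jacobians on randomized draws in the test suite — worth stating because
it is easy to get the $z_1$ convention silently wrong by symmetry
arguments. Since $A_0 > 0$ whenever the stimuli are not collinear, no
branch of equilibria can bifurcate: stability can only be lost through a
Hopf bifurcation, located where the Routh–Hurwitz residual
$A_1 A_2 - A_0$ first crosses zero. Multiplying the residual by $\tau^2$
gives a quadratic in $\tau$; `hopf_tau_z1()`/`hopf_tau_z2()` return its
smallest positive downward crossing, handling the degenerate linear case
$a = c$ where the leading coefficient vanishes. In the standard case
$a = c = 1$ the threshold collapses to $\tau_c = 1/(1-b^2)$, which is
1.412 for stimuli at angle 1. `selective_equilibrium_stable()` evaluates
the full Routh–Hurwitz set (all coefficients and the residual) rather
than the residual alone, because at large $\tau$ a coefficient itself can
turn negative while the residual is positive again; the residual is the
binding condition only near the first crossing.

The origin is a degenerate equilibrium (double zero eigenvalue): its
instability is a center-manifold statement, and the package asserts it
numerically as an escape property — trajectories started on small
nonnegative-response directions (the expanding cone, where the quadratic
terms are all of one sign for $b \ge 0$) leave a ball of radius $10^{-2}$
in finite time. Signed random directions are *not* claimed to escape: the
origin also has stable directions, and at large $\tau$ it attracts almost
everything even while being unstable. The symmetric state $(1,1,1)$ is
always unstable: the constant characteristic coefficient equals
$\rho(1-\rho)(b^2-a)/\tau < 0$.

## More stimuli than weights: conservation and the reduced system

With $m$ stimuli driving $n < m$ weights, the response vector is confined
to an $n$-dimensional affine subspace: any $q$ with $q^T X = 0$ gives a
conserved quantity $q \cdot v(t)$ (`conserved_basis()`, orthonormalized
via the SVD). For the worked three-stimulus planar case with stimuli
$(1,0)$, $(\cos\alpha, \sin\alpha)$, $(\cos\beta, \sin\beta)$ and equal
probabilities, the package uses the null vector scaled so its third entry
is $\sin^2\alpha$:

$$e = \big(\sin\alpha\,\sin(\beta-\alpha),\; -\sin\alpha\,\sin\beta,\;
  \sin^2\alpha\big),$$

which satisfies $e^T X = 0$ identically (the first coefficient is the one
that is easy to get wrong by a factor of $\cos\beta$; the test suite
checks the annihilation property directly). Eliminating
$v_3 = (C - e_1 v_1 - e_2 v_2)/e_3$ gives a three-dimensional system in
$(v_1, v_2, \theta)$ parameterized by $\tau$ and the conservation constant
$C$ (`reduce_three_stimuli()`), refused when $\sin\alpha \approx 0$.

At $\alpha = 0.92$, $\beta = 2.5$ this reduced system has a principal
equilibrium branch for all $C$ plus an *isola* — a closed loop of
additional equilibria over a bounded window of $C$. `isola_bounds()`
locates the window by bisection on the equilibrium count; the count comes
from warm-started multi-start Newton searches in $(v_1, v_2)$ with
$\theta$ eliminated at its equilibrium value. Two numerical subtleties are
handled explicitly. First, near a fold the two merging roots have shrinking
Newton basins, so the search is seeded with the roots found at neighboring
$C$ plus small perturbations. Second, close to $C = 0$ the degenerate
origin produces a cloud of spurious "roots" that all pass a residual test;
`find_equilibria()` therefore polishes every candidate with extra undamped
Newton sweeps (collapsing the cloud onto the true root) and the reduced
wrapper deduplicates at $10^{-4}$, far below the separation of genuine
roots at the bisection tolerance. Our two independent routes — count
bisection, and extrema of $e \cdot v$ along the pseudo-arclength-traced
loop — agree on the window to three decimals ($\approx 0.234$ to
$\approx 3.517$).

Hopf thresholds along the branches exploit structure instead of brute
bisection: with $\tau_w = 1$ only the $\theta$ row of the reduced Jacobian
scales with $1/\tau$, so every characteristic coefficient is affine in
$1/\tau$ and the Routh–Hurwitz residual is a quadratic in $1/\tau$, solved
in closed form at each equilibrium (`reduced_hopf_taus()`); candidates are
kept only where all coefficients are positive, i.e. where a genuine
imaginary pair crosses. `reduced_min_hopf_tau()` sweeps $C$ on a grid
(step 0.1 over $[-4, 5]$, with two tenfold local refinement passes around
the running minimum) and reports the smallest threshold on any branch —
below it the diagram contains no Hopf bifurcation at all.

## Cycles, Floquet multipliers and chaos

`find_limit_cycle()` integrates past a transient, detects recurrence on a
Poincaré plane placed at the midrange of the most active coordinate, and
refines the orbit by Newton shooting on the (possibly iterated) return
map until the state recurs within $10^{-6}$; non-recurrent motion
(equilibria, tori, chaos) yields `NULL` with a retrievable diagnostic.
The return map itself is computed with event-exact root finding inside
the adaptive integrator (relative tolerance $10^{-10}$ there;
trajectory-level work uses $10^{-8}$/$10^{-10}$, tightened to
$10^{-9}$/$10^{-11}$ for cycle and variational work). An explicit option
(`shoot_anyway`) allows shooting for the mildly unstable simple cycle
embedded in a period-doubled attractor — exactly what bisecting a
period-doubling point requires — without weakening the default "no
recurrence means no cycle" semantics.

`floquet_multipliers()` integrates the variational equations over one
period and reports the eigenvalues of the monodromy matrix; the trivial
multiplier must sit within $10^{-3}$ of $+1$ or the result is flagged.
Period doubling is a real multiplier crossing $-1$
(`reduced_period_doubling_C()` bisects on exactly that sign), a torus
bifurcation is a complex pair crossing the unit circle.

`continue_cycle()` is deliberately naive natural-parameter continuation of
*attracting* cycles: each step re-converges the cycle from the previous
one, and when convergence fails the branch end is refined by bisection on
cycle existence. Folds of stable branches are therefore detected as branch
termination (the attractor jumps elsewhere — in the worked example, to
collapse toward the origin), which is exactly the observable the package
cares about; unstable branch segments and two-parameter continuation are
out of scope, as is pseudo-arclength continuation around folds. Homoclinic
behavior is only ever reported as a *candidate* (long period plus close
approach to a supplied saddle), since near-homoclinic numerics cannot
certify the connection; the printed thresholds (period above $10^3$,
distance below $10^{-2}$) are intentionally conservative and can be
relaxed per call for coarse desk-scale sweeps.

The maximal Lyapunov exponent (`max_lyapunov()`) uses tangent-vector
growth with periodic renormalization, reported with a standard error over
segments. A chaos call should demand the exponent exceed zero by several
standard errors — quasi-periodic motion after a torus bifurcation sits
at zero and is the classic false positive. In the chaotic window of the
reduced system the exponent is small (order 0.02 per unit time), so runs
of several thousand time units are needed for a clean separation; the
acceptance suite uses 1500 segments of length 5.

## The two-neuron network

Two neurons receiving the common ensemble inhibit each other with strength
$\gamma$; the lateral interaction is algebraic (responses at the steady
state of the fast relaxation dynamics, whose linearization has eigenvalues
$\gamma - 1$ and $-(1 + (N-1)\gamma)$, both negative for
$0 < \gamma < 1$ — the general-$N$ steady state is
`inhibition_steady_state()`). With $g = 1/(1-\gamma^2)$ and
$h = \gamma/(1-\gamma^2)$ the six-dimensional mean field
(`network_meanfield_rhs()`, state ordered
$(v_{a1}, v_{a2}, \theta_a, v_{b1}, v_{b2}, \theta_b)$ — one fixed wire
format, since equilibrium orderings are easy to scramble) is equivariant
under swapping the neurons. Equilibrium conditions decouple per neuron, so
all 16 combinations of the four single-neuron options are equilibria
(`network_fixed_points()`).

At the symmetric selective equilibrium the linearization is block
symmetric and splits into two $3 \times 3$ blocks with amplitudes
$a_1 = g - h$ (in-phase perturbations) and $a_2 = g + h$ (anti-phase);
since $a_2 > a_1$, stability is lost in the anti-phase block — a
symmetry-breaking Hopf at $\tau_H^s = (1-\gamma)/(1-\cos^2\alpha)$, linear
in $\gamma$. The antisymmetric equilibrium persists to
$\tau_H^a = (1-\gamma\cos\alpha)/(1-\cos^2\alpha)$; for acute angles the
symmetric state therefore destabilizes first. Both closed forms are
checked against bisection on the full $6 \times 6$ spectrum. Partially
selective equilibria are saddles: the constant characteristic coefficient
$-(g^2-h^2)^2(\beta^2-1)^2/(4\tau^2)$ is negative, and equals the numeric
Jacobian determinant. Regime classification
(`classify_network_regime()`) is simulation-based and coarse by design:
equilibrium proximity, cycle detection, the per-neuron selectivity gap,
an optional Lyapunov call, and an explicit collapsed-to-origin test
(late-time activity below 0.05).

## Problem sizes and reproducibility

Every stochastic choice (switching draws, start grids, drawn initial
conditions) takes an explicit integer seed, and the blow-up guard aborts
any integration whose state exceeds $10^6$ in magnitude — solutions of the
averaged equations genuinely blow up in finite time at large $\tau$. The
shipped analysis sizes are chosen for interactive use: hybrid runs of a
few thousand time units at switching rate 5, twenty-seed ensembles for the
averaging comparison, a $C$ grid of step 0.1 for the Hopf-floor sweep,
bisection tolerances of $10^{-3}$ on fold and period-doubling locations,
and Lyapunov runs of $\le 10^4$ time units. All of these are arguments,
not constants, and scale up transparently.

`scripts/acceptance.R` recomputes the package's headline numbers from
scratch (the four Hopf/fold points of the unequal-amplitude two-stimulus
system, and the Hopf floor, isola window and period-doubling point of the
reduced three-stimulus system) and writes them to JSON; the test suite
additionally verifies the property-level claims (conservation, averaging
convergence in the switching rate, closed-form/numeric stability
agreement, spectrum factorization, escape of the expanding cone, the
selectivity regimes of the hybrid simulator, and sign patterns of the
Lyapunov exponent).

## Known limitations

* The threshold exponent is fixed at 2; the temporal-average formulation
  and general exponents are not implemented.
* Inhibitory weights are constant: no plasticity on the lateral coupling,
  and no networks beyond the two-neuron mean field other than the
  steady-state algebra above.
* Continuation follows stable objects only; unstable cycle branches,
  two-parameter bifurcation curves and certified homoclinic connections
  are out of scope.
* The averaged model is exact only in the fast-switching limit; at rate 5
  with $\tau_w = 25$ the hybrid dynamics visibly fluctuate around the mean
  field, and near stability boundaries those fluctuations can sustain
  oscillations where the mean field alone would spiral in.
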