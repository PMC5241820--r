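---
title: "Methods: birth-death dynamics in populations of ideas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: birth-death dynamics in populations of ideas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideapop)
```

## The model

`ideapop` treats reinforcement learning of a repeated 2×2 game as selection
in a finite population of N ideas, each idea being one of the two pure
strategies. The composition x = n/N of the population is the player's mixed
strategy. Two ingredients define the chain:

1. **Modified fitness.** An idea of type i has fitness
   $f_i = \pi_i - \lambda \ln x_i$, its average payoff
   $\pi_i = a_{i1}x + a_{i2}(1-x)$ penalised by the log of its own
   frequency. The entropic term (strength λ = α/Γ in terms of the memory
   discount α of the underlying learning rule) favours rare ideas; it is
   what distinguishes learning-with-forgetting from plain selection. The
   finite-N payoff uses the lattice composition including the focal
   individual, $\pi_1 = [a_{11} n + a_{12}(N-n)]/N$, with no
   self-exclusion correction.
2. **Linear pairwise comparison.** A pairwise update replaces the second
   idea by the first with probability
   $g(f_1, f_2) = [1 + \Gamma (f_1 - f_2)]/2$. The rates are
   $T^\pm_n = N x (1-x)\, g(\cdot, \cdot)$ with the arguments in the two
   orders; the factor N makes time count generations. Because
   $g(f_1,f_2) - g(f_2,f_1) = \Gamma (f_1 - f_2)$, the drift
   $(T^+ - T^-)/N$ is exactly the deterministic Sato-Crutchfield velocity
   $\Gamma x(1-x)(f_1 - f_2)$, which at λ = 0 is Γ times the replicator
   flow. The linear form is essential: averaging the comparison probability
   over a randomly drawn adversary commutes with the linearity, which is
   why the triplet-sampling microdynamics (`triplet_microsim()`) reproduces
   the rates exactly and why no separation of time scales between game play
   and selection is needed. A sigmoidal (Fermi) comparison function would
   change the stochastic dynamics and is deliberately not offered.

States n = 0 and n = N have zero rates: they are absorbing, so ideas fix or
go extinct in finite time with probability one, for *every* admissible λ.
The contrast model, the replicator-mutator flow
$\dot x = \Gamma x(1-x)(\pi_1-\pi_2) + u(1-2x)$, has strictly inward flow
at the boundary for u > 0 — mutation forbids fixation, memory loss does
not. This structural difference is the package's central point and is
asserted by the test suite (boundary rates identically zero versus boundary
flow of magnitude u).

For asymmetric games two populations of N ideas evolve on the (n, m)
lattice; each population's payoffs are evaluated against the *other*
population's composition, each population's entropic penalty against its
own. The four corners are the only absorbing states (exhaustively verified
at N = 30 in the tests).

## Parameters

* **Γ (intensity of choice), default 0.1.** Scales selection strength and
  the speed of the deterministic flow. 0.1 is the conventional middle
  ground between best-response (Γ ≳ 1) and weak selection (Γ ≪ 1); fixed-
  point *locations* are independent of Γ, only rates and eigenvalues scale.
* **λ (memory loss), dimensionless, ≥ 0.** The rates are only non-negative
  while $\Gamma |f_1 - f_2| \le 1$ everywhere on the lattice; since the
  entropic term peaks one step from the boundary, this imposes
  λ < λ_c = O(1/ln N). `validate_rates()` checks the whole lattice and
  reports the maximal admissible λ (by bisection) rather than clipping g —
  clipping would silently change the model. All simulation constructors
  refuse invalid parameters.
* **N (population size), ≥ 2.** Default analyses use N = 200 for
  one-population chains (large enough for the deterministic flow to
  organise the dynamics, small enough for visible finite-size effects),
  N = 30 for two-population backward solves (the linear system has
  (N+1)² − 4 unknowns), N = 100–500 for two-population Monte Carlo, and
  N = 1000 for the non-monotonicity scan, which needs a tall activation
  barrier. These mirror the study conditions; the closed-form and sparse
  solvers make the N = 1000 scans cheap, so no reduced default is needed.
* **u (mutation rate)** enters only the replicator-mutator comparison.

## Numerical choices

* **Logit-space root finding.** Interior fixed points of the 1D flow are
  roots of $\phi = \pi_1 - \pi_2 - \lambda\,\mathrm{logit}(x)$; all roots
  satisfy $|\mathrm{logit}(x^*)| \le \max|\pi_1-\pi_2|/\lambda$, so sign-
  change bracketing on a uniform grid (default 1024 points) in logit space
  over exactly that band finds them all. This matters because roots sit
  exponentially close to the boundary at small λ (e.g. within 10⁻¹⁷ for
  the coordination fixture at λ = 0.05): in x-space they would be
  indistinguishable from the boundary fixed points, in logit space they
  are well separated. Interior roots are deduplicated in logit space
  (10⁻⁶; boundary points are a separate category and never merged), and
  classified analytically via the flow derivative
  $\Gamma[k\,x(1-x) - \lambda]$, k the slope of π₁ − π₂.
* **2D fixed points** come in three kinds, searched separately: corners
  (always fixed; for λ > 0 the entropic force makes all four unstable),
  edge points (the frozen player's payoff difference is constant there, so
  λ > 0 pins exactly one per edge at logit(x) = const/λ, always a saddle),
  and interior roots (damped Newton with the analytic Jacobian from a
  64×64 logit-space seed grid, accepted only on *step* convergence
  < 10⁻⁹ — a residual-only test accepts spurious flat-region points when a
  bifurcation makes the root degenerate; deduplication at 10⁻³ in logit
  space, two orders below genuine root separations at the λ_c-refinement
  width and two above the degenerate-case noise). Centers are eigenvalue
  pairs with |Re| < 10⁻⁸ and nonzero imaginary part; the Matching Pennies
  λ = 0 eigenvalues are ±iΓ analytically and classify robustly.
* **λ_c** is found by tracking the fixed-point count across a λ grid and
  bisecting each count change to width 10⁻⁴; a scan without count change
  (coexistence game) reports no λ_c, a valid outcome.
* **Closed-form fixation sums** use the standard birth-death first-passage
  solution in the rate ratios γ_k = T⁻_k/T⁺_k; all running products and
  their partial sums are accumulated with log-sum-exp, so large N and
  strong selection cannot overflow. The backward-master-equation solver
  assembles the transient-state system in sparse triplet form and uses a
  direct sparse factorisation at all sizes used here (up to the 58 081
  unknowns of N = 240, a few seconds); the two agree to a relative 10⁻⁸
  on every fixture, and Monte Carlo agrees within 3 standard errors.
  Reported mean fixation times are unconditional (not conditioned on the
  absorbing boundary reached); this convention is pinned here and in the
  tests.
* **Gillespie core in C++** (Rcpp), drawing from R's RNG so `set.seed()`
  governs everything; replicate r of an ensemble is seeded
  `seed + (r − 1)`, making ensembles reproducible and splittable. Censoring
  by time horizon or event cap (default 10⁹) is flagged distinctly from
  absorption and censored replicates are excluded from fixation-time means
  but reported.
* **ODE integration** uses `deSolve`'s lsoda with rtol = atol = 10⁻⁹;
  boundary evaluations use the limit value 0 of the flow (the x(1−x)
  prefactor dominates the log divergence), and integrator probe points are
  clamped to the unit interval.
* **Diffusion exponent**: ensemble RMS distance from the lattice centre,
  log-log slope over the automatic window 2/N ≤ d ≤ 0.25 (below: lattice
  discreteness; above: saturation as orbits feel the corners), requiring
  at least 10 window points.
* **Scaling-law comparison** fits each candidate (power law, exponential,
  logarithmic) on its own linearisation and reports R² side by side; no
  formal model-selection criterion is claimed, matching how such scaling
  evidence is usually presented.

## Fixture games

The displayed payoff matrices of the source analyses are not machine-
readable here, so the package pins canonical representatives of each class
and treats every structural claim as a class property (fixed-point counts,
stability patterns, scaling signatures), never a property of specific
entries: coexistence (1,2,2,1), dominance (3,1,2,0), coordination
(2,0,0,1), neutral (1,1,1,1); Matching Pennies A = ((1,−1),(−1,1)),
B = −A (zero-sum); asymmetric dominance A = ((2,1),(1,0)) (row 1 strictly
dominant) with B = ((2,0),(0,1)); hyperbolic A = B = ((1,0),(0,1)), whose
player/action-swap symmetry makes the two stable interior points and the
saddle merge *simultaneously* at λ_c (here exactly 1/2) — without the
symmetry the saddle would annihilate with one stable point only.

## What the simulations do and do not show

The generator *is* the model: Gillespie samples the exact chain defined by
the rates, so agreement between simulation, closed form and backward solve
is an internal-consistency triangle, not evidence about real learners. What
the package's tests establish about the model itself: the diffusive
(τ ∝ N, exponent 1/2), activated (τ ~ e^{cN}, also e^{cλ}) and
relaxational (τ ~ ln N) fixation mechanisms appear in the predicted
regimes; fixation times grow monotonically in λ for coexistence and
dominance games but non-monotonically for coordination games near the
saddle-node (visible at N = 1000 for initial conditions near the merging
pair); and the triplet microdynamics matches the rates to binomial
accuracy. Statistical assertions use fixed seeds; per-state 3-standard-
error checks across ~100 simultaneous states allow the expected multiple-
comparison exceedances (at most 5% of states beyond 3 se, none beyond
4.5).

Real learning data would add everything the model idealises away:
non-stationary opponents, payoff noise, finite observation between
updates, and S > 2 strategies. The triplet construction is payoff-only
(λ = 0): the entropic fitness term is a population-level quantity with no
per-encounter counterpart, so entropic simulation goes through the rates,
never through triplets.

## Design decisions that were genuinely open

* **Mutation-term form.** The replicator-mutator comparison uses the
  symmetric two-type flux u(1 − 2x) added to the Γ-scaled replicator term,
  so that its u → 0 limit coincides exactly with the λ → 0 learning flow
  on every grid point.
* **Unconditional fixation times** (above).
* **Deterministic-relaxation helper.** `relaxation_time()` measures the
  time for the deterministic flow to come within c/N of a stable fixed
  point; c is exposed with default 1 — it is an order-one calibration
  constant, not a fitted parameter.
* **Desk-scale problem sizes.** The scaling fits use exact backward solves
  on N-grids of 20–60 (activated, two populations), 30–240 (relaxational)
  and Monte Carlo on 60–420 (diffusive): the exact solver is preferable
  wherever it is available because it removes sampling error from a fitted
  slope; Monte Carlo is kept where the quantity is a property of sample
  paths (diffusion exponent) or where the lattice is too large to solve.

## Known limitations

* S = 2 strategies only; the construction generalises but nothing here
  implements S > 2.
* No Fermi-rule chain, no tau-leaping or diffusion-approximation
  simulation: exact SSA only.
* No analytic activation-barrier (large-deviation) computations; the
  exponential-in-N signature is established by fits, not by a computed
  barrier height.
* `fixation_closed_form_1d()` is one-population only; two-population exact
  results go through the sparse backward solve, whose direct factorisation
  is the practical limit (~N = 300 on a laptop-class machine).
* The λ_c bisection tracks fixed-point *counts*; a bifurcation that
  exchanges stability without changing the count would not be flagged.
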