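---
title: "Methods: Moran dynamics, fixation, and long-term evolution on graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Moran dynamics, fixation, and long-term evolution on graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evograph)
```

## Model

A population of `N` haploid individuals occupies the nodes of a connected,
undirected, unweighted graph with adjacency matrix `A = (a_lm)`. Two types
compete: residents of fitness `f` and mutants of fitness `f'`. One
reproduction event happens per time step, under one of two orders:

* **Bd** — an individual is chosen to reproduce with probability
  proportional to fitness among *all* nodes; one of its neighbours is chosen
  uniformly to die and is replaced.
* **dB** — an individual is chosen uniformly among all nodes to die; its
  neighbours compete to fill the vacancy with probability proportional to
  fitness.

Reproduction creates two daughter cells. The **mover convention** says which
daughter occupies the vacated node: the offspring (`-o`) or the parent-type
daughter (`-p`). Because mutation is coupled to reproduction (probability
`mu` per birth), the mover convention determines where a *new* mutant sits
when it first appears, even though it has no effect on the mutation-free
competition that follows. The induced initialisation distributions are:

| rule | initialisation |
|------|----------------|
| `Bd-o` | temperature, `p_i = T_i / N` |
| `Bd-p` | uniform, `p_i = 1/N` |
| `dB-o` | uniform |
| `dB-p` | temperature |

with the (in-)temperature `T_i = Σ_j a_ji / Σ_k a_jk`. For undirected
graphs in- and out-temperatures coincide and sum to `N`. A mixed rule
(`Bd-mix:λ`, `dB-mix:λ`) lets the parent move with probability `λ` per
event; since the mutation-free kernel is mover-invariant, its average
fixation probability is exactly the `λ`-convex combination of the two pure
rules' values, and its initialisation distribution is the same convex
combination. (For `Bd` we adopt this extension by analogy with the `dB`
case; it is a package convention, not an independently derived result.)

### Assumptions

* One individual per node; no empty sites.
* Unweighted, undirected, connected graphs; no self-loops (an individual
  never replaces itself).
* dB death is uniform over *all* nodes, including mutants.
* Mutations are rare enough that at most one mutant lineage segregates at a
  time (relevant for the long-term dynamics below).

## Exact fixation probabilities

The mutation-free process is an absorbing Markov chain on mutant subsets,
with the empty and full configurations absorbing. `fixation_per_node_exact()`
builds the one-event transition kernel for all `2^N` configurations at once
(vectorised over configurations) and solves the sparse linear system
`(I - P_TT) x = P_T,fix`. The per-node flip probabilities are assembled from
closed expressions: under Bd the probability that node `i` changes type is
the fitness-weighted mass of opposite-type neighbours spread over their
degrees; under dB it is `1/N` times the opposite-type share of fitness in
`i`'s neighbourhood.

Numerical choices:

* configurations are indexed by bitmask; the solver is capped at `N <= 16`
  (65k states) — beyond that the dense index arrays dominate memory and the
  star-specific solver below is the intended tool;
* the neutral case `f' = f` is solved like any other (the system is
  nonsingular); closed forms use the analytic limit `1/N` instead of
  evaluating 0/0;
* closed-form geometric ratios `(1 - ρ)/(1 - ρ^k)` use `expm1` near
  neutrality and switch to log-space asymptotics when `ρ^k` would overflow.

`step_kernel()` re-derives single-state successor distributions by direct
enumeration over birth/death pairs. It deliberately shares no code with the
vectorised solver so the test suite can play the two against each other on
small graphs.

### The star graph and the banded solver

Leaves of a star are exchangeable, so the chain lumps to
(centre occupied?, number of mutant leaves): `2N` states on a ladder,
giving a pentadiagonal transition structure. `fixation_star_reduced()`
solves this system with banded Gaussian elimination **without pivoting** in
the natural ladder order. For an M-matrix absorbing-chain system this
elimination never subtracts quantities of equal sign in the off-diagonal and
right-hand-side updates, so the solution is componentwise accurate down to
the smallest representable magnitudes. This matters: a deleterious mutant on
a large Bd star fixes with probability ~1e-92 at `N = 1000`, far below the
absolute accuracy of a generic sparse LU (which returns sign-indefinite
noise near 1e-16 there). The banded solver reproduces those values with full
relative precision — verified indirectly by the effective-population-size
fits below, which would be garbage otherwise.

The dB star additionally has closed forms for centre and leaf starts
(`fixation_star_closed()`); the temperature average is
`((N-1) φ_centre + φ_leaf)/N`. Large-N limits: the temperature-initialised
dB star tends to `f'/(f + f')` — nonzero even for deleterious mutants —
while the complete graph tends to `max(0, 1 - f/f')`.

## Monte Carlo

`simulate_fixation()` simulates the **embedded jump chain**: self-loop
events (which cannot change the configuration) are skipped analytically and
the successor is drawn from the conditional distribution. Absorption
probabilities are identical to event-by-event simulation; only time scales
(out of scope here) would differ. A single R RNG stream is seeded once per
call, making runs bitwise reproducible given the seed; the per-replicate
step cap (default 1e6 configuration changes) guards against non-absorbing
loops. The binomial standard error `sqrt(p(1-p)/n)` is reported.

## Classification

`classify()` compares the graph's initialisation-averaged profile with the
complete graph at the nine grid fitnesses `0.5, 0.75, ..., 2.5`
(resident `f = 1`):

* **AoS / SoS** use the deleterious (`f' < 1`) and beneficial (`f' > 1`)
  points; the neutral point is excluded (uniform-initialised rules tie with
  the baseline there by construction).
* **AoF / SoF** require a strict inequality at *every* grid point.
* **piecewise-AoF** is above the baseline up to a crossing `f* >= 1` and
  below beyond it; `f*` is reported at grid resolution only — no
  root-finding between grid points.
* **isothermal** is decided structurally (regular graph) before any
  comparison, with the caveat that equality of fixation probabilities with
  the complete graph holds only for Bd updating.
* anything else, including any tie within tolerance (default `1e-9`, the
  exact-solver noise floor) at a point a category needs, is **other**.

The dB reference profile is the complete-graph closed form; the Bd reference
is computed by the exact solver on the complete graph at the same `N`
(avoiding any dispute over which classical formula to use), and cached.

One consequence of grid resolution worth knowing: the `dB-p` star at
`N = 8` crosses the complete graph near `f' ≈ 4.3`, *outside* the default
grid, so at grid resolution it is classified as a universal AoF; on a grid
extended past the crossing it becomes piecewise-AoF. Both behaviours are
asserted in the test suite.

`census()` classifies `n` connected Erdős–Rényi samples (rejection sampling
conditions on connectivity, preserving the G(N, p)-given-connected law).
Isomorphic duplicates are kept — the tallies describe sampled graphs, not
distinct topologies. The sample count is a parameter; no canonical value
exists.

## Long-term origin-fixation dynamics

At mutation rate `μ ≪ 1` the population is monomorphic between fixation
events and its fitness performs a Markov chain with rates
`T_{f'←f} = μ ρ(f'|f) Φ_G(f', f)`. `μ` multiplies every rate and cancels
from all stationary quantities, so it is not a solver parameter.

* `psi_ratio()` forms `Ψ(f', f) = Φ(f', f)/Φ(f, f')`. The chain is
  reversible iff `Ψ = (f'/f)^ν`; `fit_nu()` fits `ν` as the no-intercept
  least-squares slope of `log Ψ` on `log(f'/f)` and reports the maximum
  residual as a reversibility diagnostic. The default ratio window
  `{0.9, 0.95, 1.05, 1.1}` brackets neutrality, where the power-law form is
  most accurate.
* `hoc_stationary()` gives the closed-form stationary density
  `P*(f) ∝ f^ν` for the House-of-Cards model with uniform mutant fitness on
  `[f_min, f_max]`, plus mean and standard deviation from the `ν+1` and
  `ν+2` moments.
* `discrete_chain_stationary()` builds the jump chain on a fitness grid with
  nearest-neighbour proposals (probability 1/2 each). At the boundaries the
  lost outward proposal mass becomes a self-loop, preserving proposal
  symmetry between neighbouring states; this convention is ours — no
  canonical choice exists. The stationary law is obtained by a direct
  global-balance solve (left null vector with a normalisation row), *not* by
  assuming detailed balance, because reversibility is generally only
  approximate; the deviation of the detailed-balance product construction is
  returned as a diagnostic (it is ~1e-16 for the complete graph, where the
  power law is exact).
* `origin_fixation_mc()` simulates propose–accept steps. Rejected proposals
  advance the clock: mutations arrive at a fitness-independent rate, so
  self-loops belong in the time average. The standard error of the mean is
  estimated by batch means (50 batches after burn-in, default one tenth of
  the run).

Reference exponents recovered by the package (and asserted in the tests):
`ν = N - 2` for the complete graph under dB (and the cycle, whose `Ψ` is
identical), `ν → 1` for the `dB-p` star, `ν → 2` for the `dB-o` star, and
`ν → 2N - 2` for the Bd star. The corresponding steady-state means explain
the headline reversal: amplifiers of fixation (low `ν`) equilibrate at lower
fitness than the well-mixed baseline because they keep accepting deleterious
mutants, while suppressors of fixation (high effective `ν`) end up fitter.
At `N = 8` on the grid `0.5..2` the exact chains give mean fitness 1.844
(complete) > 1.529 (star `dB-o`) > 1.410 (star `dB-p`), with the standard
deviations ordered the other way.

A caution on "identical" Bd star steady states: the `Bd-o` and `Bd-p` star
share `ν = 2N - 2` only asymptotically. At `N = 8` their exact discrete-grid
means differ by about 0.4% relative — approximately equal on the scale of
simulation scatter, but not numerically identical. One acceptance check in
the test suite demands agreement at 1e-6 relative and is therefore expected
to fail; it is kept as written rather than loosened.

## What the generators emulate — and what a green test does not establish

There is no external data: graphs, fitness values and mutation models are
the objects of study, and the package generates them. The Erdős–Rényi census
emulates the stated world of small (`N = 8`) random structures; it says
nothing about large graphs, degree-heterogeneous ensembles beyond G(N, p),
or weighted/directed interactions, all of which are out of scope. Monte
Carlo agreement checks are calibrated at 4 standard errors and can flag a
correct implementation roughly once per few thousand runs by chance; seeds
are fixed in the tests to keep them deterministic.

## Known limitations

* Full-configuration exactness stops at `N = 16`; only stars scale further.
* Fixation *times* (conditional or not) are not computed.
* Db and bD orders, directed/weighted graphs, metapopulations, and
  polymorphic (high mutation rate) dynamics are out of scope.
* `estimate_nu()` on irreversible graphs returns a window-dependent
  effective exponent; the residual diagnostic should always be inspected
  before interpreting `ν` as an effective population size.
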