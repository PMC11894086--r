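# evograph

Moran evolutionary dynamics on graph-structured populations.

## The problem

In evolutionary graph theory a population of `N` asexual individuals sits on
the nodes of an undirected, unweighted graph; links define who can replace
whom. A single mutant of fitness `f'` arises in a resident background of
fitness `f`, and the central observable is its **fixation probability**
`Φ_G(f', f)`: the chance that the mutant lineage takes over the whole graph.
Structure can bend this probability relative to the well-mixed (complete
graph) baseline, and the direction of the bend depends on fine details of the
update rule.

`evograph` implements the full cross of two such details:

* **event order** — `Bd` (fitness-proportional birth, then uniform death
  among the parent's neighbours) versus `dB` (uniform death, then
  fitness-proportional birth among the dead node's neighbours);
* **which daughter moves** — after reproduction either the offspring (`^o`)
  or the parent-type daughter (`^p`) occupies the vacated node.

Without mutation the mover choice is invisible (both daughters are copies),
but it decides **where a new mutant appears**: `Bd-o` and `dB-p` place the
first mutant proportional to node *temperature*
`T_i = Σ_j a_ji / Σ_k a_jk` (hot, high-degree nodes turn over often), while
`Bd-p` and `dB-o` place it uniformly. The initialisation-averaged fixation
probability is `Φ_G = Σ_i p_i φ_{G,i}`.

Comparing `Φ_G` to the complete graph over a fitness grid classifies graphs
as amplifiers/suppressors of **selection** (AoS/SoS: the usual definitions)
or of **fixation** (AoF/SoF: above/below the baseline at *every* fitness —
including deleterious mutants). On long time scales the package follows
origin-fixation (weak mutation) dynamics: the population fitness performs a
Markov chain with rates `μ ρ(f'|f) Φ_G(f', f)`, whose stationary law under a
power-law fixation ratio `Ψ = Φ(f',f)/Φ(f,f') = (f'/f)^ν` is tilted by
`f^ν`. The exponent `ν` acts as the graph's effective population size.

Intended users: theoretical/computational population geneticists and anyone
teaching or exploring evolutionary graph theory who needs exact small-graph
solvers, stable closed forms, and reproducible simulation in one place.

## What is inside

| area | functions |
|---|---|
| graphs | `make_named_graph`, `sample_er_connected`, `temperature`, `read_graph`, `write_graph` |
| update rules | `update_rule`, `parse_rule`, `initialisation_distribution`, `step_kernel` |
| fixation, exact | `fixation_per_node_exact` (full `2^N` chain, N ≤ 16), `fixation_star_reduced` (lumped star chain, N up to ~10⁴), `fixation_complete_closed`, `fixation_star_closed`, `limit_complete`, `limit_star_db_temp` |
| fixation, Monte Carlo | `simulate_fixation` |
| classification | `fixation_profile`, `classify`, `census` |
| long-term dynamics | `psi_ratio`, `fit_nu`, `estimate_nu`, `hoc_stationary`, `discrete_chain_stationary`, `origin_fixation_mc` |
| I/O & CLI | `write_results`, `evograph_cli` (+ `inst/cli/evograph` executable) |

## Worked example

```r
library(evograph)

star <- make_named_graph("star", 8)

# A beneficial mutant (f' = 2) fixes more readily on the dB-p star than in a
# well-mixed population of the same size ...
average_fixation(star, "dB-p", fprime = 2)   # 0.5647321
fixation_complete_closed(8, 2)               # 0.4409449

# ... and so does a deleterious one (f' = 0.5): the star amplifies fixation.
average_fixation(star, "dB-p", fprime = 0.5) # 0.3319515
fixation_complete_closed(8, 0.5)             # 0.006889764

# The same star under the four rules lands in four different categories:
sapply(c("Bd-o", "dB-o", "Bd-p", "dB-p"),
       function(r) classify(star, r)$category)
#   Bd-o   dB-o   Bd-p   dB-p
#  "SoF"  "SoS"  "AoS"  "AoF"

# Effective population size of the large dB-p star: nu -> 1
estimate_nu(phi_star_reduced(2000, "dB-p"))$nu  # 0.998999

# Long-term origin-fixation dynamics on the discrete fitness grid 0.5..2:
# the amplifier of fixation ends up LESS fit than the well-mixed population,
# because it also fixes the deleterious mutants it is offered.
grid <- seq(0.5, 2, by = 0.25)
discrete_chain_stationary(phi_complete(8), grid)$mean           # 1.844367
discrete_chain_stationary(phi_exact(star, "dB-o"), grid)$mean   # 1.528567
discrete_chain_stationary(phi_exact(star, "dB-p"), grid)$mean   # 1.410278
```

Command line (same machinery):

```sh
inst/cli/evograph fixation --graph star:8 --rule dB-p --fprime 0.5:2.5:0.25 --method exact
inst/cli/evograph census --n 8 --p 0.5 --samples 200 --rule Bd-o --seed 7 --out counts.tsv
inst/cli/evograph longterm --graph star:8 --rule dB-p --grid 0.5:2:0.25 --method solve
```

Exit codes: 0 success, 2 validation error, 3 capacity/sampling failure.

## Notes

* Exact solvers are deterministic; every stochastic routine takes an explicit
  seed and is bitwise reproducible given it.
* The full-configuration solver is capped at N ≤ 16; stars use the lumped
  (centre, mutant-leaf-count) chain, solved by a cancellation-free banded
  elimination that stays accurate even when fixation probabilities underflow
  toward 1e-90.
* See `vignettes/evograph-methods.Rmd` for the model, conventions, numerical
  choices, and known limitations.
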