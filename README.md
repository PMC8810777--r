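# rpslattice

Stochastic lattice simulator for cyclic three-species competition
(rock–paper–scissors) with **territorial awareness**: each species is split
into two heritable *genera* tied to the top and bottom halves of the
lattice, and intraspecific competition fires only between same-species
individuals of different genera, at a rate scaled by a sensitivity
coefficient *k*. The package is aimed at theoretical ecologists and
evolutionary-game researchers who want a fast, reproducible implementation
of this model class together with its standard observables.

## The model

On an L × L periodic square lattice (von Neumann neighbourhoods, one
individual or vacancy E per site), adjacent actor–neighbour pairs react by

| reaction | rule | rate |
|---|---|---|
| interspecific | A + B → A + E, B + C → B + E, C + A → C + E (any genera) | p₁ |
| intraspecific | Xᵢ + Xⱼ → Xᵢ + E or E + Xⱼ (i ≠ j in territorial mode) | k·p₂ |
| reproduction | X + E → X + X (genus inherited) | r |
| migration | X + ⊗ → ⊗ + X (⊗ = any species or vacancy) | m = 2MN |

For each attempt one event type is drawn with probability
`rate / (p₁ + k·p₂ + r + m)`; a drawn reaction that does not match the pair
state fails and still consumes the attempt. One generation is N = L² pairwise
attempts. With k = 0 the model reduces exactly to the classic spatial RPS
game, including its critical mobility M_c ≈ 4.5 × 10⁻⁴ separating coexistence
from single-species dominance at the conventional horizon T = N.

Observables: survival-state classification (`summarize_lattice()`), two
regime-specific extinction times (`extinction_time()`: first generation at
which every species has lost a genus, or at which two whole species are
gone), and the interface width W (`interface_width()`), the mean
interpenetration depth of the two territory classes near the boundary:
I_j = max(P(1,j) − P(2,j), 0) per column, W = Σ I_j / L. A replicated sweep
harness (`sweep_spec()`, `sweep_extinction_vs_k()`, `sweep_width_vs_k()`,
`sweep_traditional_vs_territorial()`, `phase_scan_mobility()`) handles seeds,
censoring and standard errors.

## Worked example

```r
library(rpslattice)

cfg <- rps_config(L = 100, M = 1e-5, k = 10, T_max = 2000, seed = 42,
                  record_every = 500)
event_probabilities(cfg)
#> interspecific intraspecific  reproduction     migration
#>    0.08196721    0.81967213    0.08196721    0.01639344

traj <- run_simulation(cfg)
traj$densities
#>   generation   A1   A2   B1   B2   C1   C2    E
#> 1          0 1244 1222 1247 1286 1232 1256 2513
#> 2        500 1558 1263 1608 1740 1308 1383 1140
#> 3       1000 1688 1573 1365  960 1517 1896 1001
#> 4       1500 1414 1285 1653 1878 1173 1718  879
#> 5       2000 1468 1987 1711 1091 1597 1256  890

summarize_lattice(traj$final_state)
#> rps_survival: full_coexistence
#>   species alive: A B C
#>   genera alive:  A1 A2 B1 B2 C1 C2

interface_width(traj$final_state)
#> rps_interface_width: W = 8.5800 over 100 columns (window rows 34..67)
```

At k = 10 intraspecific competition dominates the drawn-event mix (0.82),
yet away from the territorial boundary those draws fail (no cross-genus
pairs), so both genera of all three species persist at generation 2000
(`full_coexistence`). W ≈ 8.6 rows means genus-1 and genus-2 individuals
interpenetrate by about nine rows around the interface at this early stage;
W shrinks as k grows, and mean extinction time rises as W shrinks — the
trends the acceptance tests verify.

A command-line front end ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rpslattice.R", package = "rpslattice"))')" \
  run inst/configs/paper_fig2_low_mobility.json --seed 7 --out-dir out --snapshots 1000
```

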