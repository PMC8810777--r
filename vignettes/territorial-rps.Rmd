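---
title: "Territorial awareness in the stochastic lattice rock-paper-scissors game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Territorial awareness in the stochastic lattice rock-paper-scissors game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rpslattice` simulates cyclic competition among three species A, B, C on an
L x L square lattice with periodic boundaries and von Neumann (4-site)
neighbourhoods.  Every site holds one individual or is vacant (E), so the
lattice enforces a finite carrying capacity N = L x L.  The lattice is split
into two equal territories — rows 1..L/2 (top) and rows L/2+1..L (bottom) —
and each species is divided into two *genera*: X1 individuals start in the
top territory, X2 in the bottom.  The genus is a heritable identity:
offspring inherit it, and an individual that migrates across the boundary
keeps it.

Four reactions act on an adjacent actor-neighbour pair:

* **Interspecific predation**, rate `p1`: A beats B, B beats C, C beats A,
  for any genus pairing; the loser's site becomes vacant.
* **Intraspecific competition**, rate `k_i * p2` for species i: in the
  default *territorial* mode it fires only between same-species individuals
  of *different* genera — the encounter a territory-aware individual treats
  as an intrusion — and one of the two dies with probability 1/2 each.  In
  *traditional* mode the genus condition is dropped and any same-species
  pair may fight.
* **Reproduction**, rate `r`: an actor copies itself (same genus) into a
  vacant neighbour.
* **Migration**, rate `m = 2 M N`: actor and neighbour exchange contents
  unconditionally (species or vacancy), the standard random-walk embedding
  of a macroscopic mobility M.

For a selected pair, one event type is drawn with the normalized
probabilities `p1/D`, `k*p2/D`, `r/D`, `m/D`, `D = p1 + k*p2 + r + m`
(`event_probabilities()`).  If the drawn reaction does not match the pair
state — reproduction without a vacancy, predation against the cycle,
intraspecific against the genus rule — the reaction *fails* and the attempt
is consumed.  One generation ("actual time step") is N attempts, so each
individual interacts about once per generation.

Defaults follow the standard protocol: `p1 = p2 = r = 1`, a common
sensitivity `k = k_A = k_B = k_C`, `L = 300`.  `m` is always derived, never
set, and may exceed 1: it only enters the normalized probabilities.

## Parameters that matter

| parameter | meaning | default |
|---|---|---|
| `L` | lattice side (even; N = L^2 sites) | 300 |
| `M` | mobility; `m = 2 M N` exchange rate | 1e-5 |
| `k` | territorial sensitivity of intraspecific competition | 0 |
| `p1`, `p2`, `r` | predation / intraspecific / reproduction rates | 1 |
| `T_max` | run length in generations | N |
| `empty_frac` | initial vacancy probability per site | 0.25 |
| `intraspecific_mode` | territorial or traditional | territorial |
| `actor_sampling` | site or occupied (see below) | site |

With `k = 0` the intraspecific channel is off and the model reduces exactly
to the classic three-species spatial game, with its well-known mobility
transition: coexistence below a critical mobility M_c ~ 4.5e-4, a single
surviving species above it (probed at the conventional horizon T = N).

## Two deliberately documented clock choices

**Failed attempts consume time.**  A drawn-but-inapplicable reaction counts
toward the N attempts of the generation.  This makes large `k` dilute all
other reactions away from the territorial boundary (where intraspecific
pairs are rare), which is part of the mechanism slowing genus extinction.

**Actor sampling defaults to all sites.**  The actor of an attempt is drawn
uniformly over all N sites; drawing a vacancy wastes the attempt
(`actor_sampling = "site"`).  The alternative, drawing uniformly over
occupied sites, is available as `"occupied"`.  The two are nearly identical
at the ~5% vacancy typical of territorial-mode quasi-equilibrium, but they
diverge strongly in traditional mode at large k, where uniform intraspecific
mortality drives the density down to ~0.2: occupied-only sampling then gives
every survivor ~5x more attempts per generation, which accelerates genus
drift so much that it *reverses* the traditional-vs-territorial ordering of
mean extinction times.  Only the all-sites clock reproduces the documented
behaviour that traditional intraspecific competition delays extinction at
least as much as the territorial form at every k, so it is the default.

## Observables

**Survival states** (`summarize_lattice()`).  A species is alive iff either
genus has positive count.  Beyond the five canonical labels
(full/reduced coexistence, two species extinct, uniform, all dead) the
classifier needs two conventions the canonical set leaves open: exactly two
species alive is reported as `one_species_extinct`, and three species alive
with four or five genus labels counts as `full_coexistence`
(`reduced_coexistence` is reserved for exactly one genus per species).

**Extinction times** (`extinction_time()`).  Two first-crossing definitions,
matching how extinction manifests in the two mobility regimes:
*low_mobility* — the first generation at which every species has lost at
least one genus (the system has collapsed to a single-genus game);
*high_mobility* — the first generation at which two whole species are gone.
Extinction runs record densities every generation and stop at the event, so
crossings are exact at generation resolution.  Runs that never reach the
event are censored at the configured horizon and enter ensemble means at the
censoring value (with `n_censored` always reported).  A trajectory that
neither reaches the event nor the horizon yields an explicit
`"undetermined"` status, never a silent number.

**Interface width** (`interface_width()`).  For each column j, P(1,j) is the
row of the genus-1 individual (A1, B1, C1 pooled) nearest the boundary from
its own side — or deepest into territory 2 if any genus-1 individual has
invaded; P(2,j) is the mirror image for genus 2.  The column width is
I_j = P(1,j) - P(2,j) if positive, else 0, and W = sum_j I_j / L.  W is the
mean interpenetration depth of the two territory classes in row units.
Conventions the definition leaves open, fixed here:

* *Scan window.*  To avoid the periodic top/bottom boundary only the central
  third of rows is scanned (rows 101..200 at L = 300; generally L/3 rows
  split evenly about the interface).
* *Empty columns.*  A column with no genus-1 (or genus-2) individual in the
  window contributes I_j = 0.  The denominator L is unconditional, so every
  column must contribute; 0 is the conservative "no measurable
  interpenetration" choice.
* *Coordinates are rows.*  Positions are measured across the interface,
  i.e. by row index, and W is in lattice-row units.

A deliberately naive cell-by-cell oracle (`interface_width_oracle()`) ships
with the package and the test suite asserts exact agreement on randomized
fixtures.

## Experiments harness

`sweep_spec()` + the `sweep_*` / `phase_scan_mobility()` functions run
replicated sweeps with one seed per (value, replicate) cell,
`base_seed + (i-1)*replicates + (j-1)`, all recorded, so any row is
replayable in isolation.  Aggregates report mean, standard error (sample sd
divided by sqrt(n); 0 when n = 1), n and n_censored, and recompute exactly
from the per-replicate rows.  Monotonicity claims are tested with a
one-sided Kendall rank-correlation trend test on the per-replicate
(value, measurement) pairs, which is far better powered at 20-30 replicates
than pairwise standard-error overlap; the extinction-time definition is
always chosen explicitly in the spec, never inferred from M.  The
coexistence-probability transition midpoint is the 1/2-crossing of a
binomial logistic fit of the replicate outcomes on log10(M), which pools the
whole grid and is stable at modest replicate counts; when the fit
degenerates (complete separation, upward slope, crossing outside the grid)
the estimator falls back to linear interpolation of the first 0.5-crossing
of the observed probabilities.

## Randomness and determinism

Each run owns one xoshiro256++ stream seeded (via splitmix64) from
`config$seed`; initialization and the per-attempt draws (actor, direction,
event type, intraspecific loser coin) consume from it in that fixed order.
A run is therefore a pure function of its validated config; the tests assert
bit-identical trajectories on repeated runs.  Ties and degenerate inputs:
simultaneous satisfaction of both extinction definitions at one generation
reports that generation under each definition independently; runs stop early
once at most one label is alive (no subsequent event can change the label
composition qualitatively); an all-empty lattice terminates with an
`all_dead` status instead of looping.

## What the initial state is, and is not

The initializer draws each site independently: vacancy with probability 1/4,
otherwise one of the three territory-appropriate species labels uniformly
(~N/8 of each of the eight drawn states).  The 1/4 vacancy fraction is a
convention of the classic model family — "three species or vacancies
randomly placed" — not a measured quantity; it is exposed as `empty_frac`.
The generator emulates the stated world of the model (well-mixed random
initial conditions, sharp territorial split); it does not emulate anything
about real ecological landscapes — structured habitats, correlated initial
clustering, unequal abundances — so a green trend test establishes a
property of this model class at the simulated sizes, not a statement about
field populations.

## Reduced-scale testing

The reference experiments are L = 300 with horizons up to 810,000
generations and 30 replicates — hours to days of CPU.  Those protocols ship
as JSON configs under `inst/configs/` (marked beyond desk scale) but the
automated acceptance tests run reduced versions sized for minutes on one
CPU: the classic-limit phase check and the mobility scan at L = 100
(T = N = 10,000), interface-width sweeps at L = 102 (t = 1000), and the
extinction-time sweeps at L = 48 with censoring at 60,000-80,000
generations.  Extinction times grow roughly with N, so absolute values at
desk scale are a factor ~40 below the L = 300 numbers; the claims under
test — trend directions, regime fractions, the M_c bracket within its
finite-size tolerance — are the size-robust ones.  Thresholds are never
relaxed to compensate: a reduced-scale run either clears the stated bar or
fails.

## Known limitations

* Square lattice, von Neumann neighbourhood, exactly two equal territories;
  no Moore/hexagonal variants, no more than two territories.
* Random sequential updating only (no synchronous automaton, no
  continuous-time Gillespie scheduling).
* No mutation, no empty-site decay, symmetric interspecific rates only.
* The interface statistic measures mean interpenetration depth, not
  roughness scaling; no spiral-wavelength or correlation-length observables.
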