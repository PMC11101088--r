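---
title: "Modelling the ecology of aggregative multicellularity on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ecology of aggregative multicellularity on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggsim)
```

## The model

`aggsim` simulates two clonal cell lineages — cooperators and defectors
(cheaters) — on an `M x M` lattice folded into a torus. Cooperators
constitutively express adhesive molecules: they can initiate association
(adhesion) links with Moore-adjacent cells and pay a higher metabolic cost
for it (`c_C = 10` versus `c_D = 8` resource units per update). Defectors
cannot initiate adhesion but may be bound as acceptors. The two types never
interconvert; there is no mutation. Each lattice site holds at most one
cell plus a local, non-diffusing resource stock (`r0 = 100` units at the
start of a habitat).

Time advances by asynchronous single-cell updates: a uniformly random cell
is selected, and its state is updated in a fixed sub-step order:

1. **metabolism** — subtract `c_C` or `c_D`; at energy 0 or below the cell
   starves and is removed;
2. **consumption** — transfer `min(site resource, uptake)` from the site to
   the cell (strict conservation; nothing is created or destroyed);
3. **division** — if energy exceeds the barrier `d = 190`, draw one of the
   8 directions; an empty target is colonized with probability `S = 0.7`,
   an occupied one with `S * O` (`O = 0.3`), destroying the resident. Both
   daughters receive half the parent's energy; the daughter starts
   link-free and inherits the parent's type;
4. **association** — a cooperator links, with probability `A_C = 0.95`, to
   one uniformly chosen occupied neighbour not already linked to it;
5. **dissociation** — a cell that did not take part in association this
   update drops its links with probability `D = 0.3`;
6. **movement** — an unassociated cell picks one of 9 equally likely options
   (8 directions or stay); relocation into an empty site costs `m`;
   associated cells are immobile;
7. **predation** — with size-dependent selection enabled, the cell is
   captured with probability `P = 1 / (N_a + 2)^s`, where `N_a` is its
   current associated-neighbour count (0–8). Smaller `s` means stronger
   predation; aggregated cells are effectively larger than the predator's
   prey range and nearly immune.

The habitat alternates between resource-rich and resource-poor periods.
While total resource is at or above `R = 400 000` (40% of the initial
1 000 000), cells grow. The first update at which total resource falls
below `R` triggers instantaneous propagule formation: a subpopulation is
selected under one of six colonization mechanisms and placed into a fresh
habitat (resource reset to `r0` everywhere, colonist energies reset to
`e0`, all links cleared). Everything not in the propagule dies.

The six mechanisms (labels as used throughout):

* **A `none`** — no colonization; the population is doomed once resource
  runs out.
* **B `random_dispersion`** — `N_P = 100` cells sampled uniformly; each
  keeps its coordinates in the new habitat.
* **C `random_refuge`** — the same sample packed in random arrangement into
  one `propagule_edge x propagule_edge` block (positions discarded).
* **D `random_fragmentation`** — a uniformly placed 10 x 10 window, redrawn
  until non-empty; its cells transfer with their spatial pattern preserved
  (population must exceed `min_pop_for_fragmentation = 10`).
* **E `agg_dispersion`** — the window is centred on a uniformly chosen cell
  among those with maximal `N_a` (the core of a strongest aggregate); the
  colonists are scattered on arrival.
* **F `agg_propagule`** — as E, but the internal spatial pattern is
  preserved on arrival.

By default every mechanism requires at least one living cooperator
(adhesion is what builds a fruiting body); `require_cooperator = FALSE`
lifts this for the random mechanisms.

## Parameters

| name | default | unit | meaning |
|---|---|---|---|
| `T` | 3e7 | updates | simulation length |
| `M` | 100 | sites | lattice edge |
| `N_P` | 100 | cells | propagule size (sampling mechanisms) |
| `propagule_edge` | 10 | sites | transfer window edge |
| `r0` | 100 | resource | initial per-site resource |
| `R` | 400 000 | resource | scarcity threshold |
| `s` | 5 | — | predation exponent (or `"off"`) |
| `e0` | 100 | resource | initial / colonist energy |
| `c_C`, `c_D` | 10, 8 | resource/update | metabolic costs |
| `d` | 190 | resource | division barrier |
| `S`, `O` | 0.7, 0.3 | prob. | division, overwrite |
| `m` | 0.875 | resource | relocation cost |
| `A_C`, `A_D` | 0.95, 0 | prob. | association |
| `D` | 0.3 | prob. | dissociation |
| `uptake` | 100 | resource/update | consumption cap (see below) |
| `n0_C`, `n0_D` | 200, 200 | cells | founders (4% occupancy) |

Three printed sources of these values conflict internally, and we fixed the
defaults once: `O = 0.3` and `m = 0.875` (the tabulated defaults; the
alternatives 0.5 and 8 appear in prose) and `T = 3e7` (the prose value; the
tabulated 3e8 is inconsistent with the stated number of lattice sweeps
under either reading). All three remain configuration knobs.

## The uptake rule

How much resource a cell consumes per update is the one genuinely
under-determined rule of the model, and it controls everything. Our default
is `uptake = r0`: a feeding cell takes all resource present at its site in
one update.

The reasoning is mechanistic. An associated cell is immobile, so all the
energy it can ever gather before dissociating comes from its own site. A
site starts with `r0 = 100` units; a cell that drains it over `n = r0/u`
updates pays `c * n` in metabolism along the way, so its maximal net gain is
`r0 - c * r0/u`. For a cooperator (`c = 10`) this reaches the `+90` needed
to cross the division barrier from `e0 = 100` only when `u >= r0`. With any
substantially smaller cap (say `u = 20`, net yield 50), no aggregated cell
can ever divide, aggregates cannot grow or even sustain themselves, the
population stays a dilute gas of wanderers (mean occupied-neighbour counts
near 1), and aggregation-based colonization degenerates — the propagule
window lands on nearly empty space. Under `uptake = r0`, aggregates grow
from within (well-fed daughters divide in place, overwriting neighbours),
deplete their cores, and form the characteristic rings with starved
centres; the strongest-aggregate window then carries a cooperator-enriched,
pattern-preserving propagule, which is the point of the whole exercise.

The cap remains exposed: `update_cells()` and `run_simulation()` honour any
`uptake`, and `scripts/acceptance.R` reports the sensitivity directly — it
re-runs the aggregation-based-dispersion condition with the cap lowered to
20 (`coop_survival_agg_dispersion_predation_uptake20_pct`), where
cooperator survival drops from ≥ 90% of replicates to well under half. We
therefore treat the capped-uptake regime as a degenerate corner of the
design rather than its centre.

## What the simulations reproduce — and what they do not

The package's own replication battery (the acceptance tests and
`scripts/acceptance.R`) runs the six-mechanism experiment at a reduced
scale — `M = 50`, with `R`, `N_P`, `T` and the founder counts scaled by
lattice area and the window edge by lattice edge, so occupancy (4%), the
scarcity fraction (40%) and the propagule's share of the lattice (1%) are
preserved — with 20 seeded replicates per condition, plus the
colonization-count comparison at the full default scale. At these settings
the suite reproduces:

* defector fixation in the homogeneous environment without predation, in
  every replicate;
* cooperator survival under aggregation-based dispersion (E) in ≥ 90% of
  replicates, with and without predation;
* the failure of random dispersion and refuge (B, C) to keep cooperators
  alive without predation (0% survival);
* rare cooperator survival (≤ 5%) under aggregation-based propagule
  formation (F) without predation;
* more colonization events under random dispersion than under any
  structure-preserving mechanism, with refuge and fragmentation
  indistinguishable.

Two quantitative effects of the original experiments are **not**
reproduced, and their acceptance tests are left failing rather than
weakened: the large predation-driven boost of cooperator survival under
mechanism F (and under no colonization), and the absolute colonization
counts (≈ 21 and ≈ 11 events for B and F). In our kinetics the predation
hazard of a solitary cell (`1/32` per own update at `s = 5`) is always an
order of magnitude below its division rate, so individual selection only
nudges outcomes (our runs show 10% versus 0–5% survival where the original
reports near-certain versus rare survival). We found no uptake cap, no
dissociation scope, and no movement-cost reading that closes this gap
without breaking the reproduced results above: slow-division regimes in
which predation would dominate also kill the dilute founding population
before any aggregate can assemble. The discrepancy is documented here
deliberately; resolving it would require the original implementation's
consumption rule, which its description does not pin down.

## Numerical and design choices

* **Coordinates** are 1-based `(row, col)` in R; the compiled engine uses
  0-based linear indices. The torus wraps by modular arithmetic.
* **Determinism.** All randomness — initial placement, every sub-step draw,
  propagule sampling — flows through R's RNG in a documented call order, so
  a `(parameters, seed)` pair replays bit-exactly. The pure-R reference
  implementation of the update rule consumes the identical stream, and the
  test suite asserts bit-identical habitats after thousands of interleaved
  updates. The occupied-cell index is maintained with canonical ordering
  (increasing site order at habitat construction, append on birth,
  swap-remove on death) in both implementations so that "pick a uniform
  cell" consumes a single draw.
* **Scarcity detection** is exact: the engine tracks total resource
  incrementally and tests the threshold after every update, so colonization
  triggers at the precise crossing update.
* **Dissociation scope.** Whether one dissociation event breaks one link or
  all of a cell's links is under-determined; the default breaks all (the
  cell detaches and becomes mobile, matching "unassociated cells can
  move"), `dissociation_mode = "single"` breaks one.
* **Window centring.** The transfer window has even edge 10, so "centred"
  is ambiguous; the window spans rows `[r - 5, r + 4]` (and likewise for
  columns) around the chosen centre. Pattern-preserving arrivals anchor the
  window's top-left corner at the lattice centre — on a torus any fixed
  anchor is equivalent.
* **Early stopping.** Once defectors are extinct they can never reappear,
  so the run may stop and score as cooperator fixation; once cooperators
  are extinct under a cooperator-requiring mechanism, the run ends at the
  next scarcity event (the population cannot colonize and is doomed). Both
  rules are on by default and toggleable. The terminal cooperator ratio is
  measured at the last moment the population was non-empty, so runs that
  starve to extinction are classified by their final survivors.
* **Seed splitting.** Replicates and sweep grid points derive their seeds
  from a base seed by a counter-based affine map modulo `2^31 - 1`, keeping
  batches independent and reproducible from one integer.
* **Movement cost** is charged only on actual relocation; choosing "stay"
  (or bouncing off an occupied target) is free.
* **Initial placement** uses exact founder counts by default
  (`placement = "poisson"` draws them), sampling distinct sites uniformly.

## What the generator emulates, and what passing tests show

All inputs are synthetic: the initializer lays down a uniform resource
field and a uniformly scattered founding population, which is the model's
own definition of a fresh habitat, not an approximation of measured data.
Real microbial systems differ in ways the model deliberately ignores:
nutrient diffusion and sharing, chemotactic aggregation cues, motile
aggregate stages, explicit predator dynamics with saturation, mutation and
re-invasion of cheaters, and more than two genotypes. Passing tests
therefore certify the internal consistency of this idealized ecology — its
conservation laws, geometry, mechanism contracts and reproducibility — and
the qualitative group-selection phenomenology described above; they are not
evidence about any particular organism.

## Problem sizes

The unit suite exercises lattices of edge 5–20; the invariant oracles run
10 000 updates on `M = 10`; the replication battery uses 20 replicates per
condition on `M = 50` and 20 full-scale (`M = 100`) replicates per
mechanism for the colonization counts. These sizes were chosen so the
entire suite completes in minutes while every stochastic assertion retains
a ≥ 4.5-sigma margin at its Monte-Carlo sample size.
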