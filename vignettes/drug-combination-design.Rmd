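---
title: "Designing selective drug combinations on metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing selective drug combinations on metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synflux)
```

## The problem

A drug that inhibits a metabolic enzyme removes reactions from a cell's
stoichiometric network. Because metabolism is highly redundant, blocking a
disease-relevant reaction often requires several drugs acting together — a
synergism that cannot be predicted from the single-drug effects — and a
therapy is only useful if, besides being effective, it leaves the rest of
metabolism as intact as possible. `synflux` searches the space of drug
subsets for the combination that blocks a chosen *objective reaction*
while minimizing a side-effect score, without enumerating the
exponentially many subsets.

## Model and side-effect score

The cell is a stoichiometric network at steady state: fluxes `v` satisfy
`S v = 0` with `0 <= v_j <= U_j` after every reversible reaction has been
decomposed into an irreversible forward/reverse pair (the pair is recorded
so all reporting counts a reversible reaction once). Drug `k` carries a
binary `d_k` (`d_k = 0` when the drug is used) and completely shuts its
target reactions: `v_j <= U_j d_k` for every target `j`.

The side effect of a drug set `D` is

```
sigma(D) = #{reactions no longer able to carry flux} + sum_k beta_k (1 - d_k)
```

where a reaction counts as stopped when its maximal attainable flux falls
below an activity threshold `epsilon`, and `beta_k = beta_bar * (number of
non-metabolic targets of drug k)` charges each used drug for the targets
the metabolic network cannot see. `beta_bar` is estimated on the network
itself: inhibit each catalogued (drug, target) pair alone and average the
number of newly stopped reactions. Averaging over (drug, target) pairs
(rather than over drugs) uses every single-target inhibition exactly once;
this is a deliberate reading of an ambiguous convention and is the
package's fixed choice. Reactions that cannot carry flux even with no
drugs (baseline-blocked) are never charged to a drug, and the objective
reaction itself is excluded from the count — an always-present constant
would not change the optimizer.

## The bilevel program and its single-level reformulation

Finding the optimal combination is bilevel: an outer problem chooses `d`
to minimize `sigma`, subject to the *inner* linear program — maximize the
objective flux over the drug-restricted flux space — attaining zero. The
inner LP is replaced by its dual feasibility conditions plus the equality
of primal and dual objectives (strong duality), collapsing everything into
one mixed-integer linear program:

* primal block: `S v = 0`, capacities, `v_j <= U_j d_k`, `v_obj = 0`;
* dual block: `S^T mu + lambda + sum_k delta_jk >= c_j` with `c` the inner
  objective, `mu` free, `lambda, delta >= 0`;
* strong duality: `c^T v = sum_j U_j lambda_j + sum_{jk} U_j z_jk`, where
  each bilinear `delta_jk d_k` is replaced exactly by `z_jk` with the
  big-M bounds `0 <= z <= delta_max d` and
  `delta - delta_max (1 - d) <= z <= delta`;
* stopped-reaction indicators: `epsilon y_j <= v_j <= U_j y_j`, with
  `y_f + y_r <= 1` for each reverse pair so an active reversible reaction
  is not double-counted;
* outer objective
  `sum_j alpha_j (1 - y_j) + sum_k beta_k (1 - d_k) - b sum_k d_k`.

One `delta` (and one `z`) exists per (target reaction, drug) pair — the
indexing under which the inner dual is exact. The `-b` term (`b`
small) rewards leaving a drug out, so optimal sets never contain
redundant drugs; it also acts as the tie-break toward smaller
combinations. Reported side effects always exclude this term and are
recomputed by the independent oracle (below).

### Reversible reactions: net-flux semantics

Two subtleties of the split formulation are handled deliberately:

* A forward/reverse pair can always run as a futile cycle
  (`v_f = v_r > 0` cancels in `S v = 0`). Whether a reversible reaction
  "can carry flux" must therefore be judged on *net* directional flux:
  the oracle pins the twin to zero when maximizing a direction. The MILP
  needs no correction — `U_j y_j >= v_j` forces `y = 1` on *any* positive
  flux, so a futile cycle would set both `y`s and violate
  `y_f + y_r <= 1`; its indicators already measure net flux.
* For a *reversible objective*, a single dual block over the summed pair
  flux would see the futile cycle as unbounded objective flux and declare
  every such objective unblockable. The package instead appends one dual
  certificate block per direction with inner objective `e_dir - e_twin`
  (net flux), which is equivalent to requiring each direction blocked
  with the twin at rest. An irreversible objective reduces to the single
  classical block.
* In the outer objective a fully blocked pair contributes 2 and an active
  one 1 (exactly one direction can have `y = 1`), i.e. a constant +1 per
  pair relative to the collapsed count — an offset that cannot change the
  argmin.

## The blocking oracle, verification, and the simultaneity gap

All reported numbers come from an independent LP oracle, not from the
MILP's own variables: `blocked_reactions()` maximizes each reaction's
(net) flux separately, `side_effect()` assembles `sigma`,
`brute_force_optimum()` enumerates subsets outright at test scale. Every
MILP solution is post-verified: an inner LP re-checks that the objective
cannot reach `epsilon` under the returned drugs (a weak-duality
certificate that the reformulation did its job), and the `y`-implied
stopped set is compared reaction-by-reaction with the oracle.

The two counts can differ legitimately: the MILP counts reactions active
*in one simultaneous flux vector*, the oracle counts reactions *each
individually* able to carry flux. Under a tight shared capacity two
branches may each sustain `epsilon` but not both at once — the
*simultaneity gap*. `bottleneck_fixture()` constructs exactly this (a
0.15-capacity uptake feeding two branches at threshold 0.1) and
`verify_solution()` flags it; on generated instances with generous
capacities the gap never bites, which the acceptance suite asserts.

## Enumeration of suboptimal combinations

After each optimum `D*` the exclusion cut `sum_{k in D*} d_k >= 1` is
added: at least one drug of `D*` must stay unused, which forbids `D*` and
all its supersets (a superset can never have a smaller side effect).
Iterating until infeasibility yields the solution hierarchy; side effects
come out non-decreasing. The whole-network screen classifies each
objective reaction by comparing the best multi-drug combination (the MILP
restricted to at least two used drugs) with the best single drug:
`new_inhibition`, `more_selective`, `less_selective`, `single_only`, or
`unblockable`.

## Two-network selectivity

To hit a target cell while sparing a reference cell, one MILP couples two
networks through the shared drug binaries: the target network carries the
full primal/dual/strong-duality machinery forcing its objective to zero;
the reference network contributes only a primal flux block and stopped
indicators, whose count is minimized. Preservation of the reference
metabolism is *soft* — a hard constraint would exclude exactly the
solutions of interest, and reported selective solutions do carry nonzero
reference side effects. The objective's corresponding reference reaction
(when the correspondence maps it) is excluded from the count; drugs act
on their targets in both networks simultaneously. The additional-target
screen deletes one reaction at a time from both networks and re-solves,
flagging deletions that are lethal alone, enable otherwise impossible
inhibitions, or improve selectivity.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.1 | flux (arbitrary units) below which a reaction counts as stopped; must sit below the smallest positive capacity |
| `b` | 0.001 | bonus per unused drug; excludes redundant inhibitions, breaks ties toward fewer drugs; far below the granularity of `sigma` differences, so it cannot reorder genuinely different solutions |
| `delta_max` | 1000 | big-M bound on the coupling duals; a post-solve check warns if a meaningful dual comes within 1% of it |
| `alpha_j` | 1 | weight of a stopped reaction; unit weights make the first term of `sigma` a plain count |
| `default_cap` | 1000 | finite replacement for infinite bounds (duality needs finite capacities) |
| `beta_bar` | estimated | mean stopped-reaction count per single metabolic inhibition; can be fixed explicitly |

Numerical conventions: blocked means `max flux - 1e-6 < epsilon` (strict,
with the LP feasibility tolerance absorbed); the MILP runs at zero
relative MIP gap; binaries are read at the 0.5 threshold; the synergy
ratio `100 |Y| / sigma` is truncated (not rounded) to one decimal,
matching the convention of the published synergism tables.

## What the generated instances emulate — and what they do not

`random_instance()` builds branched pathway DAGs: ordered metabolites,
uptakes at the head, conversions from earlier to later metabolites
(occasionally two substrates or coefficient 2), exports wherever a
metabolite would dead-end, capacities drawn from 5–15 against
`epsilon = 0.1`, a configurable fraction of reversible conversions, and
drugs with 1–3 random targets and 0–2 non-metabolic targets. The defaults
(12 metabolites, 16 conversions, 6 drugs, 15% reversible) keep exhaustive
subset search tractable as the test oracle. These instances exercise
redundancy, reversibility, synergy and enumeration, but they are not
genome-scale reconstructions: no compartments, no cofactor coupling, no
loops spanning many reactions, and capacities far from the threshold (so
the simultaneity gap — covered separately by the bottleneck construction —
does not arise spontaneously). Passing on them shows the optimizer and
oracle agree on the combinatorics; it does not certify biological
predictions on a curated reconstruction.

The validation problem sizes — 50 seeded instances for the
MILP-vs-exhaustive equivalence (about 30 reactions and 6 drugs each), 20
for monotonicity, 10 for the two-network degeneracy — were chosen so the
exhaustive oracle stays exact and the whole suite runs in minutes on one
CPU.

## Known limitations

* Inhibition is all-or-none; dose, IC50 and partial inhibition are out of
  scope, as are kinetic interactions invisible at steady state (e.g.
  drugs acting along one linear pathway).
* `sigma` counts lost reactions, not flux rerouting; it deliberately
  avoids wild-type reference fluxes, which are ill-defined for human
  cells.
* The screen solves one MILP per reaction; at genome scale a dedicated
  solver and warm starts would be needed — the package targets method
  correctness at desk scale and modest networks.
* SBML support covers the common COBRA-style Level 2 and Level 3 fbc
  bound conventions, not the full specification.
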