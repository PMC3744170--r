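# synflux

Optimal selective drug combinations on genome-scale metabolic networks.

## What problem this solves, and for whom

Metabolic diseases and cancers are treated by shutting down specific
metabolic reactions, but single inhibitors are often either unavailable or
unacceptably broad. Because metabolism is redundant, *combinations* of
existing drugs can block a reaction that no single drug stops — a
synergism that depends on network topology and cannot be read off the
single-drug effects — and among the blocking combinations one wants the
most *selective*: the one stopping the fewest other cellular functions.
`synflux` is for computational/systems biologists who work with
constraint-based (flux-balance) models and want to screen an approved-drug
catalog for such combinations, including the anticancer setting where a
tumor network must be hit while a normal-cell network is spared.

## The optimization at the core

With stoichiometric matrix `S`, fluxes `0 ≤ v ≤ U` (reversible reactions
split into irreversible pairs), drug binaries `d_k` (`d_k = 0` = used,
forcing `v_j ≤ U_j d_k` on its targets `j ∈ T_k`), the side effect of a
drug set `D` is

    σ(D) = Σ_j α_j (1 − y_j) + Σ_k β_k (1 − d_k),

where `y_j` indicates reaction `j` still carries flux ≥ ε, and
`β_k = β̄ · #(non-metabolic targets of k)` penalizes what the network
cannot see (`β̄` = mean number of reactions stopped per single metabolic
inhibition). The optimal combination solves the bilevel program

    min_D  σ(D)   subject to   max { v_obj : v ∈ H(D) } = 0,

which is collapsed into a single MILP by appending the inner LP's dual
feasibility (`SᵀΜ + λ + Σ δ ≥ c`) and the strong-duality equality
`cᵀv = Σ U_j λ_j + Σ U_j z_jk`, with each bilinear `δ_jk·d_k` replaced
exactly by `z_jk` under big-M bounds (`0 ≤ z ≤ δ_max d`,
`δ − δ_max(1−d) ≤ z ≤ δ`). Defaults: `ε = 0.1`, `b = 0.001` (the
small per-unused-drug bonus excluding redundant inhibitions),
`δ_max = 1000`, `α_j = 1`. Suboptimal combinations are enumerated by
adding the exclusion cut `Σ_{k∈D*} d_k ≥ 1` after each optimum until the
program becomes infeasible. Every solution is re-verified by an
independent LP oracle (inner-LP certificate + per-reaction blocked-set
comparison). See the vignette `vignettes/drug-combination-design.Rmd` for
the full formulation, the net-flux treatment of reversible reactions, and
the two-network (target-vs-reference cell) variant.

## Worked example

The bundled ten-reaction network has an uptake, a gateway reaction `v2`,
two parallel routes (through `v4` and `v7`) to the precursor of the
objective export `v10`, and drugs at `v2`, `v4`, `v7`:

```r
library(synflux)
toy <- figure1_toy()
sol <- solve_optimal_combination(toy$model, toy$catalog, "v10")
print(sol)
#> synergy solution [ optimal ] objective: v10
#>   drugs used: drug_v4 + drug_v7
#>   sigma (oracle): 4  sigma (MILP): 5
verify_solution(toy$model, toy$catalog, sol)
#> verification: PASS
#>   inner LP max objective flux: 0 (blocked)
#>   stopped count MILP/oracle: 4 / 4
prof <- synergy_profile(toy$model, toy$catalog, sol$used_drugs)
print(prof)
#> synergy of { drug_v4, drug_v7 }: |Y| = 2
synergy_ratio(sol$sigma_oracle, length(prof$Y))
#> [1] 50
```

Neither `drug_v4` nor `drug_v7` alone stops `v10`, and `drug_v2` stops it
only by killing the entire network (σ = 9); the optimizer finds the
two-drug synergism with σ = 4 (the four reactions `v3, v4, v7, v8`
stopped besides the objective). The synergy set `Y` — reactions no single
drug of the pair stops but the pair does — is `{v8, v10}`, giving the
45%-style selectivity ratio of 50%. Enumerating onward returns the
gateway drug as the (worse) second solution and then proves no further
combination exists:

```r
enumerate_solutions(toy$model, toy$catalog, "v10")
#> [[1]] drugs used: drug_v4 + drug_v7   sigma (oracle): 4
#> [[2]] drugs used: drug_v2             sigma (oracle): 9
```

A command-line wrapper covers the same pipeline
(`solve`, `screen`, `selective`, `add-target`, `cluster`):

```sh
Rscript inst/scripts/synflux.R solve --model net.tsv --drugs drugs.tsv \
    --objective v10 --out results/
```

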