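# fluxmodes

Exact enumeration of elementary flux modes (EFMs) and elementary flux
vectors (EFVs) in metabolic networks, in pure R with exact rational
arithmetic end to end.

## The problem

A metabolic network with stoichiometric matrix **N** (metabolites ×
reactions) operates at steady state when **N v = 0**, with irreversible
reactions constrained to **v ≥ 0**. After splitting each reversible
reaction into two opposed irreversible ones, the feasible flux
distributions form the *flux cone*

```
FC = { r : N r = 0,  r ≥ 0 }.
```

Its extreme rays — once the artifactual forward/backward "two-cycle"
modes are discarded — are the **elementary flux modes**: the
support-minimal pathways the network can run, from which every
steady-state flux is a nonnegative combination. Adding inhomogeneous
constraints (uptake caps, maintenance demands, e.g. `R_GlcUp ≤ 10` or
`R_ATPM ≥ 3.15`) turns the cone into a *flux polyhedron*

```
P = { x : C x = d,  E x ≥ f,  x ≥ 0 }
```

whose extreme points are the **elementary flux vectors** and whose
extreme rays remain EFMs. Homogenizing with a slack coordinate ζ embeds
P into a pointed cone one dimension higher (`G = (C | −d)`,
`H = ((E | −f); (I | 0); ζ ≥ 0)`), recovering P at ζ = 1, so vertex
enumeration and extreme-ray enumeration are interchangeable. A further
slack embedding `N = ((C, 0, −d); (E, −I, −f))` expresses the same
polyhedron as a flux cone, the formulation the package uses by default.

`fluxmodes` covers the full workflow around this geometry:

* **model_io** — SBML (L2/L3 + fbc) reading/writing with digit-exact
  rational stoichiometry, efmtool-style input files, reaction-bound
  tables, and LP-based consistency preprocessing (blocked-reaction
  removal, direction fixing).
* **compress** — loss-free stoichiometric compression (dead-end removal,
  kernel-blocked removal, enzyme-subset merging, conservation-relation
  removal) with an invertible record, so enumerated modes decompress
  exactly onto the original reactions.
* **geometry** — the three H-representations (polyhedron, polyhedral
  cone, flux cone), all transformations among them, redundancy removal by
  exact LP, and lrs `.ine`/`.ext` file interop.
* **ddm_engine** — the binary null-space double description method:
  kernel start, pairwise combination of adjacent positive/negative rays,
  bitset zero-set pruning.
* **rs_engine** — sequential lexicographic reverse search with symbolic
  perturbation, enumerating vertices and rays basis by basis, with
  per-vertex emission multiplicities under degeneracy.
* **postprocess** — two-cycle removal, signed merging of split pairs,
  exact deduplication, yield and support-distance analytics.
* **fixtures** — permutahedra, Birkhoff polytopes, a toy branched
  network, seeded random flux cones, nested uptake series.
* **cli** — a `pre → enumerate → post → analyze` subcommand pipeline
  (`fm_main()`, also installed as a thin `exec/fluxmodes` script).

Everything is computed over exact rationals (numerator/denominator pairs
on IEEE doubles with hard overflow guards), so no result ever depends on
a floating-point tolerance.

## Worked example

The toy branched network — metabolites A, B, C; uptake `R1: → A`,
branches `R2: A → B` and reversible `R3: A ⇌ C`, exports `R4: B →`,
`R5: C →` — has exactly two EFMs.

```r
library(fluxmodes)

model <- toy_branch()
cp    <- compress_model(model)                 # loss-free compression
sp    <- split_reversible(cp$model)            # reversible splitting
cone  <- flux_cone(sp$model$S, sp$model$reaction_ids)

raw   <- enumerate_efms_ddm(cone)              # double description
modes <- filter_two_cycles(raw, sp$record)     # drop fwd/rev artifacts
modes <- merge_split_pairs(modes, sp$record)   # back to signed fluxes
efms  <- decompress_modes(modes, cp$record)    # original reaction space
efms
#> ModeSet: 2 modes (2 efm, 0 efv) over 5 reactions
rq_to_double(efms$values)
#>      [,1] [,2] [,3] [,4] [,5]
#> [1,]    1    0    1    0    1
#> [2,]    1    1    0    1    0
compute_yields(efms, "R1", "R4")$yields
#>   mode yield value
#> 1    1     0     0
#> 2    2     1     1
support_distance_matrix(efms)
#>      [,1] [,2]
#> [1,]    0    4
#> [2,]    4    0
```

Row 1 is the `R1→R3→R5` route through C, row 2 the `R1→R2→R4` route
through B; their yields of `R4` on the substrate `R1` are 0 and 1, and
the two pathways differ in 4 of 5 reactions. The same result comes out
of the shell pipeline:

```sh
Rscript exec/fluxmodes pre toy.xml --out pre/ --formulation flux_cone
Rscript exec/fluxmodes enumerate pre/flux_cone.ine --ext out.ext --engine ddm
Rscript exec/fluxmodes post out.ext --transform pre/transform_record.json \
        --compression pre/compression_record.json --out post/
Rscript exec/fluxmodes analyze post/modes.tsv --out analysis/ \
        --substrate R1 --target R4
```

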