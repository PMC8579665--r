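---
title: "Exact enumeration of elementary flux modes: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact enumeration of elementary flux modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmodes)
```

## The model

A metabolic network is a stoichiometric matrix $N \in \mathbb{Q}^{m
\times n}$ (metabolites by reactions) with a reversibility flag per
reaction and, optionally, flux bounds (conventionally mmol/gDW/h; the
package stores but does not interpret units). At steady state the flux
vector $v$ satisfies $N v = 0$; irreversible reactions additionally
satisfy $v_i \ge 0$. After replacing every reversible reaction by two
opposed irreversible columns, all variables are nonnegative and the
feasible set is the flux cone $FC = \{r : N r = 0,\ r \ge 0\}$, a
pointed polyhedral cone. Its extreme rays, minus the *two-cycle* modes
that pair the forward and backward halves of one formerly reversible
reaction, are the elementary flux modes (EFMs): the support-minimal
steady-state pathways. No reaction can be dropped from an EFM's support
without forcing the whole flux to zero, and every steady-state flux is a
conic combination of EFMs.

Inhomogeneous constraints — substrate-uptake caps, maintenance demands —
generalize the cone to a flux polyhedron
$P = \{x : Cx = d,\ Ex \ge f,\ x \ge 0\}$. Its extreme points are the
elementary flux vectors (EFVs) and its recession-cone extreme rays
remain EFMs. Two embeddings connect the shapes:

* *homogenization*: a slack coordinate $\zeta \ge 0$ with rows
  $G = (C \mid -d)$ and $H = ((E \mid -f); (I \mid 0); \zeta \ge 0)$
  gives a pointed cone whose $\zeta = 1$ section is $P$ — rays with
  $\zeta > 0$ rescale to vertices (EFVs), rays with $\zeta = 0$ are
  recession directions (EFMs);
* *slack embedding*: one nonnegative slack per inequality row gives the
  flux cone $N' = ((C, 0, -d); (E, -I, -f))$ over $(x, \xi, \zeta)$, so
  any EFM machinery applies unchanged to EFV problems.

Both routes are implemented (`homogenize()`, `to_flux_cone()`,
`dehomogenize()`) and are verified against each other in the test suite;
the flux-cone formulation is the pipeline default because every
downstream consumer (compression records, two-cycle filtering, split
merging) operates naturally in that coordinate system.

## Why exact arithmetic

Extreme-ray identity is a rank condition; a candidate ray is kept or
discarded on an exact zero test. Floating point cannot distinguish "this
$5 \times 7$ minor is singular" from "nearly singular", and enumeration
errors do not average out — a single misclassified candidate changes the
EFM count. The package therefore computes everything over rationals
stored as numerator/denominator pairs of IEEE doubles. Doubles represent
integers exactly below $2^{53}$; every multiplication and addition is
cross-reduced first and *guarded*: any intermediate that could reach
$2^{52}$ raises an error instead of rounding. On the model sizes this
package targets (tens of reactions after compression, coefficients of
small magnitude), guarded doubles never trip; the guard is the contract
that if they ever did, the user gets a hard failure, not a wrong mode
set. The same exactness extends to linear programming: a dense tableau
simplex with Bland's anti-cycling rule answers every
feasibility/optimality question without a tolerance. The
`make_consistent()` interface retains a `tol` argument for compatibility
with float-LP formulations of the same preprocessing, but the exact
implementation ignores it; the flux box constant defaults to $M = 1000$,
the conventional "unbounded" magnitude in constraint-based modelling,
and SBML bounds at or above that magnitude are treated as absent rather
than becoming polyhedron rows.

## Double description engine

`enumerate_rays_ddm()` implements the binary null-space double
description method. Starting from an exact kernel basis of the equality
block (held as free *lines*), it first consumes lines by pivoting them
onto constraints, then enforces the remaining halfspaces one at a time:
rays are partitioned by the sign of the new constraint, each adjacent
(positive, negative) pair combines into the candidate
$r' = v_p\, q - v_q\, p$ on the hyperplane, and a candidate survives
only if no third surviving ray's zero-set contains the pair's common
zero-set — the combinatorial adjacency test. Implementation choices that
matter:

* zero-sets are packed 30 bits per integer word, making the superset
  scan a handful of vectorized word operations per pair;
* a necessary condition filters pairs before that scan: adjacent rays
  share at least $q - 2$ tight constraints ($q$ the kernel dimension),
  checked by vectorized popcount — on the degenerate order-6 Birkhoff
  cone this filter cuts the run from minutes to seconds;
* candidates with identical zero-sets are generated once (hash dedup),
  which in a pointed cone suffices because an extreme ray is determined
  by its tight set;
* constraint values of every ray are cached and updated incrementally —
  a candidate's value row is the same linear combination of its
  parents' rows, rescaled by the integer-normalization factor;
* the processing order takes, at each step, the unprocessed constraint
  minimizing $|Pos| \cdot |Neg|$, the standard heuristic bounding
  intermediate blow-up; a `row_order` override exists and the tests use
  it to confirm the final set is order-independent;
* a configurable `max_rays` guard fails resumably, naming the constraint
  row reached, rather than exhausting memory.

Output rays are scaled to coprime integers and sorted canonically
(support pattern, then exact values), so results are diffable across
runs and engines.

## Reverse search engine

`enumerate_vertices_rs()` enumerates vertices and extreme rays of
$\{t : At \ge b\}$ after eliminating equality rows by exact
substitution. It inverts the simplex method: from the optimum basis,
depth-first, visiting exactly the bases whose deterministic improving
pivot path leads back to the root.

Degeneracy is the crux — a vertex on more than $\dim$ facets has many
bases, and naive traversal would revisit or miss them. The engine
perturbs the right-hand side symbolically, $b_i \to b_i - \eta_i$ with
$\eta = \Lambda\,(\varepsilon, \varepsilon^2, \dots)^\top$, choosing the
perturbation matrix $\Lambda$ *aligned with the initial basis*: basic
rows get unit vectors, each nonbasic row gets its expansion over the
basis plus one fresh higher-order $\varepsilon$. Two properties follow
by construction and are load-bearing. First, the initial basis is
lexicographically feasible outright, so no phase of lex-feasibility
repair is needed. Second, no slack polynomial can vanish identically
(each nonbasic row owns a private $\varepsilon$ power), so the perturbed
polyhedron is *simple*: bases correspond one-to-one to perturbed
vertices and the traversal is a true tree. The objective is the negated
sum of the initial basis rows — making that basis the optimum with
strictly negative reduced costs — plus a symbolic $\delta$-power
perturbation that breaks dual ties, which is what guarantees a *unique*
root even when a degenerate optimum admits several optimal bases (the
square-pyramid apex exercises exactly this in the tests). The initial
vertex itself comes from an exact phase-1 LP followed by a crawl along
null directions of the tight set until the basis has full rank.

Under degeneracy a vertex of the original polyhedron is emitted once per
basis in its cluster; the engine reports this per-vertex multiplicity
(the quantity that distinguishes the polyhedron formulation, where
duplicates occur, from the cone formulations, where output is unique)
and returns each distinct vertex and ray exactly once. No claim is made
of matching any external implementation's emission order or duplicate
counts, which are pivot-rule artifacts; set-correctness is the contract,
and it is checked against an independent basis-subset brute-force oracle
(`brute_force_enumerate()`) on every fixture and on seeded random
polyhedra.

## Compression

Compression operates on the signed, unsplit model, because the
enzyme-subset logic needs direction information. Four steps repeat until
a full pass changes nothing:

1. *dead-end removal* — a metabolite with no producer or no consumer
   (reversible reactions count as both) forces its incident reactions to
   zero; iterated to a fixpoint;
2. *kernel-blocked removal* — reactions whose kernel row is identically
   zero carry no flux in any steady state;
3. *enzyme-subset merging* — reactions with pairwise proportional kernel
   rows carry proportional flux everywhere; each subset collapses to one
   representative column $\sum_j c_j S_j$, with the exact ratios $c_j$
   recorded; a negative ratio between two irreversible members blocks
   the whole subset; the merged reaction is reversible only if every
   member is;
4. *dependent-row removal* — metabolite rows that are linear
   combinations of earlier rows (conservation relations) are removed by
   exact elimination, leaving the kernel untouched.

Every step appends to an ordered record; `decompress_modes()` replays it
backwards, distributing merged fluxes as $v_j = c_j v$ and restoring
removed reactions at zero. The defining property — the decompressed EFM
set of the compressed model equals the EFM set of the original, as
exact normalized vectors — is asserted wholesale in the tests against
the independent minimal-support oracle, which is a stronger and more
portable guarantee than matching any particular tool's compressed matrix
dimensions (tools differ in step order, and published comparisons show
they reach slightly different fixpoints; this package fixes one
deterministic order and proves losslessness instead). Bound tables
translate through the record (`translate_bounds()`): a bound on a merged
member becomes a bound on the representative scaled by $1/c_j$, flipping
direction for negative ratios.

## Oracles and testing strategy

Three independent routes to the same answers anchor the suite:

* `efm_support_test()` / `brute_force_efms()` — the definitional oracle:
  a support is an EFM support iff the kernel of the restricted matrix is
  one-dimensional with a strictly signed generator; enumeration over
  supports of size at most $\mathrm{rank}(N) + 1$ with superset pruning
  and a fraction-free (Bareiss) integer rank filter;
* `brute_force_enumerate()` — basic solutions over all row subsets, for
  vertex/ray problems;
* cross-engine agreement — double description versus reverse search on
  every fixture and a 200-instance seeded random-cone corpus
  ($m \le 6$, $n \le 12$), plus cross-formulation agreement (polyhedron
  versus slack-embedded flux cone) on bounded fixtures.

The random generators are deliberate about determinism: they use a
self-contained Park–Miller stream, so fixtures are bit-identical for a
given seed and never touch or depend on the session RNG. Entries are
small integers in $\{-3..3\}$, sparse, with every row and column
guaranteed a nonzero entry; across seeds the corpus contains both
degenerate and non-degenerate cones (asserted by a scan in the tests).
These synthetic cones emulate the *combinatorial* structure of small
metabolic networks (sparsity, degeneracy, reversibility after signing a
subset of columns) but not their biological organization — no
compartments, no conserved moieties beyond what randomness produces, no
realistic bound magnitudes. Passing tests therefore certify the
algorithms and their bookkeeping exactly; they say nothing about the
scalability wall that genome-scale networks pose, which is intrinsic to
the combinatorial growth of EFM counts.

### Fixture families and problem sizes

The permutahedron of order $n$ (sum linearity plus one inequality per
proper subset) and the Birkhoff polytope of order $n$ (doubly stochastic
matrices) both have exactly $n!$ vertices — the first is simple, the
second highly degenerate, so together they probe both engine regimes.
The routine suite verifies the factorial law through order 6 (720
vertices; seconds for the permutahedron, ~10 s for the Birkhoff cone via
double description) and the reverse-search engine through order 4, the
larger orders being covered by the double description runs. The order-7
Birkhoff polytope (5,040 vertices) and the order-10 permutahedron
(3,628,800 vertices) are generated and structurally checked (63 rows /
49 columns; 1,023 rows / 10 columns) but their full enumerations are
extended runs beyond the routine suite's scale; the order-10
permutahedron in particular is out of reach for an interpreted
double-description inner loop, and its acceptance rests on the factorial
law plus the printed H-structure. Published genome-derived models are
external downloads and are likewise out of the routine suite.

## Known limitations

* The guarded-double rational kernel bounds coefficients by $2^{52}$;
  networks whose compressed kernels need larger integers fail loudly.
  An arbitrary-precision backend would lift this at the cost of speed.
* The reverse-search engine recomputes basis inverses per node
  ($O(d^3)$) rather than maintaining rank-one updates; fine at fixture
  scale, wasteful beyond it.
* Enumeration is single-threaded by design; the algorithms parallelize
  (the reverse-search tree embarrassingly so), but scheduling is out of
  scope here.
* `write_sbml()` requires stoichiometries with exact decimal
  representations (denominators $2^a 5^b$); other rationals round-trip
  through the efmtool-style text files instead.
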