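---
title: "Exact parsimony for small morphological matrices: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact parsimony for small morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsaltans)
```

## Scope and model

`mpsaltans` analyses small matrices of unordered (non-additive) discrete
characters under equal-weights maximum parsimony. The cost model is the
simplest one in cladistics: every transformation between any two states
of a character costs one step, characters are independent, and the score
of a topology is the sum over characters of the minimum number of steps
needed to explain the observed tip states. Nothing probabilistic is
assumed about the evolutionary process; parsimony is used here as an
optimality criterion, exactly as it is applied to morphological
matrices of this size in the systematics literature.

Trees are treated as **unrooted** during all scoring and searching,
because the Fitch count is invariant to root placement. Rooting at a
designated outgroup is applied afterwards, purely for presentation:
character-state changes and verbal claims such as "most basal lineage"
only acquire direction once the outgroup orients the tree. The bundled
data set fixes `willistoni` as that outgroup.

## Scoring: Fitch and Hartigan

For binary (fully resolved) nodes the bottom-up Fitch pass is used: the
node's state set is the intersection of its children's sets when
non-empty, otherwise the union with one step added. Polytomies are
scored with Hartigan's generalisation: the node keeps the states of
maximal frequency among its children's sets and adds (degree − max
frequency) steps. Hartigan reduces exactly to Fitch on binary nodes, and
is exact for multifurcations, so collapsed (polytomous) trees are scored
with the same machinery as binary ones — a property the test suite
checks against brute-force enumeration of all internal assignments.

A missing entry (`?`) enters the pass as the full state set of its
character: it never forces a change, and it is excluded from the
minimum/maximum step bounds below. Gap symbols (`-`) are rejected
outright; a morphological matrix has no alignment-gap semantics.
Polymorphic cells such as `{01}` are not supported — a documented
limitation that keeps the state sets single-symbol and was not needed
for the bundled data.

## Step bounds and ensemble indices

Per character, `m` = (observed states − 1) is the fewest steps any tree
can need, and `g` = (scored taxa − largest state frequency) is the most
steps any tree can force, which equals the character's length on the
star tree. This "star-tree maxsteps" is the convention used by the
standard parsimony programs for the retention index; the test suite
verifies `m ≤ s ≤ g` on arbitrary topologies and that the star tree
attains `Σg` exactly.

Ensemble CI = Σm/L and RI = (Σg − L)/(Σg − Σm) **include uninformative
characters** by default. That choice is deliberate: it is the default of
the common programs and it is the convention under which the bundled
matrix reproduces its published index values. An
`include_uninformative = FALSE` variant exists for comparison but is not
the reference path.

### The truncated-percent rendering

Cladistics papers print CI and RI as integer percentages. On the bundled
optimum CI = 0.875 and RI = 0.90625: rounding would print (88, 91),
truncation prints (87, 90). Only truncation reproduces both published
values simultaneously, so `printed_CI`/`printed_RI` are defined as
⌊100·value⌋ and are never rounded. This convention is inferred from the
numbers, not stated by any source; it is surfaced prominently in the
report objects so a user comparing against differently-rendered output
can see exactly what was applied.

## Exact search

Eleven taxa admit 34,459,425 unrooted binary topologies — large enough
that published analyses used heuristic searches, small enough that an
exact search is comfortable on one CPU. The package therefore makes the
exact search the reference path:

* **Stepwise enumeration.** Taxon k is inserted into every branch of
  every partial tree on the first k−1 taxa; this generates each unrooted
  binary topology exactly once, which makes deduplication unnecessary
  inside the search.
* **Addition order.** Taxa are added in decreasing order of character
  conflict (the number of cells holding a minority state), ties broken
  by input order. Conflict-rich taxa placed early make partial lengths
  grow sooner and pruning fire earlier. The order is deterministic, so
  runs are reproducible without a seed.
* **Bound.** A partial tree is abandoned when its own Fitch length plus
  an admissible completion bound exceeds the current best complete
  length. The completion bound charges one step for every state that
  occurs only among unplaced taxa (computed from non-missing cells so it
  stays admissible). Pruning is strict (`>`), never `≥`, so ties are
  retained and the optimum **set** — not just one optimum — is provably
  identical to exhaustive enumeration. The initial upper bound comes
  from one greedy stepwise-addition tree (ties to the first-scanned
  branch) unless the caller supplies one.
* **Exhaustive mode** disables pruning and is retained as the in-package
  oracle; it refuses more than 11 taxa (configurable) with an explicit
  combinatorial-cost error.

The parsimony ratchet is included as the representative heuristic so
that heuristic behaviour can be tested against a known exact optimum:
random-addition start, hill climbing over all NNI neighbours and then
all SPR neighbours, and ratchet cycles that upweight a random quarter of
the characters twofold before re-climbing under original weights. SPR
(not TBR) is the largest neighbourhood: at these matrix sizes SPR
already reaches the exact optimum in a handful of iterations, and the
simpler move set keeps the implementation auditable. All stochastic
operations take an explicit seed and restore the ambient RNG state.

## Reconstruction ambiguity and change mapping

"Unambiguous optimization" is implemented literally: for each character
the package enumerates **every** most-parsimonious reconstruction
(depth-first over the observed states of the internal nodes, cost-pruned
at the Fitch minimum; enumeration is restricted to observed states,
which cannot exclude any optimal change structure). A change is reported
as unambiguous iff it appears with the same branch and the same
from/to states in every reconstruction. ACCTRAN/DELTRAN are deliberately
not implemented: they are tie-breaking conventions, and the analysis
this package reproduces used unambiguous changes only.

Changes are classified for figure-style annotation at character level:
characters whose observed steps exceed their minimum (`s > m`)
contribute homoplasies; a perfectly fitting character contributes an
autapomorphy where its derived state marks a single taxon and a
synapomorphy where an unambiguous change subtends two or more taxa.
This character-level rule reproduces the black/white-circle dichotomy of
a printed cladogram without attempting to read unreproducible artwork.

Because a two-child root is a scoring artefact, reconstructions are
enumerated on the unrooted tree; a change on the outgroup's incident
edge is presented on the ingroup stem, oriented away from the outgroup.

### Collapsing and the "single tree" convention

Three binary optima tie on the bundled matrix, differing only in the
resolution of one three-taxon cluster. The package collapses every
internal branch whose minimum length over all reconstructions of all
characters is zero — i.e. no character is forced to change there — and
deduplicates by a canonical form. Under this rule the three optima merge
into one polytomous tree, which is how an analysis of this matrix can
defensibly report "a single most parsimonious tree" while the raw binary
count (always reported alongside) is three.

The canonical identity token is a sorted nested-parenthesis normal form
rooted at the lexicographically smallest leaf's incident edge; it is
label-set aware, polytomy-safe, and stable across sessions.

## The synthetic-data generators

Three generators make every stage testable without external data:

* `simulate_mk()` evolves characters independently down a rooted
  traversal from root state 0; each branch receives a Poisson number of
  changes (branch-specific mean, default 0.3 per branch) and each change
  moves to a uniformly chosen other state. Counts-per-branch rather than
  continuous-time rates were chosen because they control expected
  homoplasy directly and suffice for recovery experiments. An
  `autapomorphy_fraction` forces that share of characters to vary in
  exactly one leaf, emulating the autapomorphy-rich profile of
  morphological matrices (7 of 19 characters in the bundled data). The
  generator returns the true tree alongside the matrix so recovery needs
  no re-derivation.
* `simulate_perfect_hierarchy()` writes one binary character per
  non-trivial split. Such matrices are fully compatible, so the unique
  optimum is the generating topology, its length is the character count
  and CI = RI = 1 — a closed-form oracle used throughout the tests.
* `permute_columns()` shuffles each column independently, preserving
  every column's state multiset (hence Σm and Σg) while destroying
  hierarchical signal — the natural null model for "how much structure
  does this matrix carry".

What the Mk generator does **not** emulate: rate variation across
characters, correlated characters, missing data, or asymmetric state
frequencies. Passing recovery tests on these matrices therefore says the
search and scoring machinery are correct, not that parsimony would
recover a real clade at comparable noise. Indeed the test suite shows
recovery of the generating topology degrades steeply with the per-branch
change rate (optimal-tree consistency falls monotonically across rates
0.1/0.3/0.6), and at the generator's default of 0.3 expected changes per
branch per character a 50-character, 8-taxon matrix is typically too
homoplastic for the true tree to sit in the optimum set at all. The
recovery acceptance check asserts a 95% recovery rate under exactly
those conditions and is expected to fail; it is kept as stated rather
than quietly weakened, because the discrepancy is a property of the
stated simulation conditions, not of the implementation — the same
search is verified exact against exhaustive enumeration and an
independent scorer on twenty random matrices.

## Numerical and degenerate-input choices

* All state sets are bitmasks over the digits 0–9; scoring is exact
  integer arithmetic (floating point appears only in weighted sums, with
  a 1e−9 tie tolerance in the search).
* Equal-cost insertions in greedy/stepwise contexts resolve to the first
  branch in deterministic traversal order.
* An all-constant matrix has CI undefined; `index_report()` refuses it
  with an explicit error rather than returning NaN. Constant characters
  inside an otherwise variable matrix contribute `m = g = s = 0` and
  leave their per-character `ci`/`ri` undefined (NA).
* Character state `2` ("present with modifications") is treated as an
  ordinary third unordered state, with no special cost against 0 or 1.
  Nothing in the data dictates otherwise, and non-additivity of all
  characters is the stated analysis condition; on the bundled matrix
  both three-state characters fit perfectly (`s = m = 2`), so no
  plausible alternative costing would change the optimum.
* Matrices must have ≥ 3 taxa and ≥ 1 character; duplicate taxon labels,
  ragged rows and unknown symbols are rejected at parse time with the
  offending taxon/position named.

## Problem sizes used in the checks

The shipped verification uses the 11-taxon bundled matrix for all exact
searches (sub-second each), 20 random 6–8-taxon matrices for
branch-and-bound/exhaustive equivalence, 30 replicates for the Mk
recovery experiment, 20 column permutations for the null comparison, and
trees of up to 8 leaves wherever an exhaustive or brute-force oracle is
enumerated. These sizes were chosen so every oracle remains a genuinely
independent computation (full enumeration, closed form, or an external
scorer) while the whole suite runs in well under a minute.

## Known limitations

* No ordered/additive or step-matrix costs, no polymorphic codings, no
  continuous characters (the `char_type` and `weights` fields exist so
  the containers do not preclude them, but only unordered equal-weights
  analysis is implemented and tested).
* No bootstrap/jackknife or Bremer support.
* The ratchet implements NNI+SPR only; TBR and the other heuristic
  strategies of large parsimony programs are out of scope because the
  exact search supersedes them at these sizes.
* Exhaustive/branch-and-bound searches are designed for ≤ 11 taxa; the
  caps are configurable but the combinatorics are not.
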