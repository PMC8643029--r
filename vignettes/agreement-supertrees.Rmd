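---
title: "Agreement supertrees for semi-labeled trees: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement supertrees for semi-labeled trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agreetree)
```

## The model

A *semi-labeled tree* (or X-tree) is a rooted tree `T` together with a map
`phi` from a taxon set `X` to the nodes of `T` such that every leaf and
every node with a single child carries at least one taxon.  Ordinary
phylogenies are the special case where `phi` is a bijection onto the
leaves; taxonomies are the general case, where internal labels denote
higher-order taxa (families containing genera containing species).  The
*cluster* of a node is the set of taxa on the node and its descendants;
the cluster set determines the tree up to isomorphism, which is why every
equality test in this package is a cluster-set comparison
(`same_clusters()`, `agrees_with()`).

Given a profile `P = {T_1, ..., T_k}` over partially overlapping taxon
sets, an *agreement supertree* is a tree on the union of the taxon sets
whose restriction to each `X_i` is isomorphic to `T_i`.  Agreement treats
multifurcations as **hard**: three taxa lying in distinct subtrees of a
node of some input must lie in distinct subtrees of some node of the
supertree.  This is the semantics you want when polytomies are assertions
(as in curated taxonomies); if your polytomies mean "unresolved", you want
compatibility instead, which this package deliberately does not implement.

## Normalization

The algorithm assumes each input tree is *fully and singularly labeled*
(every node exactly one taxon).  `fully_label()` establishes the first
half by assigning fresh taxa (reserved prefix `__anon`) to unlabeled
nodes; an agreement tree of the augmented profile is an agreement tree of
the original, so nothing is lost, and `strip_synthetic_labels()` removes
the helpers from the output for presentation.  Singular labeling is
required of the input (a node carrying two taxa in one input tree is a
modeling error the parser reports).  Note the output is *not* in general
singularly labeled: distinct inputs can force several taxa onto one
supertree node.

## The construction

All work happens on the *display graph* `H_P`: one vertex per taxon, one
edge per distinct parent–child label pair pooled over the inputs.  The
builder walks top-down over *positions* — k-tuples, one subtree root label
per input tree — starting from the roots.  For a position `pi`:

1. A label is *exposed* when it is the position's entry in every input
   containing it.  Newly exposed labels are deleted from `H_P` (each
   vertex and edge at most once over the whole run; labels already deleted
   in an ancestor call are skipped).
2. The children of the position labels are partitioned into *blocks* by
   connected component of what remains.
3. An exposed label is *bad* if two of its same-tree children fall into
   one block: it must be a multifurcation in any agreement tree, but the
   current split would separate its children inconsistently.  Bad labels
   are removed from the candidate set `S` and the blocks holding their
   children are merged *virtually* — block records are unioned and the
   child-to-block map updated, but nothing is reinserted into the graph.
4. The loop runs at most `k` times, and the surviving `S` is the unique
   maximal *nice exposed subset* (uniqueness makes the elimination order
   irrelevant; the test suite re-runs it under randomized orders).  `S`
   becomes a supertree node; each final block yields a successor position
   (for a tree whose entry `a` stayed outside `S`, the entry is carried
   unchanged into the single block of the component containing `a`).

If `S` comes up empty, no agreement tree exists for the position, hence
none for the profile; the builder stops and reports the position's
per-tree roots as a conflict certificate.  (No minimal-conflict extraction
is attempted — the reported position localizes, but does not minimize, the
disagreement.)  One subtlety worth recording: the successor-position rule
as a bare formula would copy a non-exposed entry into *every* block; the
correct reading, which the implementation follows, assigns it only to the
block of the component that actually contains it.

A worked run of all of this, with every intermediate value, is in the
README and in `decompose_position()`'s documentation; the same values are
frozen in the acceptance tests.

## Connectivity backends

Deletions dominate the running time, so the display graph maintains its
components decrementally.  Two backends are provided (`backend=` in
`ast_engine()`/`build_agreement_tree()`):

* `"forest"` (default): a spanning forest with replacement-edge search.
  Deleting a non-forest edge is O(1).  Deleting a forest edge triggers a
  simultaneous alternating BFS over forest edges from both endpoints; the
  side whose frontier exhausts first — the smaller side — is scanned for a
  replacement edge, and split off as a new component if none exists.
* `"bfs"`: the same alternating search over graph adjacency, with meeting
  detection; simpler, used as a cross-check.

Because only the smaller side is ever moved, a vertex changes component at
most about `log2` of the graph size times (`component_move_counts()`
exposes the counters; the tests assert the bound).  A full
polylogarithmic-worst-case structure (hierarchical forests with level
promotion) was considered and rejected: the replacement-search structure
is what performs well on display graphs in practice, and correctness is
backend-independent — both backends must match a fresh BFS partition (and
igraph) after every deletion in the test suite.

## Verification: three independent routes

* `verify_agreement()` checks the LCA characterization: for each input
  tree and taxon `a`, (E1) `phi(a)` is the supertree LCA of `a`'s input
  cluster; (E2) `phi(a)` is a proper ancestor of `phi(b)` for each child
  label `b`; (E3) distinct children of `a` descend from distinct children
  of `phi(a)`.  The conditions are jointly equivalent to agreement, so
  this is a complete oracle.  It shares no code with the engine.
* `agrees_with()` is the definitional cluster-restriction test.
* `brute_force_agreement()` enumerates, for at most six taxa, every
  fully-labeled candidate (set partitions of the taxa crossed with rooted
  tree shapes on the blocks — sufficient because an agreeing profile
  always has an agreement tree with every node labeled) and checks each
  definitionally.

The acceptance suite runs the engine against the brute-force decider on
hundreds of random small profiles and the verifier on everything the
engine outputs.  The verifier computes LCAs by vectorized binary lifting
rather than naive upward walks: verification must also run on generated
profiles with tens of thousands of taxa, where naive walks would dominate
the whole pipeline.  This changes no semantics.

## The synthetic generator: what it does and does not emulate

`generate_profile()` reproduces the benchmarking world of the method's
experimental setting: a complete `D`-ary seed tree with `m` labeled nodes
(levels filled left to right), restricted to `k` random label subsets, so
the profile agrees by construction.  Where that setting leaves parameters
open, the package fixes them once:

* subset size ~ uniform on `[max(2, ceiling(0.1 m)), m]` — large enough
  that trees genuinely interact, with substantial size variation;
* each element is drawn with probability `p_used = 0.5` from the pool of
  labels already used by earlier draws, else from the unused pool —
  guaranteeing the partially-overlapping-taxon-sets regime the method is
  about.  Both knobs sit in `generator_config()` with those defaults.

Restriction creates unlabeled LCA nodes, which receive fresh labels; the
generator also returns a `reference` agreement tree (the seed tree with
the fresh labels attached at their source nodes, restricted to the
profile's taxa), so soundness is checkable without running the builder.

What a green generator test establishes: the builder handles large,
agreeing, taxonomy-shaped profiles and recovers every input exactly.  What
it does not establish: behavior on *real* conflicting profiles (real
supertree inputs mostly disagree, and then the builder exits early), on
adversarial display-graph topologies, or on name-level noise (synonyms,
misspellings) — those are exercised separately by hand-built conflict
fixtures, and name reconciliation is out of scope entirely.

## Numerical and procedural choices

* **Determinism.** Bad-label scanning is tree-index-ascending then child
  order; successor blocks and canonical Newick children are ordered by
  smallest contained taxon (radix/C-locale sorting throughout); the
  generator consumes its RNG in a documented order under one seed.  Two
  runs are byte-identical.
* **Multiply labeled nodes** serialize as taxa sorted and joined by a
  delimiter (`+` by default) — the serialization is our choice, as none is
  standard; `parse_newick(multi_label_delimiter=)` inverts it.
* **Branch lengths** are parsed, discarded, and warned about once per
  call: agreement is purely topological.
* **Unary nodes** are kept when labeled (the X-tree definition demands
  the label), unlike most phylogenetics parsers, which suppress them.
* **Queue discipline** (FIFO vs LIFO) is configurable and provably
  immaterial; the default is breadth-first, and the test suite checks
  cluster-identical output both ways.
* **Single-use engines.** Graph deletions are destructive and performed
  once; `build_agreement_tree()` creates a fresh engine per call, and an
  `ast_engine` refuses a second `ae_build`.

## Known limitations

* Agreement only — no compatibility testing, no polytomy refinement, no
  mixed hard/soft polytomy handling.
* One agreement tree is returned (the one whose node label sets are
  maximal nice exposed subsets); profiles can admit others, and
  enumeration is not attempted.
* The conflict certificate is a position, not a minimal obstruction.
* The brute-force oracle is exponential by design and guarded at six
  taxa.
* Wall-clock performance claims are not asserted anywhere: timing is
  hardware-dependent, so `benchmark_sweep()` reports but never tests it.
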