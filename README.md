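# agreetree

Agreement supertrees for rooted **semi-labeled trees** — phylogenies whose
internal nodes may also carry taxon labels, as in taxonomies (e.g. a subtree
rooted at a node labeled *Fabaceae* containing *Glycine max* and a leaf
labeled *Phaseolus*).

## The problem

Given a profile `P = {T_1, …, T_k}` of rooted semi-labeled trees over
partially overlapping taxon sets `X_1, …, X_k`, decide whether there is a
tree `T` on `X_P = X_1 ∪ … ∪ X_k` such that

```
T | X_i  ≅  T_i      for every i,
```

where `T | Y` is the restriction of `T` to the taxa `Y` (the tree whose
clusters are the nonempty sets `C ∩ Y` over clusters `C` of `T`), and `≅`
is isomorphism of semi-labeled trees (equality of cluster sets).  Such a
`T` is an **agreement supertree**.  Agreement treats multifurcations as
*hard* facts: a polytomy in an input tree may not be refined, which is the
right semantics when polytomies are assertions rather than uncertainty.
This is what distinguishes agreement from the (more permissive)
compatibility problem, which is out of scope here.

The package implements a top-down construction over the **display graph**
`H_P` (one vertex per taxon, one edge per distinct parent–child label pair
pooled over all inputs).  From the initial *position* (the tuple of root
labels) each step computes the unique maximal *nice exposed subset* `S`:
exposed labels are deleted from `H_P`, the children of the position labels
are partitioned by connected component, and *bad* labels — exposed labels
with two same-tree children in one block, i.e. forced multifurcations that
the current split would break — are eliminated by virtually merging blocks.
`S` becomes a node of the supertree; the blocks yield the successor
positions.  If `S` ever comes up empty, the profile provably disagrees.
With the decremental-connectivity backend this runs in roughly
`O(nk (Σ_i d_i + log² (nk)))` time for `n` taxa, `k` trees and maximum
out-degrees `d_i`; in practice it is far faster (see the vignette).

## Worked example

Four input trees; taxa `a`–`l` are original, the numeric taxa are the
fresh labels that make every tree fully labeled (`fully_label()` adds them
automatically when you start from partially labeled trees):

```r
library(agreetree)
p <- toy_taxonomy_profile()
print(p)
#> Profile of 4 semi-labeled trees, 18 distinct taxa
#>   [1] (((a,c)3,b)2,d)1;
#>   [2] (b,c,(e)g)4;
#>   [3] (f,(h,e)5,k)g;
#>   [4] ((h)i,(k)j,l)6;

initial_position(p)
#> [1] "1" "4" "g" "6"

eng <- ast_engine(p)
d <- decompose_position(eng, initial_position(p))
d$exposed          # "1" "4" "6"   (g is not exposed: it sits below 4 in tree 2)
d$blocks_initial   # {2,b,c} {5,f,g,i,j,k} {d} {l}
d$bad_labels       # "4" "6"  -> their blocks get virtually merged
d$S                # "1"      -> the maximal nice exposed subset
d$successors       # ({2},{4},{g},{6})  and  ({d},-,-,-)

res <- verify_and_build(p)
print(res)
#> Profile agrees. Agreement tree:
#>   (((a,c)3,((e,h)5+i,f,(k)j,l)6+g,b)2+4,d)1;
#> Positions processed: 15, bad labels eliminated: 3
```

Nodes like `5+i` carry several taxa: the agreement tree of singularly
labeled inputs need not be singularly labeled.  Restricting the answer to
any input's taxon set reproduces that input exactly
(`agrees_with(res$tree, p[[i]])` is `TRUE` for all four), and the
independent verifier confirms the characterization conditions
(`verify_agreement(res$tree, p)$ok`).

A conflicting profile is certified, not silently dropped:

```r
build_agreement_tree(slt_profile(list(parse_newick("(a,b,c);"),
                                      parse_newick("((a,b),c);"))))$status
#> [1] "DISAGREES"    # the fan is a hard polytomy; ((a,b),c) refines it
```

## Command line

```sh
Rscript exec/agreetree agree inst/extdata/example_profile.nwk
Rscript exec/agreetree verify supertree.nwk profile.nwk
Rscript exec/agreetree generate --D 3 --m 500 --k 50 --seed 1 --out prof.nwk
Rscript exec/agreetree bench --D 2,3 --m 100,500 --k 50 --trials 3 --out bench.csv
```

Exit codes: `0` agree / verified, `1` disagree / verification failed,
`2` usage or parse error.

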