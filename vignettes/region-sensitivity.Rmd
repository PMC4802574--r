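---
title: "Ranking 16S rRNA hypervariable regions by tree-space distance to the full-length phylogeny"
author: "rRNAregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking 16S rRNA hypervariable regions by tree-space distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rRNAregions)
```

## The question

Amplicon surveys sequence one or two hypervariable sub-regions (V1–V9) of
the 16S rRNA gene, not the full gene, so the choice of sub-region decides
how much phylogenetic signal a study retains. This package quantifies that
choice directly: for many independently drawn sets of taxa it builds one
tree per sub-region and one tree from the (near) full-length sequence
("VT", the concatenation of all sub-regions), and measures how far each
sub-region tree is from the full-length tree as an exact geodesic distance
in Billera–Holmes–Vogtmann (BHV) tree space. Averaging over taxon sets
gives a stable sensitivity ranking of the regions; hierarchical clustering
of the full inter-region distance matrix, condensed by majority-rule
consensus across taxon sets, shows which regions behave alike.

## The analysis design

The workflow operates on a fixed-width rRNA alignment whose columns are
divided into V1–V9 by a breakpoint table (`builtinRegionTable()`), given in
both alignment columns and *E. coli* reference coordinates, 1-based and
inclusive at both ends. Each sub-region starts with its conserved
(primer-binding) stretch followed by the hypervariable interior. V1 and V9
are excluded from analysis by default because they are mostly incomplete in
SILVA-style data; merged blocks of consecutive regions (V2-3-4, …, V6-7-8)
can be analysed as additional units.

Records are filtered (ungapped length strictly greater than 1400,
non-empty taxonomy, no organelle annotation) and stratified lists are drawn:
three representatives per phylum, with phyla holding fewer than three
records discarded, and the designated large phylum (Proteobacteria) split
into one stratum per subphylum. Where a stratum spans at least three
next-lower-rank groups, three distinct groups are drawn first and one member
from each — the weakest reading of "prefer different sub-levels" that is
still an algorithm. List `i` is drawn under sub-seed `seed + i`, so any
single list can be regenerated; lists are independent draws and may overlap.
With 31 eligible phyla and 5 subphyla the design yields 89 lists × 108
members, hence 712 trees and 2492 geodesic distances (`planSummary()`).

## Tree inference

The built-in engine computes model-corrected distances (p, JC69 or K80)
over pairwise-complete columns — both records in `{A,C,G,T}` — and runs
Saitou–Nei neighbor joining. Three contracts make it reproducible and safe
for tree-space work: Q-criterion ties are broken toward the
lexicographically smallest label pair; negative branch lengths are clamped
to zero (BHV space requires non-negative lengths); and saturated pairs
(JC69 at `p >= 0.749`, or a non-positive K80 log argument) are capped at a
configurable ceiling (default 5 substitutions/site) with a warning, while a
pair sharing fewer than `minOverlap` (default 50) comparable columns is an
error rather than a guess. The engine is deliberately pluggable: externally
built trees (e.g. Bayesian ones) enter through `ingestNewick()`, which
validates leaf uniqueness, requires branch lengths, clamps only numerical
negatives (> −1e−9) and suppresses degree-2 roots, or through the
pipeline's `treeDir` convention (`list<id>_<region>.nwk`), where a missing
file is a hard error rather than a silent fallback.

## The BHV geodesic and the GTP algorithm

BHV tree space glues one Euclidean orthant per topology along shared faces;
the geodesic distance between two trees is the length of the shortest path
through this space. `gtpDistance()` computes it exactly:

* Splits present in both trees, and all pendant edges, contribute squared
  length differences. A split unique to one tree but compatible with every
  split of the other behaves exactly like a shared split of partner length
  zero — the geodesic shrinks it linearly — and is moved into the common
  part up front.
* The remaining split sets A (unique to tree 1) and B (unique to tree 2)
  are paired into an ordered path space `(A_1,B_1), …, (A_k,B_k)`
  contributing `sum((||A_i|| + ||B_i||)^2)`. Starting from the single-pair
  cone path, each pair is refined whenever the minimum-weight vertex cover
  of its bipartite incompatibility graph — vertex weights
  `||a||^2/||A_i||^2` and `||b||^2/||B_i||^2`, solved as an s–t max-flow —
  weighs less than 1. The cover `(C, D)` splits the pair into
  `(C, B_i \ D)` followed by `(A_i \ C, D)`; when no pair admits a cover
  below 1, the path space certifies the geodesic.

Numerical choices: the cover test uses a `1e-10` slack against 1 so
floating-point flow values cannot trigger false refinements; zero-length
internal edges are dropped before split extraction (a zero-length split is
topologically absent); trees are compared unrooted; polytomies are
supported; pendant edges contribute in quadrature unless
`internalOnly = TRUE`.

The independent check is `bruteForceDistance()`: exhaustive enumeration of
every ordered partition of A and B into nonempty groups that is *valid*
(anything added at step i is compatible with everything dropped later) and
*realisable* (norm ratios `||A_i||/||B_i||` non-decreasing — an ordered
partition violating monotonicity does not correspond to a bent path of the
naive length; the geodesic through those orthants is the coarser merged
partition, which the enumeration reaches separately). The test suite holds
the two routes equal to 1e-10 over a thousand random tree pairs, and checks
the metric axioms and the sandwich
`lowerBound <= distance <= coneLength` on every computed pair.

## Summaries, consensus and classes

Per list, all region-pair distances form an 8×8 matrix. `vtSummary()`
reports each region's mean and sample standard deviation of distance to VT
across lists (SE available by option; with a single list the SD is
undefined and flagged, not invented). `ahcCluster()` runs agglomerative
clustering with average linkage by default — the most common default on a
raw dissimilarity matrix, with complete and single linkage exposed — and
breaks ties toward the lexicographically smallest cluster-label pair so
merge sequences are deterministic. Per-list dendrograms enter
`majorityConsensus()` as rooted topologies (heights discarded); clades
present in strictly more than half the lists are kept with support
`100 * occurrences / n`, which makes supports exact multiples of `100/n`
in `(50, 100]` and guarantees pairwise compatibility. Finally
`classifyRegions()` cuts the rank order into sensitivity classes at
configurable cut points (default 3/2/2 — three classes with the closest
three regions in Class I); classes are rank-based rather than
threshold-based because the ranking plus the clustering structure, not any
absolute distance value, is the scientifically stable output. Ties across a
cut are flagged rather than resolved silently.

## The synthetic benchmark: what it emulates and what it does not

`simulationSpec()` + `makeBenchmark()` generate SILVA-like datasets with
known ground truth so every stage is testable without downloads. The
generator emulates: a fixed-width alignment partitioned by a (rescaled)
breakpoint table; taxonomy paths with phylum/class structure including one
multi-subphylum Proteobacteria-like group; organelle-labelled contaminants
and gap-truncated short records, at 5% each by default, exercising both
filters; and a region-specific rate mosaic in which the leading
`conservedAnchorFraction` (default 25%) of each region's columns evolves at
`anchorRate` (default 0.1×) of the region's rate, emulating conserved
anchors against hypervariable interiors. Sites evolve down the true tree
under GTR (16S-like exchangeabilities, AG and CT transitions elevated) with
discrete-gamma rate classes and a proportion of invariant sites.

Key defaults and their reasoning:

* **Taxonomic design** — 31 phyla + 5 subphyla, 3 classes each, 2
  sequences per class (216 leaves). This supports the full 108-member
  stratified draw while leaving the sampler real choices.
* **Region table** — a 1/10-scale map (width 1437) keeps unit tests fast;
  the truth-recovery benchmark uses a 1/4-scale map (VT = 3593 columns) so
  topology estimation has realistic sequence length; the full-width map is
  one flag away. The length filter scales with the map
  (`benchmarkLengthThreshold()`, `round(1400 × scale)`).
* **True-tree edge lengths** — exponential with hard floors per level
  (backbone 0.02, within-group 0.015, pendant 0.008 substitutions/site;
  crown depth around 0.7–0.8 pairwise). The floors keep every internal edge
  long enough to be identifiable from benchmark-length sequences, which is
  the point of a ground-truth benchmark: a tree with unidentifiably short
  edges tests sequence length, not pipeline correctness.
* **Within-region heterogeneity** — gamma shape 8 with 5% invariant sites.
  The built-in engine's model family (p/JC69/K80) has no rate-heterogeneity
  correction, and under strong within-region gamma (shape near 1) JC
  distances become systematically non-additive, so truth recovery would
  measure model misfit rather than pipeline behaviour. The dominant,
  biologically central heterogeneity — conserved anchors versus
  hypervariable interiors, and region-specific rates — is kept at full
  strength; stronger within-region gamma is available by argument.
* **Per-region rates** — all 1.0 by default, so a region's information
  content (summed column rates ≈ expected substitutions) is driven by its
  width; V4, the widest analysed region, is then the designed
  most-informative region, and the benchmark checks that it indeed attains
  the smallest mean geodesic distance to VT.

What the generator does *not* emulate: secondary-structure–constrained
evolution, indels and alignment error (full-length synthetic records are
gapless; gaps appear only in the deliberately truncated records; real-data
gap handling is exercised by unit fixtures), chimeras, and the taxon
sampling biases of real databases. Passing benchmark tests therefore shows
the pipeline is internally correct and well-calibrated, not that any
particular region is optimal for a given real community.

## Degenerate inputs and edge behaviour

Empty alignments filter to empty with a warning; a stratum falling below
three candidates disappears from the design rather than being padded;
all-equal distance matrices cluster deterministically by the tie-break; a
clade in exactly half the input trees is *not* a majority; identical trees
give distance exactly 0; star trees have empty split sets and reduce the
geodesic to pendant differences.

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their computations as: exact
bookkeeping at the full 89-list design (arithmetic only); geodesic
oracle agreement on 500–1000 random 5–7-leaf tree pairs; metric axioms on
500 random triples; truth recovery and region ranking on one 216-leaf
benchmark at 1/4 scale with 10 lists of 108 taxa; and one end-to-end
pipeline run with 5 lists at 1/10 scale. These sizes were chosen so the
whole battery re-runs comfortably on a laptop while still exercising
108-taxon trees, the scale at which the geodesic and NJ code paths are
actually used.

## Known limitations

* The built-in engine is distance-based; users wanting Bayesian or ML trees
  should build them externally and supply Newick files — the geodesic and
  consensus machinery is agnostic to the tree source.
* BHV geodesics are reported as lengths with certificates; Fréchet means
  and parameterised geodesic paths are out of scope.
* Breakpoints are taken as given for the supported alignment; mapping an
  arbitrary alignment into reference coordinates (or re-deriving
  breakpoints from conserved motifs) is not attempted.
* `bruteForceDistance()` is exponential by design and refuses more than
  `maxUniqueSplits` unique splits per side; it exists to verify
  `gtpDistance()`, which has no such limit.
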