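# rRNAregions

Which 16S rRNA hypervariable sub-region best stands in for the full-length
gene in phylogenetic analysis? `rRNAregions` answers that question
quantitatively. For many independently drawn, phylum-stratified sets of
taxa it builds one phylogenetic tree per sub-region (V2–V8) and one from
the near full-length sequence (VT), then measures how far each sub-region
tree is from the full-length tree as an **exact geodesic distance in
Billera–Holmes–Vogtmann (BHV) tree space**. Averaging over taxon sets
ranks the regions by phylogenetic sensitivity; agglomerative clustering of
the full inter-region distance matrix, condensed by majority-rule
consensus with node supports, shows which regions behave alike. It is
aimed at microbial ecologists choosing amplicon primers and at
methodologists working with tree-space distances.

## The core computation

BHV tree space is a union of Euclidean orthants, one per tree topology,
glued along shared faces; the distance between two trees T and T' on the
same leaf set is the length of the shortest path through this space.
Writing C for the splits present in both trees (with lengths
|e|<sub>T</sub>, |e|<sub>T'</sub>) and pairing the remaining split sets A
(unique to T) and B (unique to T') into an ordered path space
(A₁,B₁), …, (A_k,B_k),

d(T, T')² = Σ<sub>e∈C</sub> (|e|<sub>T</sub> − |e|<sub>T'</sub>)²
          + Σ<sub>leaves</sub> (pendant diff)²
          + Σ<sub>i</sub> (‖A_i‖ + ‖B_i‖)²,

where the optimal path space is valid (each split added at step i is
compatible with every split dropped later), has non-decreasing norm ratios
‖A_i‖/‖B_i‖, and admits no improving refinement. `gtpDistance()` finds it
with the GTP extension-problem algorithm: starting from the single-pair
cone path, a pair (A_i, B_i) is split whenever the minimum-weight vertex
cover of its bipartite incompatibility graph (weights ‖a‖²/‖A_i‖²,
‖b‖²/‖B_i‖², solved as a max-flow) weighs less than 1. An exhaustive
path-space enumeration oracle, `bruteForceDistance()`, verifies the
implementation on small trees.

## Worked example

A complete run on a synthetic benchmark with known ground truth (5
ordinary phyla plus 3 Proteobacteria-like subphyla, 1/10-scale alignment,
5 taxon lists):

```r
library(rRNAregions)

spec <- simulationSpec(nPhyla = 5, nSubphyla = 3, seqsPerClass = 2,
                       regionTable = scaledRegionTable(0.1), seed = 11)
bm  <- makeBenchmark(spec, "readme_bm")
cfg <- pipelineConfig(alignment = bm$paths$alignment, outDir = "readme_run",
                      regionTable = spec@regionTable,
                      sampling = samplingConfig(nLists = 5, seed = 7,
                        minUngappedLength = benchmarkLengthThreshold(spec)),
                      seed = 7)
res <- runPipeline(cfg)
#> filterDataset: kept 48 / 52 (removed 2 short, 0 unannotated, 2 organellar)
pipelineReport(res)
#> Region sensitivity report (5 lists, 8 regions)
#> region         mean         sd  rank  class  tie
#> V4          0.05389    0.00347     1      I
#> V5          0.06631    0.00515     2      I
#> V7          0.07726    0.00746     3      I
#> V3          0.07950    0.00496     4     II
#> V2          0.08037    0.00360     5     II
#> V6          0.11437    0.00916     6    III
#> V8          0.13300    0.00771     7    III
#> consensus: (V8,(V6,(V2,(V7,(V5,(V3,(V4,VT)100)60)60)60)100)100);
#> engine: builtin:JC69+NJ; linkage: average; seed: 7; trees: 40; distances: 140
```

Reading the output: `mean`/`sd` are each region's average (± sample SD
over the 5 lists) BHV geodesic distance to the full-length (VT) tree —
smaller means the region's trees resemble the full-length trees more
closely. V4, the widest region and therefore the one carrying the most
substitution information in this benchmark, ranks first and lands in
sensitivity Class I. The consensus line is the majority-rule consensus of
the five per-list cluster dendrograms; the node label `100` on `(V4,VT)`
says V4 clustered with the full-length tree in 100% of lists.

A single geodesic with its certificate:

```r
t1 <- ingestNewick(text = "((A:0.1,B:0.1):0.3,C:0.1,D:0.1);")
t2 <- ingestNewick(text = "((A:0.1,C:0.1):0.4,B:0.1,D:0.1);")
gtpDistance(t1, t2)
#> BHV geodesic distance: 0.7
#>   common part: 0  leaf part: 0
#>   bounds: [0.5, 0.7] (lower, cone)
#>   path space: 1 support pair(s)
#>     (1) |A|=1 ||A||=0.3  |B|=1 ||B||=0.4  ratio=0.75
```

The two quartets disagree in their single internal split, so the geodesic
passes through the star tree: 0.3 + 0.4 = 0.7.

Real data enter the same way: an aligned FASTA with SILVA-style headers
through `readAlignedFasta()`, externally built (e.g. Bayesian) trees
through `ingestNewick()` or the pipeline's `treeDir` option. A thin CLI
over the same functions is installed at
`inst/scripts/region-pipeline.R` (subcommands `simulate`, `run`,
`geodesic`, `report`).

## Package layout

- `R/` — S4 classes (`RegionTable`, `RegionAlignment`, `GeodesicResult`,
  `SamplingConfig`, `SimulationSpec`, `ConsensusTree`, `PipelineConfig`)
  and the module functions: region slicing, filtering/sampling, distance +
  NJ engine, Newick IO, BHV geodesics, clustering/consensus, synthetic
  benchmark generator, pipeline orchestration.
- `vignettes/region-sensitivity.Rmd` — the methods vignette: models,
  parameter defaults and rationale, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
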