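#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats sd setNames rexp runif
#' @importFrom utils read.delim write.table
NULL

#' RegionTable: sub-region coordinate system of the 16S rRNA alignment
#'
#' A `RegionTable` holds the ordered breakpoint map dividing the columns of a
#' fixed-width 16S rRNA alignment into the nine hypervariable sub-regions
#' V1--V9, plus one "total" row (VT) spanning all of them. Coordinates are
#' 1-based and inclusive at both ends, in two systems: alignment columns
#' (`alnStart`/`alnEnd`) and ungapped *E. coli* reference positions
#' (`refStart`/`refEnd`). Consecutive regions must be contiguous and
#' non-overlapping in both systems, and the total row must span exactly from
#' the first region's start to the last region's end.
#'
#' @slot regions data.frame with columns `name`, `alnStart`, `alnEnd`,
#'   `refStart`, `refEnd`, one row per sub-region in genomic order.
#' @slot total one-row data.frame with the same columns for the spanning
#'   region (conventionally named `"VT"`).
#' @seealso [builtinRegionTable()], [scaledRegionTable()], [readRegionTable()]
#' @exportClass RegionTable
setClass("RegionTable",
         representation(regions = "data.frame", total = "data.frame"))

.validRegionTable <- function(object) {
  msgs <- character()
  need <- c("name", "alnStart", "alnEnd", "refStart", "refEnd")
  reg <- object@regions
  tot <- object@total
  if (!all(need %in% names(reg)) || !all(need %in% names(tot)))
    return(paste("missing columns; need", paste(need, collapse = ", ")))
  if (nrow(tot) != 1L) msgs <- c(msgs, "total must have exactly one row")
  co <- rbind(reg[need[-1]], tot[need[-1]])
  if (any(unlist(co) <= 0) || any(unlist(co) != floor(unlist(co))))
    msgs <- c(msgs, "all coordinates must be strictly positive integers")
  if (any(reg$alnStart > reg$alnEnd) || any(reg$refStart > reg$refEnd))
    msgs <- c(msgs, "region start must not exceed end")
  if (anyDuplicated(c(reg$name, tot$name)))
    msgs <- c(msgs, "region names must be unique")
  n <- nrow(reg)
  if (n >= 2L) {
    if (!all(reg$alnStart[-1] == reg$alnEnd[-n] + 1L))
      msgs <- c(msgs, "regions not contiguous in alignment coordinates")
    if (!all(reg$refStart[-1] == reg$refEnd[-n] + 1L))
      msgs <- c(msgs, "regions not contiguous in reference coordinates")
  }
  if (n >= 1L) {
    if (tot$alnStart != reg$alnStart[1] || tot$alnEnd != reg$alnEnd[n])
      msgs <- c(msgs, "total row must span the regions in alignment coordinates")
    if (tot$refStart != reg$refStart[1] || tot$refEnd != reg$refEnd[n])
      msgs <- c(msgs, "total row must span the regions in reference coordinates")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("RegionTable", .validRegionTable)

#' RegionAlignment: aligned sequences with taxonomy annotations
#'
#' A thin extension of [Biostrings::DNAStringSet] for one fixed-width
#' multiple alignment: all sequences must have identical width. Sequence
#' identifiers live in `names()`; the semicolon-delimited taxonomy path of
#' each record lives in `mcols()$taxonomy` (possibly `NA` for unannotated
#' records). Gap characters `-` and `.` are both treated as gaps; `U` is
#' normalised to `T` on ingest.
#'
#' @seealso [regionAlignment()], [readAlignedFasta()], [extractRegion()]
#' @exportClass RegionAlignment
setClass("RegionAlignment", contains = "DNAStringSet")

.validRegionAlignment <- function(object) {
  w <- Biostrings::width(object)
  if (length(w) && length(unique(w)) != 1L)
    return("all records in an alignment must have identical column counts")
  if (length(object) && is.null(names(object)))
    return("records must be named by sequence identifier")
  if (anyDuplicated(names(object)))
    return("sequence identifiers must be unique")
  TRUE
}
setValidity("RegionAlignment", .validRegionAlignment)

#' GeodesicResult: an exact BHV geodesic distance and its certificate
#'
#' Result of [gtpDistance()]. The squared distance decomposes as
#' `distance^2 = commonPart + leafPart + sum((||A_i|| + ||B_i||)^2)` over the
#' ordered path space `(A_1,B_1), ..., (A_k,B_k)` pairing the two trees'
#' unique split sets. `coneLength` is the single-pair (k = 1) upper bound and
#' `lowerBound` the orthogonal-decomposition lower bound, so
#' `lowerBound <= distance <= coneLength` always holds.
#'
#' @slot distance non-negative geodesic length.
#' @slot commonPart summed squared length differences of splits shared by the
#'   two trees (including splits unique to one tree but compatible with the
#'   whole of the other, which behave as shared splits of partner length 0).
#' @slot leafPart summed squared pendant-edge length differences.
#' @slot pathSpace list of pairs, each `list(A=, B=, normA=, normB=)` with
#'   `A`/`B` lists of canonical split sides (character vectors of leaf labels).
#' @slot coneLength k = 1 upper bound.
#' @slot lowerBound orthogonal-decomposition lower bound.
#' @seealso [gtpDistance()], [bruteForceDistance()], [conePathLength()]
#' @exportClass GeodesicResult
setClass("GeodesicResult",
         representation(distance = "numeric", commonPart = "numeric",
                        leafPart = "numeric", pathSpace = "list",
                        coneLength = "numeric", lowerBound = "numeric"))

.validGeodesicResult <- function(object) {
  msgs <- character()
  d <- object@distance
  if (d < 0) msgs <- c(msgs, "distance must be non-negative")
  ps <- sum(vapply(object@pathSpace,
                   function(p) (p$normA + p$normB)^2, numeric(1)))
  if (abs(d^2 - (object@commonPart + object@leafPart + ps)) > 1e-8 * max(1, d^2))
    msgs <- c(msgs, "distance^2 must equal commonPart + leafPart + path-space part")
  if (object@lowerBound > d + 1e-9 || d > object@coneLength + 1e-9)
    msgs <- c(msgs, "lowerBound <= distance <= coneLength violated")
  if (length(msgs)) msgs else TRUE
}
setValidity("GeodesicResult", .validGeodesicResult)

#' SamplingConfig: filtering and stratified-sampling parameters
#'
#' Parameters of the taxon-sampling design: how many taxonomic lists to draw,
#' how many representatives per stratum, the minimum ungapped length (records
#' must be strictly longer), which phylum is treated as a collection of
#' subphyla (Proteobacteria in the reference design), and which taxonomy
#' substrings mark organellar contaminants for exclusion.
#'
#' @slot nLists number of independent taxonomic lists (reference design: 89).
#' @slot perStratum representatives drawn per stratum (reference design: 3).
#' @slot minUngappedLength records are kept only if their ungapped length is
#'   strictly greater than this (reference design: 1400).
#' @slot seed RNG seed; list `i` is drawn with seed `seed + i`.
#' @slot proteobacteriaLabel phylum whose subphyla become separate strata.
#' @slot organelleKeywords taxonomy substrings marking records to exclude.
#' @seealso [samplingConfig()], [filterDataset()], [generateLists()]
#' @exportClass SamplingConfig
setClass("SamplingConfig",
         representation(nLists = "integer", perStratum = "integer",
                        minUngappedLength = "integer", seed = "integer",
                        proteobacteriaLabel = "character",
                        organelleKeywords = "character"))

.validSamplingConfig <- function(object) {
  msgs <- character()
  if (object@nLists < 1L) msgs <- c(msgs, "nLists must be >= 1")
  if (object@perStratum < 1L) msgs <- c(msgs, "perStratum must be >= 1")
  if (object@minUngappedLength < 0L) msgs <- c(msgs, "minUngappedLength must be >= 0")
  if (length(msgs)) msgs else TRUE
}
setValidity("SamplingConfig", .validSamplingConfig)

#' SimulationSpec: parameters of the synthetic SILVA-like benchmark
#'
#' Fully describes one synthetic dataset: the taxonomic design (number of
#' ordinary phyla, subphyla of the designated large group, classes per
#' phylum/subphylum and sequences per class), the region coordinate system,
#' the per-region substitution-rate mosaic (conserved leading anchors at a
#' low rate, hypervariable interiors at region-specific rates), the GTR +
#' gamma + invariant-sites site model, the edge-length regime of the true
#' phylogeny, and the contamination knobs (organelle-labelled and
#' short/truncated records). Together with `seed` the spec reproduces a
#' dataset byte-for-byte.
#'
#' @slot nPhyla number of ordinary (single-stratum) phyla.
#' @slot nSubphyla subphyla of the designated multi-subphylum group.
#' @slot nClassesPerPhylum,nClassesPerSubphylum classes per stratum.
#' @slot seqsPerClass sequences simulated per class.
#' @slot regionTable a [RegionTable-class]; defaults to the 1/10-scale map.
#' @slot perRegionRate named relative rate multiplier per sub-region.
#' @slot conservedAnchorFraction fraction of each region's leading columns
#'   held at the anchor rate.
#' @slot anchorRate rate multiplier of anchor (and pre-V1 flank) columns.
#' @slot gtrRates six GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @slot baseFreqs equilibrium base frequencies (A, C, G, T).
#' @slot gammaShape,gammaCategories discrete-gamma rate heterogeneity.
#' @slot pInvariant proportion of invariant sites.
#' @slot backboneMean,backboneFloor,withinMean,withinFloor,pendantMean,pendantFloor
#'   exponential means and hard floors (substitutions/site) of the true
#'   tree's backbone, within-group and pendant edges.
#' @slot organelleFraction,shortFraction contaminant record fractions
#'   (relative to the number of true leaves).
#' @slot seed RNG seed of the whole dataset.
#' @seealso [simulationSpec()], [makeBenchmark()]
#' @exportClass SimulationSpec
setClass("SimulationSpec",
         representation(nPhyla = "integer", nSubphyla = "integer",
                        nClassesPerPhylum = "integer",
                        nClassesPerSubphylum = "integer",
                        seqsPerClass = "integer",
                        regionTable = "RegionTable",
                        perRegionRate = "numeric",
                        conservedAnchorFraction = "numeric",
                        anchorRate = "numeric",
                        gtrRates = "numeric", baseFreqs = "numeric",
                        gammaShape = "numeric", gammaCategories = "integer",
                        pInvariant = "numeric",
                        backboneMean = "numeric", backboneFloor = "numeric",
                        withinMean = "numeric", withinFloor = "numeric",
                        pendantMean = "numeric", pendantFloor = "numeric",
                        organelleFraction = "numeric",
                        shortFraction = "numeric", seed = "integer"))

.validSimulationSpec <- function(object) {
  msgs <- character()
  if (object@nPhyla < 1L) msgs <- c(msgs, "nPhyla must be >= 1")
  if (object@nSubphyla < 0L) msgs <- c(msgs, "nSubphyla must be >= 0")
  if (object@seqsPerClass < 1L) msgs <- c(msgs, "seqsPerClass must be >= 1")
  rn <- object@regionTable@regions$name
  if (!all(rn %in% names(object@perRegionRate)))
    msgs <- c(msgs, "perRegionRate must name every sub-region")
  if (any(object@perRegionRate < 0)) msgs <- c(msgs, "rate multipliers must be >= 0")
  if (object@anchorRate <= 0) msgs <- c(msgs, "anchorRate must be > 0")
  fr <- c(object@conservedAnchorFraction, object@pInvariant,
          object@organelleFraction, object@shortFraction)
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (length(object@gtrRates) != 6L || any(object@gtrRates <= 0))
    msgs <- c(msgs, "gtrRates must be six positive exchangeabilities")
  if (length(object@baseFreqs) != 4L || any(object@baseFreqs <= 0) ||
      abs(sum(object@baseFreqs) - 1) > 1e-8)
    msgs <- c(msgs, "baseFreqs must be four positive frequencies summing to 1")
  if (object@gammaShape <= 0) msgs <- c(msgs, "gammaShape must be > 0")
  if (length(msgs)) msgs else TRUE
}
setValidity("SimulationSpec", .validSimulationSpec)

#' PipelineConfig: one end-to-end analysis configuration
#'
#' Bundles everything [runPipeline()] needs: the input alignment (path or
#' [RegionAlignment-class]), optional taxonomy table, optional directory of
#' externally built Newick trees (matched as `list<id>_<region>.nwk`; when
#' given, tree inference is skipped and missing files are hard errors), the
#' region coordinate system and the region include list, the sampling design,
#' the distance model and AHC linkage, and the output directory. The config
#' is serialised verbatim into the run manifest so a run can be audited and
#' reproduced.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
         representation(alignment = "ANY", taxonomy = "ANY",
                        treeDir = "ANY", regionTable = "RegionTable",
                        include = "character", mergedSets = "ANY",
                        sampling = "SamplingConfig", model = "character",
                        minOverlap = "integer", maxDistance = "numeric",
                        linkage = "character", classCuts = "integer",
                        outDir = "character", seed = "integer"))
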