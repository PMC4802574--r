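# Synthetic SILVA-like benchmark generator with known ground truth.

#' Construct a SimulationSpec
#'
#' Defaults emulate the reference sampling design at desk scale: 31
#' ordinary phyla plus one Proteobacteria-like group with 5 subphyla, 3
#' classes per phylum/subphylum and 2 sequences per class (216 leaves, so
#' 108-member stratified lists have real sampling freedom); a 1/10-scale
#' region coordinate map; a rate mosaic with conserved leading anchors in
#' every sub-region; a GTR + discrete-gamma + invariant-sites site model
#' with 16S-like exchangeabilities; and small fractions of
#' organelle-labelled and truncated contaminant records exercising the
#' filters.
#'
#' @param nPhyla,nSubphyla,nClassesPerPhylum,nClassesPerSubphylum,seqsPerClass
#'   taxonomic design (see [SimulationSpec-class]).
#' @param regionTable region coordinate map used for the rate mosaic.
#' @param perRegionRate named rate multiplier per sub-region (default all 1,
#'   so a region's information content is driven by its width).
#' @param conservedAnchorFraction,anchorRate leading-anchor design.
#' @param gtrRates,baseFreqs,gammaShape,gammaCategories,pInvariant site model.
#' @param backboneMean,backboneFloor,withinMean,withinFloor,pendantMean,pendantFloor
#'   edge-length regime (substitutions/site) of the true tree.
#' @param organelleFraction,shortFraction contaminant fractions.
#' @param seed RNG seed.
#' @return A validated [SimulationSpec-class].
#' @examples
#' simulationSpec(nPhyla = 4, nSubphyla = 2, seqsPerClass = 1, seed = 7)
#' @export
simulationSpec <- function(nPhyla = 31L, nSubphyla = 5L,
                           nClassesPerPhylum = 3L,
                           nClassesPerSubphylum = 3L,
                           seqsPerClass = 2L,
                           regionTable = scaledRegionTable(0.1),
                           perRegionRate = NULL,
                           conservedAnchorFraction = 0.25,
                           anchorRate = 0.1,
                           gtrRates = c(AC = 1.0, AG = 2.8, AT = 1.3,
                                        CG = 0.9, CT = 3.6, GT = 1.0),
                           baseFreqs = c(A = 0.25, C = 0.23,
                                         G = 0.31, T = 0.21),
                           gammaShape = 8, gammaCategories = 4L,
                           pInvariant = 0.05,
                           backboneMean = 0.015, backboneFloor = 0.02,
                           withinMean = 0.01, withinFloor = 0.015,
                           pendantMean = 0.012, pendantFloor = 0.008,
                           organelleFraction = 0.05, shortFraction = 0.05,
                           seed = 1L) {
  if (is.null(perRegionRate)) {
    perRegionRate <- rep(1, nrow(regionTable@regions))
    names(perRegionRate) <- regionTable@regions$name
  }
  new("SimulationSpec", nPhyla = as.integer(nPhyla),
      nSubphyla = as.integer(nSubphyla),
      nClassesPerPhylum = as.integer(nClassesPerPhylum),
      nClassesPerSubphylum = as.integer(nClassesPerSubphylum),
      seqsPerClass = as.integer(seqsPerClass),
      regionTable = regionTable, perRegionRate = perRegionRate,
      conservedAnchorFraction = conservedAnchorFraction,
      anchorRate = anchorRate, gtrRates = gtrRates, baseFreqs = baseFreqs,
      gammaShape = gammaShape, gammaCategories = as.integer(gammaCategories),
      pInvariant = pInvariant,
      backboneMean = backboneMean, backboneFloor = backboneFloor,
      withinMean = withinMean, withinFloor = withinFloor,
      pendantMean = pendantMean, pendantFloor = pendantFloor,
      organelleFraction = organelleFraction, shortFraction = shortFraction,
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SimulationSpec", function(object) {
  nl <- object@nPhyla * object@nClassesPerPhylum +
        object@nSubphyla * object@nClassesPerSubphylum
  cat("SimulationSpec:", object@nPhyla, "phyla +", object@nSubphyla,
      "subphyla;", nl * object@seqsPerClass, "leaves;",
      "alignment width", object@regionTable@total$alnEnd, "; seed",
      object@seed, "\n")
})

.randSubtreeNewick <- function(labels, mean, floor) {
  k <- length(labels)
  if (k == 1L) return(labels)
  tr <- ape::rtree(k, tip.label = labels, br = NULL)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean) + floor
  sub("\\);$", ")", sub("^\\(", "(", ape::write.tree(tr)))
}

# Strip the trailing ';' of a newick so it can be used as a subtree fragment.
.asFragment <- function(nwk) sub(";$", "", nwk)

#' Sample a taxonomy-labelled true phylogeny
#'
#' Draws a binary tree whose leaves carry hierarchical taxonomy paths
#' consistent with its clade structure: a random backbone over the
#' phylum-level groups (the designated multi-subphylum group forms a single
#' clade containing its subphylum clades), random class clades within each
#' group and `seqsPerClass` leaves per class. Edge lengths are exponential
#' with hard floors per level (backbone / within-group / pendant), keeping
#' every internal edge identifiable at benchmark sequence lengths.
#' Uses the current RNG state; see [makeBenchmark()] for seeding.
#'
#' @param spec a [SimulationSpec-class].
#' @return List with `tree` (`ape::phylo`), `taxonomy` (named
#'   semicolon-joined paths per leaf id).
#' @export
sampleTrueTree <- function(spec) {
  greek <- c("Alpha", "Beta", "Gamma", "Delta", "Epsilon", "Zeta", "Eta",
             "Theta")
  if (spec@nSubphyla > length(greek))
    stop("at most ", length(greek), " subphyla supported")
  taxonomy <- character(0)
  classFragment <- function(ids) {
    if (spec@seqsPerClass == 1L) return(ids)
    .asFragment(.randSubtreeNewick(ids, spec@pendantMean, spec@pendantFloor))
  }
  groupFragment <- function(prefix, path, nClasses) {
    classes <- sprintf("Class%02d", seq_len(nClasses))
    frags <- vapply(seq_along(classes), function(ci) {
      ids <- sprintf("%sC%02dS%d", prefix, ci, seq_len(spec@seqsPerClass))
      taxonomy[ids] <<- paste(c(path, classes[ci]), collapse = ";")
      classFragment(ids)
    }, "")
    if (length(frags) == 1L) return(frags)
    holder <- sprintf("HOLD%04d", seq_along(frags))
    bb <- .randSubtreeNewick(holder, spec@withinMean, spec@withinFloor)
    for (i in seq_along(frags))
      bb <- sub(holder[i], frags[i], bb, fixed = TRUE)
    .asFragment(bb)
  }
  units <- character(0)
  phyla <- sprintf("Phylum%02d", seq_len(spec@nPhyla))
  for (pi in seq_len(spec@nPhyla))
    units[phyla[pi]] <- groupFragment(sprintf("P%02d", pi),
                                      c("Bacteria", phyla[pi]),
                                      spec@nClassesPerPhylum)
  if (spec@nSubphyla > 0L) {
    subs <- paste0(greek[seq_len(spec@nSubphyla)], "proteobacteria")
    subFrags <- vapply(seq_len(spec@nSubphyla), function(si) {
      groupFragment(sprintf("PR%02d", si),
                    c("Bacteria", "Proteobacteria", subs[si]),
                    spec@nClassesPerSubphylum)
    }, "")
    if (length(subFrags) == 1L) {
      units[["Proteobacteria"]] <- subFrags
    } else {
      holder <- sprintf("HOLD%04d", seq_along(subFrags))
      bb <- .randSubtreeNewick(holder, spec@withinMean, spec@withinFloor)
      for (i in seq_along(subFrags))
        bb <- sub(holder[i], subFrags[i], bb, fixed = TRUE)
      units[["Proteobacteria"]] <- .asFragment(bb)
    }
  }
  if (length(units) == 1L)
    stop("need at least two phylum-level units to build a tree")
  holder <- sprintf("UNIT%04d", seq_along(units))
  bb <- .randSubtreeNewick(holder, spec@backboneMean, spec@backboneFloor)
  for (i in seq_along(units))
    bb <- sub(holder[i], units[[i]], bb, fixed = TRUE)
  tree <- ape::read.tree(text = paste0(.asFragment(bb), ";"))
  list(tree = tree, taxonomy = taxonomy[tree$tip.label])
}

# Per-column relative rate over the alignment: anchor columns (leading
# fraction of each sub-region, plus any flank before the first region) at
# anchorRate, interiors at the region rate; discrete-gamma category and
# invariant mask multiply on top.
.columnRates <- function(spec) {
  tab <- spec@regionTable
  width <- tab@total$alnEnd
  base <- rep(spec@anchorRate, width)
  region <- rep(NA_character_, width)
  for (i in seq_len(nrow(tab@regions))) {
    r <- tab@regions[i, ]
    cols <- r$alnStart:r$alnEnd
    region[cols] <- r$name
    nAnchor <- ceiling(spec@conservedAnchorFraction * length(cols))
    rates <- rep(spec@perRegionRate[[r$name]], length(cols))
    if (nAnchor > 0)                    # anchors down-weight the region rate
      rates[seq_len(nAnchor)] <- rates[seq_len(nAnchor)] * spec@anchorRate
    base[cols] <- rates
  }
  gam <- phangorn::discrete.gamma(spec@gammaShape, spec@gammaCategories)
  cat <- sample.int(spec@gammaCategories, width, replace = TRUE)
  inv <- stats::runif(width) < spec@pInvariant
  rate <- base * gam[cat] * as.numeric(!inv)
  list(rate = rate, region = region, base = base)
}

#' Simulate an aligned dataset down the true tree
#'
#' Evolves sequences along the tree under GTR with the per-column rate
#' mosaic of the spec (region rate x conserved-anchor down-weighting x
#' discrete-gamma category x invariant mask), then appends the
#' spec-controlled contaminants: organelle-labelled copies (excluded by the
#' taxonomy filter) and gap-truncated short records (excluded by the length
#' filter). Full-length synthetic records contain no alignment gaps; gaps
#' enter only through the deliberately truncated records. Uses the current
#' RNG state; see [makeBenchmark()] for seeding.
#'
#' @param truth output of [sampleTrueTree()].
#' @param spec a [SimulationSpec-class].
#' @return A [RegionAlignment-class] with attribute `"columnRates"` (the
#'   realised per-column relative rates).
#' @export
simulateAlignment <- function(truth, spec) {
  tree <- truth$tree
  width <- spec@regionTable@total$alnEnd
  rates <- .columnRates(spec)
  n <- ape::Ntip(tree)
  seqMat <- matrix("A", n, width, dimnames = list(tree$tip.label, NULL))
  for (r in sort(unique(rates$rate))) {
    cols <- which(rates$rate == r)
    if (r == 0) {
      bases <- sample(c("A", "C", "G", "T"), length(cols), replace = TRUE,
                      prob = spec@baseFreqs)
      seqMat[, cols] <- matrix(bases, n, length(cols), byrow = TRUE)
    } else {
      sim <- phangorn::simSeq(tree, l = length(cols), Q = spec@gtrRates,
                              bf = spec@baseFreqs, rate = r)
      ch <- toupper(as.character(sim))
      seqMat[rownames(ch), cols] <- ch
    }
  }
  seqs <- apply(seqMat, 1L, paste, collapse = "")
  tax <- truth$taxonomy[rownames(seqMat)]
  ids <- rownames(seqMat)
  # contaminants: organelle-labelled copies of random leaves
  nOrg <- round(spec@organelleFraction * n)
  if (nOrg > 0) {
    src <- sample.int(n, nOrg, replace = TRUE)
    orgTax <- rep_len(c("Bacteria;Cyanobacteria;Chloroplast",
                        "Bacteria;Alphaproteobacteria;Mitochondria"), nOrg)
    seqs <- c(seqs, seqs[src])
    tax <- c(tax, orgTax)
    ids <- c(ids, sprintf("ORG%03d", seq_len(nOrg)))
  }
  # short records: gap-truncated below the (scaled) length threshold
  nShort <- round(spec@shortFraction * n)
  if (nShort > 0) {
    thr <- benchmarkLengthThreshold(spec)
    keepLen <- max(1L, min(width, floor(0.8 * thr)))
    src <- sample.int(n, nShort, replace = TRUE)
    shortSeqs <- vapply(src, function(i) {
      s <- seqs[i]
      paste0(substr(s, 1L, keepLen), strrep("-", width - keepLen))
    }, "")
    seqs <- c(seqs, shortSeqs)
    tax <- c(tax, truth$taxonomy[src])
    ids <- c(ids, sprintf("SHORT%03d", seq_len(nShort)))
  }
  out <- regionAlignment(seqs, ids = ids, taxonomy = tax)
  attr(out, "columnRates") <- rates$rate
  out
}

#' @describeIn makeBenchmark The length-filter threshold matched to the
#'   spec's alignment scale (`round(1400 * VT width / 14364)`).
#' @export
benchmarkLengthThreshold <- function(spec) {
  ref <- builtinRegionTable()@total
  refWidth <- ref$alnEnd - ref$alnStart + 1L
  tot <- spec@regionTable@total
  as.integer(round(1400 * (tot$alnEnd - tot$alnStart + 1L) / refWidth))
}

#' Write a complete synthetic benchmark to disk
#'
#' Generates one reproducible dataset from `(spec, seed)` and writes:
#' `alignment.fasta` (SILVA-style headers), `taxonomy.tsv`,
#' `true_tree.nwk`, `region_rates.tsv` (per-region rate summary),
#' `spec.yaml` and `manifest.json` (seed, counts and the recommended
#' sampling configuration, including the scale-matched length threshold).
#' Identical spec and seed give byte-identical files.
#'
#' @param spec a [SimulationSpec-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
makeBenchmark <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec@seed)
  truth <- sampleTrueTree(spec)
  aln <- simulateAlignment(truth, spec)
  paths <- list(
    alignment = file.path(dir, "alignment.fasta"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    tree = file.path(dir, "true_tree.nwk"),
    rates = file.path(dir, "region_rates.tsv"),
    spec = file.path(dir, "spec.yaml"),
    manifest = file.path(dir, "manifest.json"))
  writeAlignedFasta(aln, paths$alignment)
  utils::write.table(
    data.frame(id = names(aln), taxonomy = taxonomyStrings(aln)),
    paths$taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
  writeNewick(truth$tree, paths$tree)
  reg <- spec@regionTable@regions
  utils::write.table(
    data.frame(region = reg$name, alnStart = reg$alnStart,
               alnEnd = reg$alnEnd,
               rate = spec@perRegionRate[reg$name],
               anchorCols = ceiling(spec@conservedAnchorFraction *
                                    (reg$alnEnd - reg$alnStart + 1L))),
    paths$rates, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(specAsList(spec), paths$spec)
  thr <- benchmarkLengthThreshold(spec)
  jsonlite::write_json(list(
    seed = spec@seed,
    nLeaves = ape::Ntip(truth$tree),
    nRecords = length(aln),
    alignmentWidth = spec@regionTable@total$alnEnd,
    recommendedSampling = list(minUngappedLength = thr)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(spec = spec, truth = truth, alignment = aln,
                 paths = paths))
}

#' @describeIn makeBenchmark The spec as a plain serialisable list.
#' @export
specAsList <- function(spec) {
  sl <- slotNames(spec)
  out <- lapply(sl, function(s) {
    v <- slot(spec, s)
    if (is(v, "RegionTable")) rbind(v@regions, v@total) else v
  })
  names(out) <- sl
  out
}
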