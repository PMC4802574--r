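# End-to-end orchestration: filter -> stratified lists -> per-(list, region)
# trees -> all pairwise BHV geodesics -> summary, per-list AHC, consensus,
# classification; every intermediate artifact is written to the output
# directory together with a JSON manifest.

#' Construct a PipelineConfig
#'
#' @param alignment path to an aligned FASTA or a [RegionAlignment-class].
#' @param outDir output directory.
#' @param taxonomy optional TSV (`id`, `taxonomy`) overriding header
#'   taxonomy (ignored when `alignment` is an object).
#' @param treeDir optional directory of externally built Newick trees named
#'   `list<id>_<region>.nwk`; when given, tree inference is skipped and a
#'   missing file is a hard error.
#' @param regionTable the [RegionTable-class] to slice with.
#' @param include region names analysed (default V2--V8 and VT).
#' @param mergedSets optional list of consecutive-region name vectors (e.g.
#'   `list(c("V4","V5","V6"))`) analysed as additional merged blocks.
#' @param sampling a [SamplingConfig-class]; its seed defaults to `seed`.
#' @param model distance model for the built-in engine (`"JC69"`, `"K80"`,
#'   `"p"`).
#' @param minOverlap,maxDistance distance-engine guards (see
#'   [distanceMatrix()]).
#' @param linkage AHC linkage (`"average"`, `"complete"`, `"single"`).
#' @param classCuts rank cut points for [classifyRegions()].
#' @param seed seed recorded in the manifest and used for sampling.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(alignment, outDir, taxonomy = NULL,
                           treeDir = NULL,
                           regionTable = builtinRegionTable(),
                           include = c(paste0("V", 2:8), "VT"),
                           mergedSets = NULL,
                           sampling = NULL, model = "JC69",
                           minOverlap = 50L, maxDistance = 5,
                           linkage = "average", classCuts = c(3L, 2L, 2L),
                           seed = 1L) {
  if (is.null(sampling)) sampling <- samplingConfig(seed = seed)
  new("PipelineConfig", alignment = alignment, taxonomy = taxonomy,
      treeDir = treeDir, regionTable = regionTable, include = include,
      mergedSets = mergedSets, sampling = sampling, model = model,
      minOverlap = as.integer(minOverlap), maxDistance = maxDistance,
      linkage = linkage, classCuts = as.integer(classCuts),
      outDir = outDir, seed = as.integer(seed))
}

.regionSlicer <- function(config) {
  tab <- config@regionTable
  defs <- lapply(config@include, function(nm) regionDefinition(tab, nm))
  if (!is.null(config@mergedSets))
    defs <- c(defs, lapply(config@mergedSets,
                           function(nm) mergedRegionDefinition(tab, nm)))
  names(defs) <- vapply(defs, function(d) d$name, "")
  defs
}

.stageFail <- function(outDir, stage, listId, region, err) {
  writeLines(sprintf("FAILED at stage '%s' (list %s, region %s): %s",
                     stage, listId, region, conditionMessage(err)),
             file.path(outDir, "FAILED"))
  stop("pipeline stage '", stage, "' failed for list ", listId,
       ", region ", region, ": ", conditionMessage(err), call. = FALSE)
}

#' Run the full region-sensitivity analysis
#'
#' Executes the workflow end to end: filter the alignment, draw the
#' stratified taxonomic lists, slice every list into the included regions
#' (plus any merged blocks), build one tree per (list, region) with the
#' built-in distance/NJ engine (or ingest external Newick trees), compute
#' all pairwise BHV geodesic distances per list, then summarise: per-region
#' mean/SD distance to the full-length tree, per-list AHC, majority-rule
#' consensus with node supports, and the sensitivity classification. All
#' artifacts are written under `config@outDir`:
#' `trees/list<id>_<region>.nwk`, `distances.tsv`, `fig_summary.tsv`,
#' `ahc_trees.nwk`, `consensus.nwk`, `classes.tsv`, `lists/`,
#' `manifest.json`. Any stage error aborts with the stage, list and region
#' named, leaving partial outputs plus a `FAILED` marker.
#'
#' @param config a [PipelineConfig-class].
#' @return Invisibly, a list with `plan`, `lists`, `trees`, `distances`
#'   (long data.frame), `matrices`, `summary`, `dendrograms`, `consensus`,
#'   `classes`, `manifestPath`.
#' @export
runPipeline <- function(config) {
  outDir <- config@outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "FAILED"))
  aln <- if (is(config@alignment, "RegionAlignment")) config@alignment
         else readAlignedFasta(config@alignment, config@taxonomy)
  filtered <- filterDataset(aln, config@sampling)
  lists <- generateLists(filtered, config@sampling)
  writeLists(lists, filtered, config@sampling, file.path(outDir, "lists"))
  defs <- .regionSlicer(config)
  regions <- names(defs)
  plan <- planSummary(length(lists), length(regions),
                      listSize = length(lists[[1]]$members))
  treeDir <- file.path(outDir, "trees")
  dir.create(treeDir, showWarnings = FALSE)
  trees <- list()
  for (tl in lists) {
    sub <- filtered[tl$members]
    for (rg in regions) {
      fname <- sprintf("list%d_%s.nwk", tl$listId, rg)
      tr <- tryCatch({
        if (!is.null(config@treeDir)) {
          src <- file.path(config@treeDir, fname)
          if (!file.exists(src))
            stop("external tree file missing: ", src)
          ingestNewick(src)
        } else {
          slice <- extractRegion(sub, defs[[rg]], config@regionTable)
          m <- distanceMatrix(slice, model = config@model,
                              minOverlap = config@minOverlap,
                              maxDistance = config@maxDistance)
          njTree(m)
        }
      }, error = function(e) .stageFail(outDir, "tree", tl$listId, rg, e))
      writeNewick(tr, file.path(treeDir, fname))
      trees[[fname]] <- tr
    }
  }
  rows <- list()
  for (tl in lists) {
    for (i in seq_along(regions)[-length(regions)]) {
      for (j in (i + 1L):length(regions)) {
        d <- tryCatch(
          bhvDistance(trees[[sprintf("list%d_%s.nwk", tl$listId, regions[i])]],
                      trees[[sprintf("list%d_%s.nwk", tl$listId, regions[j])]]),
          error = function(e)
            .stageFail(outDir, "geodesic", tl$listId,
                       paste(regions[i], regions[j], sep = "-"), e))
        rows[[length(rows) + 1L]] <- data.frame(
          list_id = tl$listId, region_a = regions[i],
          region_b = regions[j], distance = d)
      }
    }
  }
  distances <- do.call(rbind, rows)
  utils::write.table(distances, file.path(outDir, "distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  matrices <- distancesToMatrices(distances)
  vtName <- config@regionTable@total$name
  summary <- vtSummary(matrices, vt = vtName)
  utils::write.table(summary, file.path(outDir, "fig_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dendros <- lapply(matrices, ahcCluster, linkage = config@linkage)
  ahcNwk <- vapply(dendros, dendrogramToNewick, "")
  writeLines(ahcNwk, file.path(outDir, "ahc_trees.nwk"))
  consensus <- majorityConsensus(unname(ahcNwk))
  tcons <- consensus@tree
  writeLines(ape::write.tree(tcons), file.path(outDir, "consensus.nwk"))
  classes <- classifyRegions(summary, cuts = config@classCuts)
  utils::write.table(classes, file.path(outDir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = config@seed,
    engine = if (is.null(config@treeDir)) paste0("builtin:", config@model,
                                                 "+NJ")
             else paste0("external:", config@treeDir),
    regions = regions, linkage = config@linkage,
    sampling = list(nLists = config@sampling@nLists,
                    perStratum = config@sampling@perStratum,
                    minUngappedLength = config@sampling@minUngappedLength,
                    seed = config@sampling@seed),
    plan = plan,
    actual = list(trees = length(trees), distances = nrow(distances)))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  if (manifest$actual$trees != plan$trees ||
      manifest$actual$distances != plan$distances)
    stop("count conservation violated: trees/distances do not match the plan")
  invisible(list(plan = plan, lists = lists, trees = trees,
                 distances = distances, matrices = matrices,
                 summary = summary, dendrograms = dendros,
                 consensus = consensus, classes = classes,
                 manifestPath = manifestPath))
}

#' Human-readable run report
#'
#' Prints the per-region mean +/- SD distance to the full-length tree with
#' ranks and class assignments (tie flags surfaced), the consensus tree with
#' supports, and the configuration echo from the manifest.
#'
#' @param result return value of [runPipeline()].
#' @return Invisibly, the report lines.
#' @export
pipelineReport <- function(result) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("Region sensitivity report (%d lists, %d regions)",
      attr(result$summary, "nLists"), nrow(result$summary) + 1L)
  add("%-8s %10s %10s %5s %6s %4s", "region", "mean", "sd", "rank",
      "class", "tie")
  cls <- result$classes
  for (i in seq_len(nrow(cls)))
    add("%-8s %10.5f %10.5f %5d %6s %4s", cls$region[i], cls$mean[i],
        result$summary$sd[match(cls$region[i], result$summary$region)],
        cls$rank[i], cls$class[i], if (cls$tie[i]) "tie" else "")
  add("consensus: %s", ape::write.tree(result$consensus@tree))
  mf <- jsonlite::read_json(result$manifestPath)
  add("engine: %s; linkage: %s; seed: %s; trees: %d; distances: %d",
      mf$engine, mf$linkage, mf$seed, mf$actual$trees,
      mf$actual$distances)
  cat(lines, sep = "\n")
  invisible(lines)
}
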