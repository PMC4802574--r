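#' Construct a SamplingConfig
#'
#' @param nLists number of taxonomic lists to draw (reference design: 89).
#' @param perStratum representatives per stratum (reference design: 3).
#' @param minUngappedLength keep records strictly longer than this
#'   (reference design: 1400 ungapped residues).
#' @param seed RNG seed; list `i` uses sub-seed `seed + i`.
#' @param proteobacteriaLabel phylum treated as a set of subphylum strata.
#' @param organelleKeywords taxonomy substrings excluding a record.
#' @return A [SamplingConfig-class].
#' @examples
#' samplingConfig(nLists = 89, seed = 1)
#' @export
samplingConfig <- function(nLists = 89L, perStratum = 3L,
                           minUngappedLength = 1400L, seed = 1L,
                           proteobacteriaLabel = "Proteobacteria",
                           organelleKeywords = c("Chloroplast",
                                                 "Mitochondria")) {
  new("SamplingConfig", nLists = as.integer(nLists),
      perStratum = as.integer(perStratum),
      minUngappedLength = as.integer(minUngappedLength),
      seed = as.integer(seed),
      proteobacteriaLabel = proteobacteriaLabel,
      organelleKeywords = organelleKeywords)
}

#' @export
setMethod("show", "SamplingConfig", function(object) {
  cat("SamplingConfig:", object@nLists, "lists x", object@perStratum,
      "per stratum; ungapped length >", object@minUngappedLength,
      "; seed", object@seed, "\n")
  cat("  subphylum-stratified phylum:", object@proteobacteriaLabel, "\n")
  cat("  organelle keywords:", paste(object@organelleKeywords,
                                     collapse = ", "), "\n")
})

#' Filter an aligned dataset for sampling
#'
#' Retains records that (1) are strictly longer than
#' `minUngappedLength` ungapped residues, (2) carry a non-empty taxonomy
#' annotation, and (3) contain no organelle keyword anywhere in their
#' taxonomy path. Record order is preserved; the retained/removed counts are
#' reported as a message and an empty result raises a warning.
#'
#' @param x a [RegionAlignment-class] with taxonomy.
#' @param config a [SamplingConfig-class].
#' @return The filtered [RegionAlignment-class].
#' @export
filterDataset <- function(x, config = samplingConfig()) {
  if (length(x) == 0L) return(x)
  lenOK <- ungappedLength(x) > config@minUngappedLength
  tx <- taxonomyStrings(x)
  taxOK <- !is.na(tx) & nzchar(tx)
  orgHit <- rep(FALSE, length(x))
  for (kw in config@organelleKeywords)
    orgHit <- orgHit | grepl(kw, tx, fixed = TRUE)
  orgHit[is.na(tx)] <- FALSE
  keep <- lenOK & taxOK & !orgHit
  message(sprintf(
    "filterDataset: kept %d / %d (removed %d short, %d unannotated, %d organellar)",
    sum(keep), length(x), sum(!lenOK), sum(lenOK & !taxOK),
    sum(lenOK & taxOK & orgHit)))
  if (!any(keep)) warning("no records pass the filters")
  x[keep]
}

# Stratum layout: ordinary phyla are one stratum each with next-lower-rank
# groups at path depth 3; subphyla of the designated phylum are separate
# strata with groups (classes) at depth 4.
.strataOf <- function(x, config) {
  paths <- taxonomyPaths(x)
  ids <- names(x)
  phylum <- vapply(paths, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  isProteo <- !is.na(phylum) & phylum == config@proteobacteriaLabel
  key <- ifelse(isProteo,
                vapply(paths, function(p) if (length(p) >= 3) p[3] else NA_character_, ""),
                phylum)
  groupRank <- ifelse(isProteo, 4L, 3L)
  grp <- vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (length(p) >= groupRank[i]) p[groupRank[i]] else paste0("__self__", ids[i])
  }, "")
  ok <- !is.na(key)
  data.frame(id = ids[ok], stratum = key[ok], group = grp[ok],
             stringsAsFactors = FALSE)
}

#' Eligible sampling strata of a filtered dataset
#'
#' One stratum per phylum holding at least `perStratum` candidate records,
#' except the designated multi-subphylum phylum (Proteobacteria in the
#' reference design), which is replaced by one stratum per subphylum (the
#' rank immediately below phylum) meeting the same threshold. Phyla or
#' subphyla with fewer candidates are discarded.
#'
#' @param x a filtered [RegionAlignment-class].
#' @param config a [SamplingConfig-class].
#' @return Named list (stratum label, sorted) of data.frames with columns
#'   `id` and `group` (the next-lower-rank group used for diversity-preferred
#'   selection).
#' @export
eligibleStrata <- function(x, config = samplingConfig()) {
  if (length(x) == 0L) return(list())
  df <- .strataOf(x, config)
  out <- split(df[c("id", "group")], df$stratum)
  out <- out[vapply(out, nrow, 0L) >= config@perStratum]
  out[order(names(out))]
}

#' Draw one stratified taxonomic list
#'
#' Draws `perStratum` members from every stratum. When a stratum contains at
#' least `perStratum` distinct next-lower-rank groups (classes under a
#' phylum, classes under a Proteobacteria-like subphylum), `perStratum`
#' distinct groups are first drawn uniformly without replacement and then
#' one member per chosen group; otherwise members are drawn uniformly
#' without replacement. Uses the current RNG state (see [generateLists()]
#' for per-list seeding).
#'
#' @param strata output of [eligibleStrata()].
#' @param config a [SamplingConfig-class].
#' @param listId integer identifier recorded in the result.
#' @return A `TaxonomicList`: list with `listId`, `members` (ordered ids)
#'   and `strata` (stratum label -> chosen ids).
#' @export
selectRepresentatives <- function(strata, config = samplingConfig(),
                                  listId = 1L) {
  k <- config@perStratum
  chosen <- lapply(strata, function(s) {
    if (nrow(s) < k)
      stop("internal invariant violation: stratum smaller than perStratum")
    groups <- sort(unique(s$group))
    if (length(groups) >= k) {
      g <- sort(groups[sample.int(length(groups), k)])
      vapply(g, function(gg) {
        ids <- sort(s$id[s$group == gg])
        ids[sample.int(length(ids), 1L)]
      }, "")
    } else {
      ids <- sort(s$id)
      sort(ids[sample.int(length(ids), k)])
    }
  })
  out <- list(listId = as.integer(listId),
              members = unname(unlist(chosen)),
              strata = chosen)
  class(out) <- "TaxonomicList"
  out
}

#' @export
print.TaxonomicList <- function(x, ...) {
  cat("TaxonomicList", x$listId, ":", length(x$members), "members from",
      length(x$strata), "strata\n")
  invisible(x)
}

#' Generate the stratified taxonomic lists
#'
#' Draws `nLists` independent lists (the reference design draws 89 lists of
#' 108 sequences from 31 ordinary phyla plus 5 Proteobacteria subphyla).
#' List `i` is drawn under sub-seed `seed + i`, making every list
#' individually reproducible; lists may overlap in membership.
#'
#' @param x a filtered [RegionAlignment-class].
#' @param config a [SamplingConfig-class].
#' @return List of `TaxonomicList` objects.
#' @export
generateLists <- function(x, config = samplingConfig()) {
  strata <- eligibleStrata(x, config)
  if (length(strata) == 0L)
    stop("no eligible strata: every phylum/subphylum has fewer than ",
         config@perStratum, " candidates")
  lapply(seq_len(config@nLists), function(i) {
    set.seed(config@seed + i)
    selectRepresentatives(strata, config, listId = i)
  })
}

#' Write taxonomic lists and their manifest
#'
#' One TSV per list (`list<id>.tsv` with columns `id`, `stratum`,
#' `taxonomy`) plus a JSON manifest recording the seed, configuration and
#' counts.
#'
#' @param lists output of [generateLists()].
#' @param x the [RegionAlignment-class] the lists were drawn from.
#' @param config the [SamplingConfig-class] used.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeLists <- function(lists, x, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- taxonomyStrings(x)
  names(tx) <- names(x)
  for (tl in lists) {
    df <- data.frame(
      id = tl$members,
      stratum = rep(names(tl$strata), lengths(tl$strata)),
      taxonomy = unname(tx[tl$members]))
    utils::write.table(df, file.path(dir, sprintf("list%d.tsv", tl$listId)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    seed = config@seed, nLists = config@nLists,
    perStratum = config@perStratum,
    minUngappedLength = config@minUngappedLength,
    proteobacteriaLabel = config@proteobacteriaLabel,
    organelleKeywords = config@organelleKeywords,
    nStrata = length(lists[[1]]$strata),
    membersPerList = length(lists[[1]]$members))
  path <- file.path(dir, "lists_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Bookkeeping of the full analysis plan
#'
#' Computes the tree and distance counts implied by a design: one tree per
#' (list, region), all region pairs per list, and the total number of
#' sequence slots. The reference design (89 lists, 8 regions, 108 members)
#' yields 712 trees, 2492 geodesic distances, 28 pairs per list and 76,896
#' sequence slots.
#'
#' @param nLists number of taxonomic lists (>= 1).
#' @param nRegions number of regions compared (>= 2).
#' @param listSize members per list.
#' @return List with `trees`, `distances`, `pairsPerList`, `listSize`,
#'   `sequenceSlots`.
#' @examples
#' planSummary(89, 8, 108)
#' @export
planSummary <- function(nLists, nRegions, listSize = 108L) {
  stopifnot(nLists >= 1, nRegions >= 2)
  list(trees = as.integer(nLists * nRegions),
       distances = as.integer(nLists * choose(nRegions, 2)),
       pairsPerList = as.integer(choose(nRegions, 2)),
       listSize = as.integer(listSize),
       sequenceSlots = as.integer(nLists * listSize * nRegions))
}
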