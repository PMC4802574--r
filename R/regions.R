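.asRegionDef <- function(region, table) {
  if (is.character(region)) {
    stopifnot(length(region) == 1L)
    regionDefinition(table, region)
  } else if (is.data.frame(region) && nrow(region) == 1L) {
    region
  } else {
    stop("region must be a region name or a one-row definition")
  }
}

#' Extract one sub-region from an alignment
#'
#' Slices each record to the region's alignment columns
#' `alnStart..alnEnd` (1-based, inclusive at both ends). Identifiers and
#' taxonomy are preserved; the sliced records use fresh 1-based columns.
#'
#' @param x a [RegionAlignment-class].
#' @param region region name (looked up in `table`) or a one-row definition.
#' @param table the [RegionTable-class] used for name lookup.
#' @return A [RegionAlignment-class] of width `alnEnd - alnStart + 1`.
#' @examples
#' aln <- regionAlignment(c(S1 = strrep("ACGT", 4)))
#' def <- data.frame(name = "toy", alnStart = 3, alnEnd = 6,
#'                   refStart = 3, refEnd = 6)
#' extractRegion(aln, def)
#' @export
extractRegion <- function(x, region, table = builtinRegionTable()) {
  def <- .asRegionDef(region, table)
  w <- Biostrings::width(x)
  if (length(x) && any(w < def$alnEnd))
    stop("record '", names(x)[which(w < def$alnEnd)[1]],
         "' has only ", w[which(w < def$alnEnd)[1]],
         " columns; region ", def$name, " ends at column ", def$alnEnd)
  out <- new("RegionAlignment",
             Biostrings::subseq(x, start = def$alnStart, end = def$alnEnd))
  mcols(out)$taxonomy <- taxonomyStrings(x)
  out
}

#' Split an alignment into per-region files
#'
#' Slices every record once per requested region and returns one
#' [RegionAlignment-class] per region, in the input record order. The
#' default include set is V2--V8 plus the total (VT): V1 and V9 are mostly
#' incomplete in SILVA-style data and are excluded from downstream analysis.
#'
#' @param x a [RegionAlignment-class].
#' @param table a [RegionTable-class].
#' @param include character vector of region names (sub-regions and/or the
#'   total's name).
#' @return Named list of [RegionAlignment-class] objects.
#' @export
splitAlignment <- function(x, table = builtinRegionTable(),
                           include = c(paste0("V", 2:8), "VT")) {
  known <- c(table@regions$name, table@total$name)
  bad <- setdiff(include, known)
  if (length(bad))
    stop("unknown region name(s): ", paste(bad, collapse = ", "))
  out <- lapply(include, function(nm) extractRegion(x, nm, table))
  names(out) <- include
  out
}

#' Concatenate consecutive sub-regions
#'
#' Merges the named sub-regions into one block per record. The names must be
#' consecutive in table order; by contiguity the result equals a single
#' slice from the first region's `alnStart` to the last region's `alnEnd`.
#'
#' @param x a [RegionAlignment-class].
#' @param table a [RegionTable-class].
#' @param names ordered character vector of consecutive sub-region names.
#' @return A [RegionAlignment-class].
#' @examples
#' # V4-5-6 block of the reference map spans alignment columns 4070..10454
#' rng <- mergedRegionDefinition(builtinRegionTable(), c("V4", "V5", "V6"))
#' rng[c("alnStart", "alnEnd")]
#' @export
mergeRegions <- function(x, table = builtinRegionTable(), names) {
  def <- mergedRegionDefinition(table, names)
  extractRegion(x, def, table)
}

#' @describeIn mergeRegions The single-slice definition of a merged block
#'   (errors if `names` are not consecutive sub-regions).
#' @export
mergedRegionDefinition <- function(table, names) {
  reg <- table@regions
  idx <- match(names, reg$name)
  if (anyNA(idx))
    stop("unknown sub-region name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  if (length(idx) > 1L && !all(diff(idx) == 1L))
    stop("regions must be consecutive in table order: ",
         paste(names, collapse = ", "))
  data.frame(name = paste(reg$name[idx], collapse = "-"),
             alnStart = reg$alnStart[idx[1]],
             alnEnd = reg$alnEnd[idx[length(idx)]],
             refStart = reg$refStart[idx[1]],
             refEnd = reg$refEnd[idx[length(idx)]])
}

#' Per-record fraction of non-gap columns
#'
#' Reports how complete each record is over its columns; used to quantify
#' region completeness (e.g. the largely incomplete V1/V9 flanks).
#'
#' @param x a [RegionAlignment-class].
#' @return Named numeric vector in `[0, 1]` (empty input gives an empty
#'   result).
#' @export
regionOccupancy <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  out <- ungappedLength(x) / Biostrings::width(x)
  names(out) <- names(x)
  out
}
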