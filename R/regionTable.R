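#' Construct a RegionTable
#'
#' Builds and validates a [RegionTable-class] from a data.frame of sub-region
#' rows plus one spanning "total" row.
#'
#' @param regions data.frame with columns `name`, `alnStart`, `alnEnd`,
#'   `refStart`, `refEnd`, one row per sub-region in order.
#' @param total one-row data.frame with the same columns, spanning all
#'   regions (conventionally named `"VT"`).
#' @return A validated [RegionTable-class].
#' @examples
#' tab <- builtinRegionTable()
#' regionTable(regionDefinitions(tab), totalDefinition(tab))
#' @export
regionTable <- function(regions, total) {
  num <- c("alnStart", "alnEnd", "refStart", "refEnd")
  regions[num] <- lapply(regions[num], as.integer)
  total[num] <- lapply(total[num], as.integer)
  regions$name <- as.character(regions$name)
  total$name <- as.character(total$name)
  rownames(regions) <- NULL
  rownames(total) <- NULL
  new("RegionTable", regions = regions, total = total)
}

#' The built-in sub-region coordinate map of the SILVA 16S alignment
#'
#' Returns the reference breakpoint map dividing the columns of the
#' SILVA-aligned full-length 16S rRNA gene into the nine hypervariable
#' sub-regions V1--V9, plus the spanning region VT, in both alignment-column
#' and *E. coli* reference coordinates (1-based, inclusive). Each sub-region
#' starts with its conserved flanking (primer-binding) stretch followed by
#' the hypervariable interior; V9's terminal conserved marker is already
#' excluded from its end coordinate.
#'
#' @return A [RegionTable-class] with ten rows (V1--V9 and VT).
#' @examples
#' tab <- builtinRegionTable()
#' regionDefinition(tab, "V4")
#' @export
builtinRegionTable <- function() {
  regions <- data.frame(
    name     = paste0("V", 1:9),
    alnStart = c(8L, 790L, 2698L, 4070L, 7045L, 9534L, 10455L, 12259L, 13598L),
    alnEnd   = c(789L, 2697L, 4069L, 7044L, 9533L, 10454L, 12258L, 13597L, 14371L),
    refStart = c(8L, 97L, 307L, 488L, 747L, 886L, 1030L, 1181L, 1373L),
    refEnd   = c(96L, 306L, 487L, 746L, 885L, 1029L, 1180L, 1372L, 1468L))
  total <- data.frame(name = "VT", alnStart = 8L, alnEnd = 14371L,
                      refStart = 8L, refEnd = 1468L)
  regionTable(regions, total)
}

#' Proportionally rescaled region table
#'
#' Rescales the built-in breakpoint map (or any other table) to a smaller
#' alignment width while preserving region proportions and contiguity. The
#' inter-region boundaries are scaled and rounded; rounding collisions are
#' resolved by forcing boundaries to stay strictly increasing, so every
#' region keeps a positive width. Used by the synthetic-data generator to
#' keep desk-scale benchmarks fast.
#'
#' @param scale positive scale factor (e.g. `0.1` for a ~1437-column map).
#' @param table the [RegionTable-class] to rescale.
#' @return A [RegionTable-class] with the same region names.
#' @examples
#' scaledRegionTable(0.1)
#' @export
scaledRegionTable <- function(scale, table = builtinRegionTable()) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  reg <- table@regions
  scaleBounds <- function(starts1, ends) {
    b <- c(starts1 - 1L, ends)          # n+1 boundaries; region i = (b[i], b[i+1]]
    s <- round(b * scale)
    for (i in seq_along(s)[-1]) if (s[i] <= s[i - 1]) s[i] <- s[i - 1] + 1
    as.integer(s)
  }
  ab <- scaleBounds(reg$alnStart[1], reg$alnEnd)
  rb <- scaleBounds(reg$refStart[1], reg$refEnd)
  n <- nrow(reg)
  out <- data.frame(name = reg$name,
                    alnStart = ab[-(n + 1L)] + 1L, alnEnd = ab[-1L],
                    refStart = rb[-(n + 1L)] + 1L, refEnd = rb[-1L])
  total <- data.frame(name = table@total$name,
                      alnStart = out$alnStart[1], alnEnd = out$alnEnd[n],
                      refStart = out$refStart[1], refEnd = out$refEnd[n])
  regionTable(out, total)
}

#' Read a region table from a five-column TSV
#'
#' Loads a region coordinate map from a tab-separated file with columns
#' `name`, `aln_start`, `aln_end`, `ref_start`, `ref_end` (a header row is
#' required). The spanning total row is identified by name (default `"VT"`);
#' all other rows are sub-regions in file order. This supports alternative
#' alignments with their own breakpoints.
#'
#' @param path TSV file path.
#' @param totalName name of the spanning row.
#' @return A validated [RegionTable-class].
#' @export
readRegionTable <- function(path, totalName = "VT") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- sub("^aln_start$", "alnStart", sub("^aln_end$", "alnEnd",
               sub("^ref_start$", "refStart", sub("^ref_end$", "refEnd",
                   names(df)))))
  if (!totalName %in% df$name)
    stop("region table has no spanning row named '", totalName, "'")
  regionTable(df[df$name != totalName, , drop = FALSE],
              df[df$name == totalName, , drop = FALSE])
}

#' @describeIn builtinRegionTable Names of the sub-regions (without the total).
#' @param table a [RegionTable-class].
#' @export
regionNames <- function(table) table@regions$name

#' Accessors for RegionTable rows
#'
#' `regionDefinitions()` returns the sub-region rows, `totalDefinition()` the
#' spanning row, and `regionDefinition()` one named row (sub-region or total).
#'
#' @param table a [RegionTable-class].
#' @param name region name (one of the sub-regions or the total's name).
#' @return data.frame row(s) with columns `name`, `alnStart`, `alnEnd`,
#'   `refStart`, `refEnd`.
#' @export
regionDefinitions <- function(table) table@regions

#' @rdname regionDefinitions
#' @export
totalDefinition <- function(table) table@total

#' @rdname regionDefinitions
#' @export
regionDefinition <- function(table, name) {
  all <- rbind(table@regions, table@total)
  hit <- all[all$name == name, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("unknown region name '", name, "'; known: ",
         paste(all$name, collapse = ", "))
  hit
}

#' @export
setMethod("show", "RegionTable", function(object) {
  cat("RegionTable with", nrow(object@regions), "sub-regions +",
      object@total$name, "\n")
  print(rbind(object@regions, object@total), row.names = FALSE)
})
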