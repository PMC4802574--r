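GAP_CHARS <- c("-", ".")

#' Construct a RegionAlignment from character sequences
#'
#' Normalises raw aligned sequences (uppercasing, `U` to `T`) and wraps them
#' in a validated [RegionAlignment-class]. All sequences must have the same
#' number of columns; `-` and `.` are both accepted as gap characters.
#'
#' @param seqs character vector of gapped sequences (or a `DNAStringSet`).
#' @param ids sequence identifiers (defaults to `names(seqs)`).
#' @param taxonomy character vector of semicolon-delimited taxonomy paths
#'   (`NA` allowed), recycled to `length(seqs)` when length 1.
#' @return A [RegionAlignment-class].
#' @examples
#' aln <- regionAlignment(c(A = "ACGU-", B = "AC.TT"),
#'                        taxonomy = "Bacteria;Phylum01")
#' ungappedLength(aln)
#' @export
regionAlignment <- function(seqs, ids = names(seqs), taxonomy = NA_character_) {
  if (is.character(seqs)) {
    seqs <- toupper(seqs)
    seqs <- chartr("U", "T", seqs)
    seqs <- Biostrings::DNAStringSet(seqs)
  } else {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  names(seqs) <- ids
  out <- new("RegionAlignment", seqs)
  mcols(out)$taxonomy <- rep_len(as.character(taxonomy), length(out))
  out
}

#' Parse SILVA-style description lines into taxonomy paths
#'
#' A SILVA-style header consists of an identifier token followed by a
#' semicolon-delimited taxonomy path (`"X1 Bacteria;Proteobacteria;..."`).
#' Ranks are trimmed of surrounding blanks; an absent path yields an empty
#' path (`character(0)`), which flags the record for filtering. Headers with
#' no identifier token are a parse error naming the offending line.
#'
#' @param headers character vector of description lines.
#' @return A named list of rank paths (identifier -> character vector).
#' @examples
#' parseTaxonomy("X1 Bacteria;Proteobacteria;Alphaproteobacteria")
#' @export
parseTaxonomy <- function(headers) {
  headers <- as.character(headers)
  out <- vector("list", length(headers))
  ids <- character(length(headers))
  for (i in seq_along(headers)) {
    h <- trimws(headers[i])
    if (!nzchar(h))
      stop("malformed header (no identifier) at line ", i)
    sp <- regexpr("[ \t]", h)
    if (sp == -1L) {
      ids[i] <- h
      out[[i]] <- character(0)
    } else {
      ids[i] <- substr(h, 1L, sp - 1L)
      path <- substr(h, sp + 1L, nchar(h))
      ranks <- trimws(strsplit(path, ";", fixed = TRUE)[[1]])
      out[[i]] <- ranks[nzchar(ranks)]
    }
  }
  names(out) <- ids
  out
}

#' Read an aligned FASTA file with SILVA-style headers
#'
#' Reads a fixed-width aligned FASTA, normalises residues (`U` -> `T`,
#' uppercase; `-` and `.` kept as gaps) and parses the taxonomy path out of
#' each description line. An optional two-column TSV (`id`, `taxonomy`)
#' overrides header-derived taxonomy.
#'
#' @param path FASTA file.
#' @param taxonomyTsv optional TSV path with columns `id` and `taxonomy`.
#' @return A [RegionAlignment-class] with taxonomy in `mcols()`.
#' @export
readAlignedFasta <- function(path, taxonomyTsv = NULL) {
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  tax <- parseTaxonomy(headers)
  seqs <- as.character(raw)
  aln <- regionAlignment(seqs, ids = names(tax),
                         taxonomy = vapply(tax, paste, "", collapse = ";"))
  if (!is.null(taxonomyTsv)) {
    tt <- utils::read.delim(taxonomyTsv, stringsAsFactors = FALSE)
    if (!all(c("id", "taxonomy") %in% names(tt)))
      stop("taxonomy TSV must have columns 'id' and 'taxonomy'")
    idx <- match(names(aln), tt$id)
    hit <- !is.na(idx)
    mcols(aln)$taxonomy[hit] <- tt$taxonomy[idx[hit]]
  }
  aln
}

#' Write a RegionAlignment to aligned FASTA
#'
#' Headers are `id taxonomy` (taxonomy omitted when `NA`); sequence lines are
#' wrapped at 80 columns.
#'
#' @param x a [RegionAlignment-class].
#' @param path output file.
#' @export
writeAlignedFasta <- function(x, path) {
  tax <- taxonomyStrings(x)
  out <- Biostrings::BStringSet(as.character(x))
  names(out) <- ifelse(is.na(tax) | !nzchar(tax), names(x),
                       paste(names(x), tax))
  Biostrings::writeXStringSet(out, path, width = 80L)
  invisible(path)
}

#' Taxonomy accessors
#'
#' `taxonomyStrings()` returns the semicolon-joined path per record;
#' `taxonomyPaths()` the split rank paths (empty `character(0)` for
#' unannotated records).
#'
#' @param x a [RegionAlignment-class].
#' @export
taxonomyStrings <- function(x) {
  tx <- mcols(x)$taxonomy
  if (is.null(tx)) rep(NA_character_, length(x)) else as.character(tx)
}

#' @rdname taxonomyStrings
#' @export
taxonomyPaths <- function(x) {
  tx <- taxonomyStrings(x)
  out <- lapply(tx, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    r <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    r[nzchar(r)]
  })
  names(out) <- names(x)
  out
}

#' Ungapped length of each record
#'
#' Counts non-gap residues (`-` and `.` both count as gaps).
#'
#' @param x a [RegionAlignment-class].
#' @return Named integer vector.
#' @export
ungappedLength <- function(x) {
  if (length(x) == 0L) return(integer(0))
  gaps <- rowSums(Biostrings::letterFrequency(x, letters = GAP_CHARS))
  out <- as.integer(Biostrings::width(x) - gaps)
  names(out) <- names(x)
  out
}

#' @export
setMethod("show", "RegionAlignment", function(object) {
  cat("RegionAlignment:", length(object), "records x",
      if (length(object)) Biostrings::width(object)[1] else 0, "columns\n")
  if (length(object)) {
    tx <- taxonomyStrings(object)
    k <- min(length(object), 5L)
    for (i in seq_len(k))
      cat(" ", names(object)[i], " [",
          substr(as.character(object[[i]]), 1, 40),
          if (Biostrings::width(object)[1] > 40) "..." else "",
          "] ", if (is.na(tx[i])) "" else tx[i], "\n", sep = "")
    if (length(object) > k) cat("  ...", length(object) - k, "more\n")
  }
})
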