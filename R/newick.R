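#' Ingest and validate a Newick tree
#'
#' Parses a Newick tree (e.g. one exported from a Bayesian analysis),
#' validates it for tree-space comparison and normalises it to the unrooted
#' convention: leaf labels must be unique, every edge needs a branch length,
#' tiny negative lengths (> -1e-9, numerical noise) are clamped to 0 and
#' anything more negative is a format error, and a degree-2 root is
#' suppressed (its two child edges merge, summing their lengths).
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text optional Newick string, used instead of `file`.
#' @return An unrooted `ape::phylo`.
#' @examples
#' tr <- ingestNewick(text = "((A:1,B:1):0.5,C:1,D:1);")
#' @export
ingestNewick <- function(file = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("unparsable Newick input",
         if (!is.null(file)) paste0(" in '", file, "'") else "")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths")
  if (any(tr$edge.length <= -1e-9))
    stop("negative branch length(s) as low as ", min(tr$edge.length))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- ape::collapse.singles(tr)
  if (ape::is.rooted(tr) && ape::Ntip(tr) >= 3L) tr <- ape::unroot(tr)
  tr
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeNewick <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}
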