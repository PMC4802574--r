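# Split (bipartition) machinery shared by the tree-space code.
# A split is stored as a logical vector over the *sorted* leaf labels,
# canonicalised to the side NOT containing the lexicographically smallest
# leaf, so equal bipartitions compare equal.

.descTips <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Split decomposition of a tree
#'
#' Extracts every internal edge of an unrooted tree as a canonical
#' bipartition (the side not containing the lexicographically smallest leaf)
#' together with its branch length, plus the pendant-edge length of every
#' leaf. Zero-length internal edges are dropped: a zero-length split is
#' topologically absent in BHV tree space. Polytomies are supported, so the
#' number of splits need not be `n - 3`.
#'
#' @param tree an `ape::phylo` (a rooted tree is unrooted first).
#' @return List with `labels` (sorted leaf labels), `sides` (logical matrix,
#'   one row per internal split over `labels`), `lengths`, `keys` (canonical
#'   string form) and `pendant` (named lengths per leaf).
#' @examples
#' sp <- splitsOf(ingestNewick(text = "((A:1,B:1):0.3,C:1,D:1);"))
#' sp$keys     # one split: {A,B}
#' @export
splitsOf <- function(tree) {
  if (ape::is.rooted(tree) && ape::Ntip(tree) >= 3L) tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  labels <- sort(tree$tip.label)
  ord <- match(tree$tip.label, labels)   # tip index -> sorted position
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  sets <- .descTips(tree)
  sides <- NULL
  lens <- numeric(0)
  pendant <- numeric(n)
  names(pendant) <- labels
  rootNode <- n + 1L
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    len <- tree$edge.length[k]
    if (ch <= n) {
      pendant[ord[ch]] <- len
    } else if (len > 0) {
      side <- logical(n)
      side[ord[sets[[ch]]]] <- TRUE
      if (side[1]) side <- !side
      if (sum(side) >= 2L && sum(!side) >= 2L) {
        sides <- rbind(sides, side)
        lens <- c(lens, len)
      }
    }
  }
  if (is.null(sides)) sides <- matrix(logical(0), 0, n)
  colnames(sides) <- labels
  rownames(sides) <- NULL
  keys <- apply(sides, 1L, function(s) paste(which(s), collapse = ","))
  if (length(keys) == 0L) keys <- character(0)
  if (anyDuplicated(keys)) {            # polytomy-safe: merge duplicate splits
    agg <- tapply(lens, keys, sum)
    first <- !duplicated(keys)
    sides <- sides[first, , drop = FALSE]
    keysU <- keys[first]
    lens <- as.numeric(agg[keysU])
    keys <- keysU
  }
  list(labels = labels, sides = sides, lengths = lens, keys = keys,
       pendant = pendant)
}

#' Are two splits compatible?
#'
#' Two bipartitions of one leaf set are compatible (can coexist in a single
#' tree) iff at least one of the four side/complement intersections is
#' empty.
#'
#' @param s,t logical vectors of equal length: one side of each split over a
#'   shared leaf ordering.
#' @return `TRUE`/`FALSE`.
#' @examples
#' splitCompatible(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE, FALSE))
#' @export
splitCompatible <- function(s, t) {
  if (length(s) != length(t))
    stop("splits must be over the same leaf set")
  !any(s & t) || !any(s & !t) || !any(!s & t) || !any(!s & !t)
}

# Pairwise incompatibility between two stacks of splits (rows), vectorised:
# splits a, b are incompatible iff all four crossings are non-empty.
.incompatMatrix <- function(S1, S2) {
  if (nrow(S1) == 0L || nrow(S2) == 0L)
    return(matrix(FALSE, nrow(S1), nrow(S2)))
  A <- S1 * 1; B <- S2 * 1
  i11 <- tcrossprod(A, B) > 0
  i10 <- tcrossprod(A, 1 - B) > 0
  i01 <- tcrossprod(1 - A, B) > 0
  i00 <- tcrossprod(1 - A, 1 - B) > 0
  i11 & i10 & i01 & i00
}

#' Robinson-Foulds topology distance
#'
#' Counts the internal splits present in exactly one of the two trees
#' (zero-length internal edges count as absent). Used for topology-only
#' truth-recovery checks on synthetic data.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @return Non-negative integer.
#' @export
topologyDistance <- function(t1, t2) {
  s1 <- splitsOf(t1); s2 <- splitsOf(t2)
  if (!identical(s1$labels, s2$labels))
    stop("trees have different leaf sets")
  length(setdiff(s1$keys, s2$keys)) + length(setdiff(s2$keys, s1$keys))
}
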