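#' ConsensusTree: majority-rule consensus with node supports
#'
#' Result of [majorityConsensus()]: the clades occurring in strictly more
#' than half of the input (rooted) clusterings, each with its supportive
#' probability `100 * occurrences / nTrees`, assembled into the unique
#' compatible rooted tree.
#'
#' @slot clades list of leaf-label sets (proper clades only).
#' @slot support percent support per clade, in (50, 100].
#' @slot nTrees number of input trees.
#' @slot tree `ape::phylo` with supports as internal node labels.
#' @exportClass ConsensusTree
setClass("ConsensusTree",
         representation(clades = "list", support = "numeric",
                        nTrees = "integer", tree = "ANY"))

.validConsensusTree <- function(object) {
  s <- object@support
  if (length(s) != length(object@clades))
    return("one support value per clade required")
  if (length(s) && (any(s <= 50) || any(s > 100)))
    return("supports must lie in (50, 100]")
  TRUE
}
setValidity("ConsensusTree", .validConsensusTree)

#' Per-region distance to the full-length (VT) tree
#'
#' Summarises, across taxonomic lists, the geodesic distance between each
#' sub-region's tree and the full-length (VT) tree: mean, sample standard
#' deviation and rank (1 = closest to VT). With a single list the SD is
#' undefined and reported as 0 with `sdEstimated = FALSE`. Regions whose
#' mean is tied with another region's are flagged.
#'
#' @param matrices list of per-list symmetric region-distance matrices with
#'   identical dimnames including `vt`.
#' @param vt label of the full-length region (default `"VT"`).
#' @param se if `TRUE`, report the standard error of the mean instead of
#'   the SD.
#' @return data.frame with columns `region`, `mean`, `sd`, `rank`, `tie`,
#'   `sdEstimated`, ordered by rank; attribute `nLists`.
#' @export
vtSummary <- function(matrices, vt = "VT", se = FALSE) {
  if (length(matrices) == 0L) stop("need at least one distance matrix")
  labs <- rownames(matrices[[1]])
  if (!vt %in% labs)
    stop("full-length region '", vt, "' missing from the matrix labels")
  regions <- setdiff(labs, vt)
  vals <- vapply(matrices, function(m) m[regions, vt], numeric(length(regions)))
  vals <- matrix(vals, nrow = length(regions),
                 dimnames = list(regions, NULL))
  mu <- rowMeans(vals)
  nL <- ncol(vals)
  if (nL > 1L) {
    sdv <- apply(vals, 1L, stats::sd)
    if (se) sdv <- sdv / sqrt(nL)
    sdEst <- TRUE
  } else {
    sdv <- rep(0, length(regions))
    sdEst <- FALSE
  }
  rk <- rank(mu, ties.method = "min")
  tie <- duplicated(mu) | duplicated(mu, fromLast = TRUE)
  out <- data.frame(region = regions, mean = mu, sd = sdv,
                    rank = as.integer(rk), tie = tie, sdEstimated = sdEst,
                    row.names = NULL)
  out <- out[order(out$rank, out$region), ]
  rownames(out) <- NULL
  attr(out, "nLists") <- nL
  out
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' AHC on a raw dissimilarity matrix under average (UPGMA-style, default),
#' complete or single linkage. When several cluster pairs attain the
#' minimum inter-cluster dissimilarity, the pair whose sorted label pair is
#' lexicographically smallest is merged; a cluster is labelled by its
#' lexicographically smallest member, making merge sequences fully
#' deterministic.
#'
#' @param m symmetric dissimilarity matrix with dimnames (>= 2 labels).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return A `Dendrogram`: list with `labels`, `merges` (data.frame `step`,
#'   `cluster1`, `cluster2`, `height`) and the nested `tree`.
#' @examples
#' m <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ahcCluster(m)$merges
#' @export
ahcCluster <- function(m, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || is.null(rownames(m)) || nrow(m) < 2L)
    stop("need a labelled dissimilarity matrix with at least 2 labels")
  labs <- rownames(m)
  nodes <- lapply(labs, function(l) list(label = l, height = 0, leaf = TRUE))
  names(nodes) <- labs
  sizes <- stats::setNames(rep(1L, length(labs)), labs)
  D <- m[order(labs), order(labs), drop = FALSE]
  merges <- NULL
  step <- 0L
  while (nrow(D) > 1L) {
    ut <- upper.tri(D)
    h <- min(D[ut])
    cand <- which(D <= h & ut, arr.ind = TRUE)
    key <- paste(rownames(D)[cand[, 1]], colnames(D)[cand[, 2]], sep = "\r")
    pick <- cand[order(key)[1], ]
    l1 <- rownames(D)[pick[1]]; l2 <- colnames(D)[pick[2]]
    step <- step + 1L
    merges <- rbind(merges, data.frame(step = step, cluster1 = l1,
                                       cluster2 = l2, height = h))
    newNode <- list(label = min(l1, l2), height = h, leaf = FALSE,
                    children = nodes[c(l1, l2)])
    keep <- setdiff(rownames(D), c(l1, l2))
    dNew <- vapply(keep, function(kk) {
      switch(linkage,
             average = (sizes[l1] * D[l1, kk] + sizes[l2] * D[l2, kk]) /
                       (sizes[l1] + sizes[l2]),
             complete = max(D[l1, kk], D[l2, kk]),
             single = min(D[l1, kk], D[l2, kk]))
    }, numeric(1))
    lab <- min(l1, l2)
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dNew), c(dNew, 0))
    rownames(D)[nrow(D)] <- lab
    colnames(D)[ncol(D)] <- lab
    ordr <- order(rownames(D))
    D <- D[ordr, ordr, drop = FALSE]
    nodes[[l1]] <- NULL; nodes[[l2]] <- NULL
    nodes[[lab]] <- newNode
    sizes[lab] <- sizes[l1] + sizes[l2]
  }
  out <- list(labels = sort(labs), merges = merges, tree = nodes[[1]])
  class(out) <- "Dendrogram"
  out
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat("Dendrogram over", length(x$labels), "labels;",
      nrow(x$merges), "merges\n")
  print(x$merges, row.names = FALSE)
  invisible(x)
}

#' Convert a dendrogram to rooted Newick
#'
#' Topology-only by default (the consensus step consumes topologies); with
#' `withHeights = TRUE` branch lengths reconstruct the merge heights
#' (ultrametric edge lengths `parent height - child height`).
#'
#' @param d a `Dendrogram` from [ahcCluster()].
#' @param withHeights emit branch lengths?
#' @return A rooted Newick string.
#' @export
dendrogramToNewick <- function(d, withHeights = FALSE) {
  rec <- function(node, parentHeight) {
    body <- if (isTRUE(node$leaf)) node$label
            else paste0("(", paste(vapply(node$children, rec, "",
                                          parentHeight = node$height),
                                   collapse = ","), ")")
    if (withHeights && !is.null(parentHeight))
      paste0(body, ":", sprintf("%.12g", parentHeight - node$height))
    else body
  }
  paste0(rec(d$tree, NULL), ";")
}

.cladeSets <- function(tree, labels) {
  n <- ape::Ntip(tree)
  ord <- match(tree$tip.label, labels)
  sets <- .descTips(tree)
  out <- lapply(sets[(n + 1L):(n + tree$Nnode)],
                function(s) sort(ord[s]))
  out[lengths(out) > 1L & lengths(out) < length(labels)]
}

#' Majority-rule consensus of rooted clusterings
#'
#' Counts, over the input rooted trees (e.g. per-list AHC dendrograms
#' converted to Newick), every proper clade and keeps those occurring in
#' strictly more than half of the inputs; a retained clade's supportive
#' probability is `100 * occurrences / n`. The retained clades are pairwise
#' compatible by the strict-majority rule and assemble into the unique
#' consensus tree.
#'
#' @param trees a list of rooted `ape::phylo` objects, a `multiPhylo`, or a
#'   character vector of Newick strings; identical label sets required.
#' @return A [ConsensusTree-class].
#' @examples
#' ct <- majorityConsensus(c("((A,B),C);", "((A,B),C);", "((A,C),B);"))
#' ct@support   # clade {A,B} at 66.7
#' @export
majorityConsensus <- function(trees) {
  if (is.character(trees))
    trees <- lapply(trees, function(s) ape::read.tree(text = s))
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  labels <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), labels))
      stop("all trees must share an identical label set")
  n <- length(trees)
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (cl in .cladeSets(tr, labels)) {
      k <- paste(cl, collapse = ",")
      prev <- if (exists(k, envir = counts, inherits = FALSE))
        get(k, envir = counts) else 0L
      assign(k, prev + 1L, envir = counts)
    }
  }
  keys <- ls(counts)
  occ <- vapply(keys, function(k) get(k, envir = counts), 0L)
  keep <- occ > n / 2
  clades <- lapply(keys[keep],
                   function(k) as.integer(strsplit(k, ",")[[1]]))
  support <- 100 * occ[keep] / n
  o <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[o]; support <- as.numeric(support[o])
  # strict majority guarantees compatibility; verify defensively
  if (length(clades) > 1L)
    for (i in seq_along(clades)[-1]) for (j in seq_len(i - 1L)) {
      int <- intersect(clades[[i]], clades[[j]])
      if (length(int) &&
          !(length(int) == length(clades[[i]]) ||
            length(int) == length(clades[[j]])))
        stop("internal error: incompatible majority clades")
    }
  fmt <- function(s) sprintf("%.10g", s)
  build <- function(set, cl, sup) {
    inside <- vapply(cl, function(x) all(x %in% set), logical(1))
    cl <- cl[inside]; sup <- sup[inside]
    tops <- which(!vapply(seq_along(cl), function(i)
      any(vapply(seq_along(cl), function(j)
        j != i && length(cl[[i]]) < length(cl[[j]]) &&
          all(cl[[i]] %in% cl[[j]]), logical(1))), logical(1)))
    parts <- character(0)
    used <- integer(0)
    for (i in tops) {
      sub <- vapply(cl, function(x)
        length(x) < length(cl[[i]]) && all(x %in% cl[[i]]), logical(1))
      parts <- c(parts, paste0(build(cl[[i]], cl[sub], sup[sub]), fmt(sup[i])))
      used <- c(used, cl[[i]])
    }
    free <- setdiff(set, used)
    paste0("(", paste(c(labels[free], parts), collapse = ","), ")")
  }
  nwk <- paste0(build(seq_along(labels), clades, support), ";")
  tree <- ape::read.tree(text = nwk)
  new("ConsensusTree",
      clades = lapply(clades, function(x) labels[x]),
      support = support, nTrees = as.integer(n), tree = tree)
}

#' @export
setMethod("show", "ConsensusTree", function(object) {
  cat("Majority-rule consensus of", object@nTrees, "trees;",
      length(object@clades), "clade(s) above 50%\n")
  for (i in seq_along(object@clades))
    cat(sprintf("  {%s}: %.1f%%\n",
                paste(object@clades[[i]], collapse = ","),
                object@support[i]))
  cat(" ", ape::write.tree(object@tree), "\n")
})

#' Rank-based sensitivity classification of the sub-regions
#'
#' Ranks the sub-regions by mean geodesic distance to the full-length tree
#' and splits the ranking into sensitivity classes at configurable rank cut
#' points. The default cuts (3, 2, 2) reproduce the reference three-class
#' design: Class I = the three closest regions (highest phylogenetic
#' sensitivity), Class II the next two, Class III the remaining two. Regions
#' tied across a cut point are flagged.
#'
#' @param summary output of [vtSummary()].
#' @param cuts integer class sizes in rank order; padded/truncated to the
#'   number of regions.
#' @return data.frame with columns `region`, `mean`, `rank`, `class`,
#'   `tie`.
#' @export
classifyRegions <- function(summary, cuts = c(3L, 2L, 2L)) {
  nR <- nrow(summary)
  cuts <- as.integer(cuts)
  if (sum(cuts) < nR) cuts[length(cuts)] <- cuts[length(cuts)] + nR - sum(cuts)
  cls <- rep(seq_along(cuts), cuts)[seq_len(nR)]
  roman <- as.character(utils::as.roman(cls))
  o <- order(summary$rank, summary$region)
  out <- data.frame(region = summary$region[o], mean = summary$mean[o],
                    rank = summary$rank[o], class = roman,
                    tie = summary$tie[o], row.names = NULL)
  # a tie spanning a class boundary makes the assignment ambiguous
  for (b in cumsum(cuts)[cumsum(cuts) < nR]) {
    if (out$mean[b] == out$mean[b + 1L])
      out$tie[c(b, b + 1L)] <- TRUE
  }
  out
}

#' Reshape long-format distances into per-list matrices
#'
#' @param df data.frame with columns `list_id`, `region_a`, `region_b`,
#'   `distance` (both orientations or one; symmetrised).
#' @return Named list (by list id) of symmetric matrices.
#' @export
distancesToMatrices <- function(df) {
  labs <- sort(unique(c(df$region_a, df$region_b)))
  lapply(split(df, df$list_id), function(d) {
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (r in seq_len(nrow(d))) {
      m[d$region_a[r], d$region_b[r]] <- d$distance[r]
      m[d$region_b[r], d$region_a[r]] <- d$distance[r]
    }
    m
  })
}
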