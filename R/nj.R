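#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with a deterministic tie-break: when several
#' pairs attain the minimal Q criterion (within 1e-12), the pair whose
#' sorted label pair is lexicographically smallest is joined (an internal
#' node inherits the lexicographically smallest leaf label beneath it).
#' Negative intermediate branch lengths are clamped to 0, so the result is
#' valid input for BHV tree-space comparison. The output is unrooted
#' (trifurcating root node).
#'
#' @param m symmetric non-negative numeric matrix with zero diagonal and
#'   dimnames (or a `dist`); at least 3 labels.
#' @return An unrooted `ape::phylo` tree.
#' @examples
#' m <- matrix(2, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' diag(m) <- 0
#' njTree(m)   # 3-leaf star, all pendant lengths 1
#' @export
njTree <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || is.null(rownames(m)))
    stop("m must be a labelled square matrix or dist")
  if (nrow(m) < 3L) stop("need at least 3 labels, got ", nrow(m))
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(m < 0)) stop("distance matrix has negative entries")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")

  labs <- rownames(m)           # active node tie-break labels
  frag <- labs                  # newick fragment per active node
  D <- unname(m)
  n <- nrow(D)
  bl <- function(x) sprintf("%.12g", max(x, 0))

  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 & upper.tri(Q), arr.ind = TRUE)
    key <- vapply(seq_len(nrow(cand)), function(k) {
      two <- sort(c(labs[cand[k, 1]], labs[cand[k, 2]]))
      paste(two, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    duk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    children <- order(c(labs[i], labs[j]))
    parts <- c(paste0(frag[i], ":", bl(bi)), paste0(frag[j], ":", bl(bj)))
    newFrag <- paste0("(", paste(parts[children], collapse = ","), ")")
    newLab <- min(labs[i], labs[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    labs <- c(labs[keep], newLab)
    frag <- c(frag[keep], newFrag)
    n <- n - 1L
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  parts <- paste0(frag, ":", c(bl(b1), bl(b2), bl(b3)))
  nwk <- paste0("(", paste(parts[order(labs)], collapse = ","), ");")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
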