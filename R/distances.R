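# Model-corrected pairwise distances over pairwise-complete columns.
# Only columns where both records hold an unambiguous base (A/C/G/T) enter a
# comparison; gaps and ambiguity codes are ignored pairwise.

.onehot <- function(x) {
  m <- t(vapply(as.character(x),
                function(s) strsplit(s, "", fixed = TRUE)[[1]],
                character(Biostrings::width(x)[1])))
  rownames(m) <- names(x)
  lapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(b) (m == b) * 1)
}

.jc69 <- function(p, maxDistance) {
  d <- ifelse(p >= 0.749, maxDistance, -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.xmin)))
  pmin(d, maxDistance)
}

.k80 <- function(P, Q, maxDistance) {
  a <- pmax(1 - 2 * P - Q, .Machine$double.xmin)
  b <- pmax(1 - 2 * Q, .Machine$double.xmin)
  ifelse(1 - 2 * P - Q <= 0 | 1 - 2 * Q <= 0, maxDistance,
         pmin(-0.5 * log(a) - 0.25 * log(b), maxDistance))
}

#' Model-corrected distance between two aligned records
#'
#' Computes the dissimilarity of two equal-width gapped sequences over their
#' pairwise-complete columns (both records in `{A,C,G,T}`). `"p"` is the raw
#' mismatch proportion; `"JC69"` applies the Jukes-Cantor correction
#' `-(3/4) ln(1 - 4p/3)`; `"K80"` the Kimura two-parameter correction from
#' transition and transversion proportions. Saturated pairs (JC69:
#' `p >= 0.749`; K80: a non-positive log argument) are capped at
#' `maxDistance` with a warning. Fewer than `minOverlap` comparable columns
#' is an error.
#'
#' @param a,b single records: character strings, or length-1
#'   [RegionAlignment-class]/`DNAStringSet` objects.
#' @param model `"JC69"` (default), `"K80"` or `"p"`.
#' @param minOverlap minimum number of pairwise-complete columns.
#' @param maxDistance saturation ceiling (substitutions/site).
#' @return A single non-negative dissimilarity.
#' @examples
#' pairwiseDistance("ACGTACGTAC", "ACGTACGTAC", minOverlap = 10)      # 0
#' @export
pairwiseDistance <- function(a, b, model = c("JC69", "K80", "p"),
                             minOverlap = 50L, maxDistance = 5) {
  model <- match.arg(model)
  asChars <- function(z) {
    if (is.character(z)) z <- regionAlignment(z, ids = "x")
    strsplit(toupper(as.character(z)[1]), "", fixed = TRUE)[[1]]
  }
  ca <- asChars(a); cb <- asChars(b)
  if (length(ca) != length(cb))
    stop("records must have equal column counts (", length(ca), " vs ",
         length(cb), ")")
  bases <- c("A", "C", "G", "T")
  ok <- ca %in% bases & cb %in% bases
  n <- sum(ok)
  if (n < minOverlap)
    stop("insufficient overlap: ", n, " pairwise-complete columns < ",
         minOverlap)
  mism <- sum(ca[ok] != cb[ok])
  p <- mism / n
  if (model == "p") return(p)
  if (model == "JC69") {
    if (p >= 0.749) {
      warning("saturated pair (p = ", signif(p, 3), "); distance capped at ",
              maxDistance)
      return(maxDistance)
    }
    return(.jc69(p, maxDistance))
  }
  ti <- sum((ca[ok] %in% c("A", "G") & cb[ok] %in% c("A", "G") |
             ca[ok] %in% c("C", "T") & cb[ok] %in% c("C", "T")) &
            ca[ok] != cb[ok])
  P <- ti / n
  Q <- (mism - ti) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    warning("saturated pair (P = ", signif(P, 3), ", Q = ", signif(Q, 3),
            "); distance capped at ", maxDistance)
    return(maxDistance)
  }
  .k80(P, Q, maxDistance)
}

#' All-pairs distance matrix of an alignment
#'
#' Computes every pairwise model-corrected distance (see
#' [pairwiseDistance()]) with one-hot matrix algebra, so the cost is a few
#' dense cross-products rather than a per-pair scan. Pairs with fewer than
#' `minOverlap` pairwise-complete columns are an error naming the offending
#' pair; saturated pairs are capped at `maxDistance` with one summary
#' warning.
#'
#' @param x a [RegionAlignment-class] with at least 3 records.
#' @inheritParams pairwiseDistance
#' @return Symmetric numeric matrix with zero diagonal, dimnames = record
#'   ids.
#' @export
distanceMatrix <- function(x, model = c("JC69", "K80", "p"),
                           minOverlap = 50L, maxDistance = 5) {
  model <- match.arg(model)
  if (length(x) < 3L)
    stop("need at least 3 records to build a distance matrix, got ",
         length(x))
  oh <- .onehot(x)
  U <- oh$A + oh$C + oh$G + oh$T        # unambiguous indicator
  nn <- tcrossprod(U)                   # pairwise-complete columns
  same <- tcrossprod(oh$A) + tcrossprod(oh$C) +
          tcrossprod(oh$G) + tcrossprod(oh$T)
  mism <- nn - same
  diag(nn) <- Biostrings::width(x)[1]   # avoid 0/0 on the diagonal
  low <- which(nn < minOverlap & upper.tri(nn), arr.ind = TRUE)
  if (nrow(low))
    stop("insufficient overlap (", nn[low[1, , drop = FALSE]],
         " columns) for pair ", names(x)[low[1, 1]], " / ",
         names(x)[low[1, 2]])
  p <- mism / nn
  if (model == "p") {
    d <- p
  } else if (model == "JC69") {
    nSat <- sum(p >= 0.749 & upper.tri(p))
    if (nSat) warning(nSat, " saturated pair(s) capped at ", maxDistance)
    d <- .jc69(p, maxDistance)
  } else {
    ti <- tcrossprod(oh$A, oh$G) + tcrossprod(oh$G, oh$A) +
          tcrossprod(oh$C, oh$T) + tcrossprod(oh$T, oh$C)
    P <- ti / nn
    Q <- (mism - ti) / nn
    nSat <- sum((1 - 2 * P - Q <= 0 | 1 - 2 * Q <= 0) & upper.tri(P))
    if (nSat) warning(nSat, " saturated pair(s) capped at ", maxDistance)
    d <- .k80(P, Q, maxDistance)
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2                   # enforce exact symmetry
  dimnames(d) <- list(names(x), names(x))
  d
}
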