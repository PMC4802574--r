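# Fixtures built in code; all randomness is seeded by the calling test.

# random unrooted tree with exponential branch lengths
randTree <- function(n, labels = paste0("L", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = labels)
  tr$edge.length <- stats::rexp(nrow(tr$edge))
  ape::unroot(tr)
}

randTreePair <- function(n) {
  labels <- paste0("L", seq_len(n))
  list(randTree(n, labels), randTree(n, labels))
}

# synthetic full-width record over the built-in coordinate map
randFullRecord <- function(width = 14371L) {
  paste(sample(c("A", "C", "G", "T", "-"), width, replace = TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
}

# alignment with taxonomy for sampling tests: nPhyla ordinary phyla with
# `classes` classes x `perClass` records, plus a Proteobacteria group with
# nSub subphyla (3 classes x perClass each)
taxAlignment <- function(nPhyla, nSub = 0L, classes = 3L, perClass = 1L,
                         width = 60L, extra = NULL) {
  ids <- character(0); tax <- character(0)
  for (p in seq_len(nPhyla)) for (cl in seq_len(classes))
    for (s in seq_len(perClass)) {
      ids <- c(ids, sprintf("P%02dC%02dS%d", p, cl, s))
      tax <- c(tax, sprintf("Bacteria;Phylum%02d;Class%02d", p, cl))
    }
  if (nSub > 0) {
    subs <- paste0(c("Alpha", "Beta", "Gamma", "Delta", "Epsilon")[seq_len(nSub)],
                   "proteobacteria")
    for (sp in seq_len(nSub)) for (cl in seq_len(classes))
      for (s in seq_len(perClass)) {
        ids <- c(ids, sprintf("PR%02dC%02dS%d", sp, cl, s))
        tax <- c(tax, sprintf("Bacteria;Proteobacteria;%s;Class%02d",
                              subs[sp], cl))
      }
  }
  seqs <- vapply(seq_along(ids), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), "")
  if (!is.null(extra)) {
    ids <- c(ids, names(extra))
    tax <- c(tax, unname(extra))
    seqs <- c(seqs, vapply(seq_along(extra), function(i)
      paste(rep("A", width), collapse = ""), ""))
  }
  regionAlignment(seqs, ids = ids, taxonomy = tax)
}
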