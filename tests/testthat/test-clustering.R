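regionMatrix <- function(vals, labs = c(paste0("V", 2:8), "VT")) {
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  m[upper.tri(m)] <- vals
  m + t(m)
}

# sorted canonical clade strings of a rooted tree (root clade excluded)
cladeKeys <- function(tr) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(i) paste(sort(labs[i]), collapse = "|"), "")
  sort(keys[lengths(pp) < length(labs)])
}

test_that("VT summary ranks regions by mean distance", {
  labs <- c(paste0("V", 2:8), "VT")
  set.seed(26)
  mats <- lapply(1:5, function(i) {
    m <- regionMatrix(stats::runif(28, 0.5, 1))
    m["V4", "VT"] <- m["VT", "V4"] <- 0.1 + 0.01 * i   # V4 closest by design
    m
  })
  s <- vtSummary(mats)
  expect_equal(s$region[s$rank == 1], "V4")
  expect_equal(nrow(s), 7L)
  expect_equal(attr(s, "nLists"), 5L)
  expect_true(all(s$sd >= 0) && all(s$sdEstimated))
})

test_that("single-list summaries report flagged zero SDs, ties are flagged", {
  m <- regionMatrix(rep(0.3, 28))
  s1 <- vtSummary(list(m))
  expect_true(all(s1$sd == 0) && !any(s1$sdEstimated))
  expect_equal(s1$mean, rep(0.3, 7))
  expect_true(all(s1$tie))
  expect_true(all(s1$rank == 1L))
  expect_error(vtSummary(list(m[1:5, 1:5])), "missing")
})

test_that("average-linkage merges follow the recurrence", {
  m <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- ahcCluster(m, "average")
  expect_equal(d$merges$height, c(1, 4.5))
  expect_equal(d$merges$cluster1, c("A", "A"))
  expect_equal(d$merges$cluster2, c("B", "C"))
  expect_equal(dendrogramToNewick(d), "((A,B),C);")
  expect_equal(ahcCluster(m, "complete")$merges$height, c(1, 5))
  expect_equal(ahcCluster(m, "single")$merges$height, c(1, 4))
  two <- m[1:2, 1:2]
  expect_equal(ahcCluster(two)$merges$height, 1)
  expect_error(ahcCluster(m[1, 1, drop = FALSE]), "at least 2")
})

test_that("tied dissimilarities merge in deterministic label order", {
  labs <- c("V2", "V3", "V4", "V5")
  m <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(m) <- 0
  d <- ahcCluster(m)
  expect_equal(d$merges$cluster1, c("V2", "V2", "V2"))
  expect_equal(d$merges$cluster2, c("V3", "V4", "V5"))
  # identical input twice -> identical merge sequence
  expect_identical(ahcCluster(m), ahcCluster(m))
})

test_that("AHC agrees with hclust on tie-free matrices", {
  set.seed(28)
  for (link in c("average", "complete", "single")) {
    for (i in 1:5) {
      n <- sample(5:8, 1)
      labs <- paste0("R", seq_len(n))
      m <- as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
      dimnames(m) <- list(labs, labs)
      mine <- ahcCluster(m, link)
      ref <- stats::hclust(stats::as.dist(m), method = link)
      expect_equal(sort(mine$merges$height), sort(ref$height),
                   tolerance = 1e-12)
      # same topology: compare as trees
      t1 <- ape::read.tree(text = dendrogramToNewick(mine))
      t2 <- ape::as.phylo(ref)
      expect_identical(cladeKeys(t1), cladeKeys(t2))
    }
  }
})

test_that("dendrogram Newick with heights reconstructs merge heights", {
  m <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- ahcCluster(m)
  tr <- ape::read.tree(text = dendrogramToNewick(d, withHeights = TRUE))
  depths <- ape::node.depth.edgelength(tr)
  # all leaves equidistant from the root at the last merge height
  expect_equal(unname(depths[seq_len(ape::Ntip(tr))]), rep(4.5, 3))
})

test_that("majority consensus counts clades with strict majority", {
  ct <- majorityConsensus(c("((A,B),C);", "((A,B),C);", "((A,C),B);"))
  expect_equal(length(ct@clades), 1L)
  expect_equal(ct@clades[[1]], c("A", "B"))
  expect_equal(ct@support, 100 * 2 / 3, tolerance = 1e-9)
  all3 <- majorityConsensus(rep("((A,(B,D)),C);", 3))
  expect_true(all(all3@support == 100))
  expect_equal(length(all3@clades), 2L)
  # exactly half is not a majority
  half <- majorityConsensus(c("((A,B),C,D);", "((A,C),B,D);"))
  expect_length(half@clades, 0L)
  expect_error(majorityConsensus(c("((A,B),C);", "((A,B),D);")), "label set")
})

test_that("supports are multiples of 100/n and clades nest", {
  set.seed(29)
  labs <- paste0("V", 2:8)
  nwk <- vapply(1:9, function(i) {
    m <- as.matrix(stats::dist(matrix(stats::rnorm(21), 7)))
    dimnames(m) <- list(labs, labs)
    dendrogramToNewick(ahcCluster(m))
  }, "")
  ct <- majorityConsensus(nwk)
  expect_true(all(ct@support > 50 & ct@support <= 100))
  mult <- ct@support / (100 / 9)
  expect_equal(mult, round(mult), tolerance = 1e-9)
  # consensus tree is a valid phylo containing exactly those clades
  expect_s3_class(ct@tree, "phylo")
  expect_equal(ape::Ntip(ct@tree), 7L)
  # cross-check topology against the reference consensus implementation
  ref <- ape::consensus(lapply(nwk, function(s) ape::read.tree(text = s)),
                        p = 0.5, rooted = TRUE)
  expect_identical(cladeKeys(ct@tree), cladeKeys(ref))
})

test_that("rank classification reproduces the three-class design", {
  labs <- c(paste0("V", 2:8), "VT")
  means <- c(V4 = 1, V5 = 2, V6 = 3, V3 = 4, V7 = 5, V2 = 6, V8 = 7)
  vals <- regionMatrix(rep(1, 28))
  for (r in names(means)) vals[r, "VT"] <- vals["VT", r] <- means[r]
  s <- vtSummary(list(vals, vals))
  cls <- classifyRegions(s)
  expect_equal(cls$region[cls$class == "I"], c("V4", "V5", "V6"))
  expect_equal(cls$region[cls$class == "II"], c("V3", "V7"))
  expect_equal(cls$region[cls$class == "III"], c("V2", "V8"))
  expect_false(any(cls$tie))
  # reversed ordering still yields the three smallest means in Class I
  for (r in names(means)) vals[r, "VT"] <- vals["VT", r] <- 8 - means[r]
  cls2 <- classifyRegions(vtSummary(list(vals)))
  expect_equal(sort(cls2$region[cls2$class == "I"]), c("V2", "V7", "V8"))
  # all-equal means: one tie group
  cls3 <- classifyRegions(vtSummary(list(regionMatrix(rep(2, 28)))))
  expect_true(all(cls3$tie))
})

test_that("identical matrices across lists give degenerate pipeline outputs", {
  set.seed(30)
  m <- regionMatrix(stats::runif(28, 0.2, 1))
  mats <- replicate(9, m, simplify = FALSE)
  s <- vtSummary(mats)
  expect_true(all(s$sd == 0))
  nwk <- vapply(mats, function(x) dendrogramToNewick(ahcCluster(x)), "")
  ct <- majorityConsensus(nwk)
  expect_true(all(ct@support == 100))
  expect_equal(length(ct@clades), 6L)   # fully resolved rooted topology
})
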