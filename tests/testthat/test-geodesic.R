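quartet <- function() {
  list(ingestNewick(text = "((A:0.1,B:0.1):0.3,C:0.1,D:0.1);"),
       ingestNewick(text = "((A:0.1,C:0.1):0.4,B:0.1,D:0.1);"))
}

test_that("worked quartet example is exact", {
  q <- quartet()
  res <- gtpDistance(q[[1]], q[[2]])
  expect_equal(res@distance, 0.7)
  expect_equal(res@commonPart, 0)
  expect_equal(res@leafPart, 0)
  expect_length(res@pathSpace, 1L)
  expect_equal(conePathLength(q[[1]], q[[2]]), 0.7)
  expect_equal(bruteForceDistance(q[[1]], q[[2]]), 0.7)
})

test_that("identity and same-orthant cases reduce to Euclidean geometry", {
  t1 <- ingestNewick(text = "((A:0.1,B:0.1):0.5,C:0.1,D:0.1);")
  expect_equal(bhvDistance(t1, t1), 0)
  t2 <- ingestNewick(text = "((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
  expect_equal(bhvDistance(t1, t2), 0.4)
  # general same-topology closed form: Euclidean norm of all differences
  set.seed(19)
  for (i in 1:10) {
    tr <- randTree(7)
    tr2 <- tr
    tr2$edge.length <- tr$edge.length + stats::runif(length(tr$edge.length),
                                                     -0.2, 0.2)
    tr2$edge.length[tr2$edge.length < 0.01] <- 0.01
    expect_equal(bhvDistance(tr, tr2),
                 sqrt(sum((tr$edge.length - tr2$edge.length)^2)),
                 tolerance = 1e-10)
  }
})

test_that("splits unique to one tree but compatible with the other shrink in place", {
  # t2 is the star: its absence of internal edges makes t1's split 'free'
  t1 <- ingestNewick(text = "((A:0.1,B:0.1):0.3,C:0.1,D:0.1);")
  star <- ingestNewick(text = "(A:0.1,B:0.1,C:0.1,D:0.1);")
  res <- gtpDistance(t1, star)
  expect_equal(res@distance, 0.3)
  expect_equal(res@commonPart, 0.09)
  expect_length(res@pathSpace, 0L)
})

test_that("GTP equals the brute-force oracle on random small pairs", {
  set.seed(20)
  worst <- 0
  for (i in 1:250) {
    pr <- randTreePair(sample(5:7, 1))
    worst <- max(worst, abs(bhvDistance(pr[[1]], pr[[2]]) -
                            bruteForceDistance(pr[[1]], pr[[2]])))
  }
  expect_lt(worst, 1e-10)
})

test_that("oracle agrees under shared splits and polytomies", {
  set.seed(27)
  for (i in 1:60) {
    # collapse random internal edges to force common splits / polytomies
    base <- randTree(7)
    t1 <- base; t2 <- randTree(7)
    drop1 <- stats::runif(length(t1$edge.length)) < 0.3
    t1$edge.length[drop1 & t1$edge[, 2] > ape::Ntip(t1)] <- 0
    # t2 shares part of t1's topology
    if (i %% 2 == 0) { t2 <- base; t2$edge.length <- t2$edge.length +
                         stats::runif(length(t2$edge.length), 0, 0.5)
                       t2$edge.length[sample(length(t2$edge.length), 2)] <- 0 }
    expect_equal(bhvDistance(t1, t2), bruteForceDistance(t1, t2),
                 tolerance = 1e-10)
  }
})

test_that("metric axioms hold on sampled triples", {
  set.seed(22)
  for (i in 1:120) {
    labels <- paste0("L", 1:6)
    t1 <- randTree(6, labels); t2 <- randTree(6, labels)
    t3 <- randTree(6, labels)
    d12 <- bhvDistance(t1, t2); d21 <- bhvDistance(t2, t1)
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_equal(bhvDistance(t1, t1), 0)
    expect_lte(bhvDistance(t1, t3), d12 + bhvDistance(t2, t3) + 1e-9)
  }
})

test_that("lower bound and cone length sandwich every distance", {
  set.seed(23)
  for (i in 1:100) {
    pr <- randTreePair(sample(5:8, 1))
    res <- gtpDistance(pr[[1]], pr[[2]])
    expect_lte(res@lowerBound, res@distance + 1e-9)
    expect_lte(res@distance, res@coneLength + 1e-9)
    expect_equal(res@coneLength, conePathLength(pr[[1]], pr[[2]]))
    # decomposition identity
    ps <- sum(vapply(res@pathSpace, function(p) (p$normA + p$normB)^2,
                     numeric(1)))
    expect_equal(res@distance^2, res@commonPart + res@leafPart + ps,
                 tolerance = 1e-9)
    # path-space ratios are non-decreasing
    if (length(res@pathSpace) > 1L) {
      rat <- vapply(res@pathSpace, function(p) p$normA / p$normB, numeric(1))
      expect_true(all(diff(rat) >= -1e-9))
    }
  }
})

test_that("distance scales linearly with branch lengths", {
  set.seed(24)
  pr <- randTreePair(7)
  d <- bhvDistance(pr[[1]], pr[[2]])
  for (c in c(0.1, 2, 13)) {
    s1 <- pr[[1]]; s2 <- pr[[2]]
    s1$edge.length <- s1$edge.length * c
    s2$edge.length <- s2$edge.length * c
    expect_equal(bhvDistance(s1, s2), c * d, tolerance = 1e-12)
  }
})

test_that("internal-only mode drops the pendant contribution", {
  q <- quartet()
  expect_equal(bhvDistance(q[[1]], q[[2]], internalOnly = TRUE), 0.7)
  t2 <- q[[2]]
  t2$edge.length[t2$edge[, 2] <= 4] <- 0.5    # change pendants only
  expect_equal(bhvDistance(q[[1]], t2, internalOnly = TRUE), 0.7)
  expect_gt(bhvDistance(q[[1]], t2), 0.7)
})

test_that("mismatched leaf sets and oversized inputs are refused", {
  q <- quartet()
  expect_error(gtpDistance(q[[1]], randTree(5)), "leaf")
  set.seed(25)
  pr <- randTreePair(12)
  expect_error(bruteForceDistance(pr[[1]], pr[[2]], maxUniqueSplits = 5),
               "maxUniqueSplits")
})
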