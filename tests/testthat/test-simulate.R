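smallSpec <- function(...) {
  simulationSpec(nPhyla = 4, nSubphyla = 2, nClassesPerPhylum = 3,
                 nClassesPerSubphylum = 3, seqsPerClass = 1,
                 regionTable = scaledRegionTable(0.05), seed = 41, ...)
}

test_that("the true tree carries clade-coherent taxonomy", {
  spec <- smallSpec()
  set.seed(spec@seed)
  truth <- sampleTrueTree(spec)
  expect_equal(ape::Ntip(truth$tree), (4 + 2) * 3)
  expect_setequal(names(truth$taxonomy), truth$tree$tip.label)
  paths <- strsplit(truth$taxonomy, ";")
  phyla <- vapply(paths, `[`, "", 2)
  for (ph in unique(phyla)) {
    tips <- names(truth$taxonomy)[phyla == ph]
    expect_true(ape::is.monophyletic(truth$tree, tips))
  }
  # the multi-subphylum group nests subphylum clades
  sub <- vapply(paths, `[`, "", 3)
  for (sp in unique(sub[phyla == "Proteobacteria"]))
    expect_true(ape::is.monophyletic(truth$tree,
                                     names(truth$taxonomy)[sub == sp &
                                                           phyla == "Proteobacteria"]))
  set.seed(spec@seed)
  truth2 <- sampleTrueTree(spec)
  expect_identical(ape::write.tree(truth$tree), ape::write.tree(truth2$tree))
})

test_that("a zero-rate region is identical across all records", {
  rt <- scaledRegionTable(0.05)
  rate <- stats::setNames(rep(1, 9), paste0("V", 1:9))
  rate["V5"] <- 0
  spec <- simulationSpec(nPhyla = 3, nSubphyla = 0, seqsPerClass = 1,
                         regionTable = rt, perRegionRate = rate,
                         organelleFraction = 0, shortFraction = 0,
                         seed = 43)
  set.seed(spec@seed)
  truth <- sampleTrueTree(spec)
  aln <- simulateAlignment(truth, spec)
  v5 <- as.character(extractRegion(aln, "V5", rt))
  expect_equal(length(unique(v5)), 1L)
  v4 <- as.character(extractRegion(aln, "V4", rt))
  expect_gt(length(unique(v4)), 1L)
})

test_that("equal rates without anchors give homogeneous regional divergence", {
  rt <- scaledRegionTable(0.25)
  spec <- simulationSpec(nPhyla = 2, nSubphyla = 0, seqsPerClass = 1,
                         regionTable = rt, conservedAnchorFraction = 0,
                         gammaShape = 100, pInvariant = 0,
                         organelleFraction = 0, shortFraction = 0,
                         seed = 44)
  set.seed(spec@seed)
  truth <- sampleTrueTree(spec)
  aln <- simulateAlignment(truth, spec)
  a <- strsplit(as.character(aln[[1]]), "")[[1]]
  b <- strsplit(as.character(aln[[4]]), "")[[1]]
  reg <- regionDefinitions(rt)
  mism <- width <- numeric(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    cols <- reg$alnStart[i]:reg$alnEnd[i]
    mism[i] <- sum(a[cols] != b[cols])
    width[i] <- length(cols)
  }
  expect_gt(stats::chisq.test(cbind(mism, width - mism))$p.value, 1e-4)
})

test_that("contaminant records appear at the configured rates and filter out", {
  spec <- simulationSpec(nPhyla = 5, nSubphyla = 0, seqsPerClass = 2,
                         regionTable = scaledRegionTable(0.05),
                         organelleFraction = 0.1, shortFraction = 0.1,
                         seed = 45)
  set.seed(spec@seed)
  truth <- sampleTrueTree(spec)
  aln <- simulateAlignment(truth, spec)
  n <- ape::Ntip(truth$tree)
  expect_equal(length(aln), n + 2 * round(0.1 * n))
  orgIds <- grep("^ORG", names(aln), value = TRUE)
  expect_length(orgIds, round(0.1 * n))
  expect_true(all(grepl("Chloroplast|Mitochondria",
                        taxonomyStrings(aln)[match(orgIds, names(aln))])))
  cfg <- samplingConfig(minUngappedLength = benchmarkLengthThreshold(spec))
  kept <- suppressMessages(filterDataset(aln, cfg))
  expect_false(any(grepl("^ORG|^SHORT", names(kept))))
  expect_equal(length(kept), n)
})

test_that("benchmarks are byte-identical per seed and feed the pipeline", {
  spec <- smallSpec()
  d1 <- file.path(tempdir(), "bmA"); d2 <- file.path(tempdir(), "bmB")
  makeBenchmark(spec, d1)
  makeBenchmark(spec, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  aln <- readAlignedFasta(file.path(d1, "alignment.fasta"))
  expect_equal(length(aln), 18 + 2 * round(0.05 * 18))
  truth <- ingestNewick(file.path(d1, "true_tree.nwk"))
  expect_setequal(truth$tip.label,
                  grep("^ORG|^SHORT", names(aln), invert = TRUE,
                       value = TRUE))
})

test_that("a design-sized dataset yields 108-member lists over 36 strata", {
  spec <- simulationSpec(regionTable = scaledRegionTable(0.02), seed = 46)
  set.seed(spec@seed)
  truth <- sampleTrueTree(spec)
  expect_equal(ape::Ntip(truth$tree), 216L)
  aln <- regionAlignment(
    stats::setNames(rep(strrep("A", 60), 216), truth$tree$tip.label),
    taxonomy = truth$taxonomy)
  cfg <- samplingConfig(nLists = 2, minUngappedLength = 10, seed = 5)
  st <- eligibleStrata(aln, cfg)
  expect_length(st, 36L)
  lists <- generateLists(aln, cfg)
  expect_true(all(vapply(lists, function(l) length(l$members), 0L) == 108L))
})
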