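test_that("built-in coordinate map matches the reference breakpoints", {
  tab <- builtinRegionTable()
  v4 <- regionDefinition(tab, "V4")
  expect_equal(unlist(v4[c("alnStart", "alnEnd", "refStart", "refEnd")]),
               c(alnStart = 4070L, alnEnd = 7044L,
                 refStart = 488L, refEnd = 746L))
  vt <- totalDefinition(tab)
  expect_equal(unlist(vt[c("alnStart", "alnEnd", "refStart", "refEnd")]),
               c(alnStart = 8L, alnEnd = 14371L,
                 refStart = 8L, refEnd = 1468L))
  expect_equal(regionNames(tab), paste0("V", 1:9))
})

test_that("all nine junctions are contiguous in both coordinate systems", {
  reg <- regionDefinitions(builtinRegionTable())
  n <- nrow(reg)
  expect_equal(reg$alnStart[-1], reg$alnEnd[-n] + 1L)
  expect_equal(reg$refStart[-1], reg$refEnd[-n] + 1L)
  # e.g. the V1/V2 junction
  expect_identical(c(reg$alnEnd[1], reg$alnStart[2]), c(789L, 790L))
})

test_that("RegionTable validity rejects broken maps", {
  tab <- builtinRegionTable()
  reg <- regionDefinitions(tab)
  bad <- reg; bad$alnStart[3] <- bad$alnStart[3] + 1L
  expect_error(regionTable(bad, totalDefinition(tab)), "contiguous")
  badTot <- totalDefinition(tab); badTot$alnEnd <- 99L
  expect_error(regionTable(reg, badTot), "span")
})

test_that("extraction slices the stated columns and preserves metadata", {
  set.seed(7)
  aln <- regionAlignment(c(S1 = randFullRecord(), S2 = randFullRecord()),
                         taxonomy = c("Bacteria;X", "Bacteria;Y"))
  v4 <- extractRegion(aln, "V4")
  expect_s4_class(v4, "RegionAlignment")
  expect_equal(unique(Biostrings::width(v4)), 7044L - 4070L + 1L)
  expect_equal(as.character(v4[[1]]),
               substr(as.character(aln[[1]]), 4070L, 7044L))
  expect_equal(names(v4), names(aln))
  expect_equal(taxonomyStrings(v4), taxonomyStrings(aln))
  vt <- extractRegion(aln, "VT")
  expect_equal(as.character(vt[[2]]),
               substr(as.character(aln[[2]]), 8L, 14371L))
})

test_that("records shorter than the region end are an error naming the id", {
  short <- regionAlignment(c(tiny1 = "ACGT"))
  expect_error(extractRegion(short, "V1"), "tiny1")
})

test_that("concatenated V1..V9 slices reproduce the VT slice exactly", {
  set.seed(11)
  tab <- builtinRegionTable()
  aln <- regionAlignment(
    stats::setNames(replicate(3, randFullRecord()), paste0("R", 1:3)))
  catted <- vapply(seq_along(aln), function(i)
    paste(vapply(regionNames(tab), function(nm)
      as.character(extractRegion(aln, nm, tab)[[i]]), ""), collapse = ""), "")
  vt <- as.character(extractRegion(aln, "VT", tab))
  expect_equal(unname(catted), unname(vt))
})

test_that("re-extracting the total from a rebased slice is the identity", {
  set.seed(3)
  aln <- regionAlignment(c(S = randFullRecord()))
  vt <- extractRegion(aln, "VT")
  w <- Biostrings::width(vt)[1]
  rebased <- regionTable(
    data.frame(name = "V1", alnStart = 1L, alnEnd = w,
               refStart = 1L, refEnd = w),
    data.frame(name = "VT", alnStart = 1L, alnEnd = w,
               refStart = 1L, refEnd = w))
  expect_equal(as.character(extractRegion(vt, "VT", rebased)),
               as.character(vt))
})

test_that("splitAlignment returns one collection per region, orders kept", {
  set.seed(5)
  aln <- regionAlignment(
    stats::setNames(replicate(4, randFullRecord()), paste0("R", 4:1)))
  parts <- splitAlignment(aln)
  expect_named(parts, c(paste0("V", 2:8), "VT"))
  expect_true(all(vapply(parts, length, 0L) == 4L))
  expect_true(all(vapply(parts, function(p)
    identical(names(p), names(aln)), logical(1))))
  empty <- splitAlignment(regionAlignment(character(0), ids = character(0)))
  expect_true(all(vapply(empty, length, 0L) == 0L))
  one <- splitAlignment(aln[1], include = "V4")
  expect_named(one, "V4")
  expect_error(splitAlignment(aln, include = c("V4", "V10")), "V10")
})

test_that("merged blocks equal the single contiguous slice", {
  set.seed(9)
  tab <- builtinRegionTable()
  aln <- regionAlignment(c(S1 = randFullRecord(), S2 = randFullRecord()))
  m <- mergeRegions(aln, tab, c("V4", "V5", "V6"))
  expect_equal(as.character(m[[1]]),
               substr(as.character(aln[[1]]), 4070L, 10454L))
  def <- mergedRegionDefinition(tab, c("V4", "V5", "V6"))
  expect_equal(c(def$alnStart, def$alnEnd), c(4070L, 10454L))
  expect_equal(as.character(mergeRegions(aln, tab, "V5")),
               as.character(extractRegion(aln, "V5", tab)))
  expect_error(mergeRegions(aln, tab, c("V2", "V4")), "consecutive")
})

test_that("occupancy counts non-gap columns", {
  expect_equal(unname(regionOccupancy(regionAlignment(c(a = "AC-G")))), 0.75)
  expect_equal(unname(regionOccupancy(regionAlignment(c(a = "----")))), 0)
  expect_length(regionOccupancy(regionAlignment(character(0),
                                                ids = character(0))), 0)
  # half the records all-gap halves the mean occupancy
  set.seed(2)
  full <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), "")
  gap <- rep(strrep("-", 40), 10)
  occ <- regionOccupancy(regionAlignment(c(full, gap),
                                         ids = paste0("r", 1:20)))
  expect_equal(mean(occ), 0.5 * mean(occ[1:10]))
})

test_that("scaled tables stay contiguous and TSV round-trips", {
  for (sc in c(0.02, 0.1, 0.25, 1)) {
    tab <- scaledRegionTable(sc)
    reg <- regionDefinitions(tab)
    expect_equal(reg$alnStart[-1], reg$alnEnd[-nrow(reg)] + 1L)
    expect_true(all(reg$alnEnd >= reg$alnStart))
  }
  expect_identical(regionDefinitions(scaledRegionTable(1)),
                   regionDefinitions(builtinRegionTable()))
  tab <- scaledRegionTable(0.1)
  tsv <- tempfile(fileext = ".tsv")
  df <- rbind(regionDefinitions(tab), totalDefinition(tab))
  names(df) <- c("name", "aln_start", "aln_end", "ref_start", "ref_end")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readRegionTable(tsv)
  expect_identical(regionDefinitions(back), regionDefinitions(tab))
  expect_identical(totalDefinition(back), totalDefinition(tab))
})

test_that("ingest normalises U/T, case and gap characters", {
  aln <- regionAlignment(c(x = "acgu.-N"))
  expect_equal(as.character(aln[[1]]), "ACGT.-N")
  expect_equal(unname(ungappedLength(aln)), 5L)
  fa <- tempfile(fileext = ".fasta")
  writeAlignedFasta(regionAlignment(c(A = "ACGT", B = "AC-T"),
                                    taxonomy = c("Bacteria;P1", NA)), fa)
  back <- readAlignedFasta(fa)
  expect_equal(names(back), c("A", "B"))
  expect_equal(as.character(back), c(A = "ACGT", B = "AC-T"))
  expect_equal(taxonomyStrings(back)[1], "Bacteria;P1")
})
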