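test_that("well-formed aligned FASTA round-trips with normalization", {
  path <- writeTempFasta(c(">wt human enzyme", "ACDEF",
                           ">s1 homolog", "acd.f",
                           ">s2", "AC-EF"))
  aln <- readFamilyAlignment(path, targetId = "wt")
  expect_s4_class(aln, "FamilyAlignment")
  expect_equal(numSequences(aln), 3L)
  expect_equal(alignmentWidth(aln), 5L)
  expect_equal(alignmentIds(aln), c("wt", "s1", "s2"))
  # lowercase uppercased, '.' mapped to the gap letter
  expect_equal(unname(alignmentSeqs(aln)[["s1"]]), "ACD-F")

  out <- tempfile(fileext = ".fasta")
  writeFamilyFasta(aln, out)
  back <- readFamilyAlignment(out, targetId = "wt")
  expect_equal(alignmentSeqs(back), alignmentSeqs(aln))
})

test_that("malformed FASTA inputs fail with informative errors", {
  ragged <- writeTempFasta(c(">wt", "ACDEFGHIKL", ">s1", "ACDEFGHIK"))
  expect_error(readFamilyAlignment(ragged, "wt"), "ragged.*s1")

  noTarget <- writeTempFasta(c(">s1", "ACD", ">s2", "ACD"))
  expect_error(readFamilyAlignment(noTarget, "wt"), "not found")

  withX <- writeTempFasta(c(">wt", "ACX", ">s1", "ACD"))
  expect_error(readFamilyAlignment(withX, "wt"), "unknown letter 'X'")
  aln <- readFamilyAlignment(withX, "wt", ambiguous = "gap")
  expect_equal(unname(targetSequence(aln)), "AC-")
})

test_that("gappiness scores follow the thresholded column-sum definition", {
  # no gaps anywhere -> all scores zero
  clean <- randomAlignment(6, 10, seed = 2)
  expect_equal(unname(gappinessScores(clean, w = 0.5)),
               rep(0, 6))

  # one column with 3/4 gaps: fraction 0.75 > w = 0.5 counts for gapped rows
  aln <- FamilyAlignment(c("wt", "a", "b", "c"),
                         c("AACD", "A-CD", "A-CD", "A-CD"), "wt")
  s <- gappinessScores(aln, w = 0.5)
  expect_equal(unname(s), c(0, 0.75, 0.75, 0.75))

  # strict inequality: at w = 0.75 the same column contributes nothing
  expect_equal(unname(gappinessScores(aln, w = 0.75)), rep(0, 4))
})

test_that("gappiness is permutation-equivariant and bounded by gap counts", {
  aln <- randomAlignment(12, 15, seed = 3, gapFrac = TRUE)
  s <- gappinessScores(aln, w = 0.2)
  perm <- withr::with_seed(9, sample(numSequences(aln)))
  alnP <- FamilyAlignment(alignmentIds(aln)[perm],
                          unname(alignmentSeqs(aln))[perm],
                          targetId = "wt")
  expect_equal(unname(gappinessScores(alnP, w = 0.2)), unname(s)[perm])
  nGaps <- vapply(strsplit(unname(alignmentSeqs(aln)), ""),
                  function(v) sum(v == "-"), integer(1))
  expect_true(all(s <= nGaps + 1e-12))
})

test_that("filtering removes gappy, short and keyword-less sequences in order", {
  # 12 columns at gap fraction 0.95 (19/20): score 12 * 0.95 = 11.4 > 10
  base <- strrep("A", 300)
  gappyRow <- paste0(strrep("-", 12), substr(base, 13, 300))
  rows <- c(base, rep(gappyRow, 19), substr(paste0(base, strrep("A", 40)), 1, 300))
  # make a 20-deep alignment: target + 19 rows gapped in the first 12 cols
  ids <- c("wt", sprintf("g%02d", 1:19))
  aln <- FamilyAlignment(ids, rows[1:20], "wt",
                         descriptions = c("wt Ornithine carbamoyltransferase",
                                          sprintf("g%02d Ornithine", 1:19)))
  s <- gappinessScores(aln, w = 0.9)
  expect_equal(unname(s[2]), 12 * 0.95)
  res <- filterAlignment(aln, gappinessParams())
  expect_equal(res$report@nRemovedGappy, 19L)
  expect_equal(res$report@nOutput, 1L)

  # short and keyword filters, tallied separately and in order
  aln2 <- FamilyAlignment(
    c("wt", "short", "nokey"),
    c(strrep("A", 300), paste0(strrep("-", 150), strrep("A", 150)),
      strrep("C", 300)),
    "wt",
    descriptions = c("wt Ornithine", "short Ornithine", "nokey other"))
  res2 <- filterAlignment(aln2, gappinessParams(minUngappedLength = 290,
                                                keyword = "Ornithine"))
  expect_equal(res2$report@nRemovedShort, 1L)
  expect_equal(res2$report@nRemovedKeyword, 1L)
  expect_equal(res2$report@removedIds$short, "short")
  expect_equal(res2$report@removedIds$keyword, "nokey")
  expect_equal(alignmentIds(res2$alignment), "wt")

  # nothing fires on identical full-length sequences with keyword disabled
  aln3 <- FamilyAlignment(c("wt", "a"), rep(strrep("A", 300), 2), "wt")
  res3 <- filterAlignment(aln3, gappinessParams(keyword = NULL))
  expect_equal(res3$report@nOutput, 2L)

  # idempotence
  again <- filterAlignment(res2$alignment,
                           gappinessParams(minUngappedLength = 290,
                                           keyword = "Ornithine"))
  expect_equal(alignmentSeqs(again$alignment),
               alignmentSeqs(res2$alignment))
})

test_that("the target is protected and report tallies are consistent", {
  aln <- FamilyAlignment(c("wt", "a"),
                         c(paste0(strrep("-", 100), strrep("A", 100)),
                           strrep("A", 200)), "wt")
  expect_error(filterAlignment(aln, gappinessParams(minUngappedLength = 150)),
               "target")
  rep <- filterAlignment(toyAlignment(),
                         gappinessParams(minUngappedLength = 2))$report
  expect_equal(rep@nInput, rep@nOutput + rep@nRemovedGappy +
                 rep@nRemovedShort + rep@nRemovedKeyword)
  expect_match(as.character(curationReportJSON(rep)), "n_input")
})

test_that("slicing drops exactly the target's gap columns and is idempotent", {
  aln <- FamilyAlignment(c("wt", "a"), c("-AC-G", "TACTG"), "wt")
  res <- sliceToTarget(aln)
  expect_equal(unname(targetSequence(res$alignment)), "ACG")
  expect_equal(res$report@slicedColumns, c(0L, 3L))   # 0-based
  expect_equal(unname(alignmentSeqs(res$alignment)[["a"]]), "ACG")
  expect_equal(alignmentWidth(res$alignment),
               nchar(gsub("-", "", targetSequence(aln))))

  # idempotence: re-slicing is a no-op
  res2 <- sliceToTarget(res$alignment)
  expect_equal(alignmentSeqs(res2$alignment),
               alignmentSeqs(res$alignment))
  expect_length(res2$report@slicedColumns, 0L)

  # gap-free target: output identical to input
  res3 <- sliceToTarget(toyAlignment())
  expect_equal(alignmentSeqs(res3$alignment),
               alignmentSeqs(toyAlignment()))
})
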