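test_that("consensus takes the modal non-gap letter with alphabet tie-break", {
  same <- FamilyAlignment(c("wt", "a", "b"), rep("ACDEF", 3), "wt")
  expect_equal(consensusSequence(same), "ACDEF")
  # plurality
  aln <- FamilyAlignment(c("wt", "a", "b"), c("A", "A", "C"), "wt")
  expect_equal(consensusSequence(aln), "A")
  # tie A vs C resolves to A (alphabet order)
  tie <- FamilyAlignment(c("wt", "a"), c("A", "C"), "wt")
  expect_equal(consensusSequence(tie), "A")
  # majority-gap column still elects the modal non-gap letter
  gappy <- FamilyAlignment(c("wt", "a", "b"), c("T-", "T-", "TC"), "wt")
  expect_equal(consensusSequence(gappy), "TC")
  # an all-gap column cannot be called
  allGap <- FamilyAlignment(c("wt", "a"), c("A-", "C-"), "wt")
  expect_error(consensusSequence(allGap), "entirely gap")
})

test_that("consensus agrees with a brute-force column-mode oracle", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      aln <- randomAlignment(sample(5:40, 1), sample(4:25, 1),
                             seed = sample(1e6, 1), gapFrac = TRUE)
      m <- do.call(rbind, strsplit(unname(alignmentSeqs(aln)), ""))
      oracle <- apply(m, 2, function(col) {
        col <- col[col != "-"]
        counts <- table(factor(col, levels = proteinAlphabet()[1:20]))
        names(counts)[which.max(counts)]   # first max = alphabet order
      })
      if (any(colSums(m != "-") == 0)) next
      expect_equal(consensusSequence(aln), paste(oracle, collapse = ""))
    }
  })
  # invariance to sequence order and whole-alignment duplication
  aln <- randomAlignment(15, 10, seed = 77)
  seqs <- unname(alignmentSeqs(aln))
  perm <- withr::with_seed(5, sample(15))
  alnP <- FamilyAlignment(sprintf("p%d", 1:15), seqs[perm], "p1")
  alnD <- FamilyAlignment(sprintf("d%d", 1:30), rep(seqs, 2), "d1")
  expect_equal(consensusSequence(alnP), consensusSequence(aln))
  expect_equal(consensusSequence(alnD), consensusSequence(aln))
})

test_that("consensus substitutions list exactly the differing columns", {
  expect_equal(nrow(consensusSubstitutions("ACD", "ACD")), 0L)
  subs <- consensusSubstitutions("ACD", "AVD")
  expect_equal(subs$name, "V2C")
  expect_equal(subs$position, 2L)

  # a family built to differ from the target at exactly 18 columns
  withr::with_seed(41, {
    tgt <- paste(sample(proteinAlphabet()[1:20], 100, TRUE), collapse = "")
    cons <- strsplit(tgt, "")[[1]]
    flip <- sort(sample(100, 18))
    cons[flip] <- vapply(cons[flip], function(l)
      sample(setdiff(proteinAlphabet()[1:20], l), 1), character(1))
    # majority of sequences carry the consensus letters
    aln <- FamilyAlignment(
      c("wt", "h1", "h2", "h3"),
      c(tgt, rep(paste(cons, collapse = ""), 3)), "wt")
    design <- consensusDesign(aln)
    expect_equal(nrow(design$substitutions), 18L)
    expect_equal(design$substitutions$position, flip)
    expect_equal(design$librarySize, 2^18)
  })
})

test_that("library enumeration covers 2^k combinations exactly once", {
  tgt <- "ACDEFGHIKL"
  subs <- consensusSubstitutions("MCDEFGHWKY", tgt)   # 3 substitutions
  expect_equal(nrow(subs), 3L)
  lib <- enumerateLibrary(tgt, subs, mode = "full")
  expect_length(lib, 8L)
  expect_false(any(duplicated(lib)))
  expect_equal(unname(lib[1]), tgt)   # the all-off member is the target
  # every member differs from the target only at substitution positions,
  # and only by the consensus letter
  for (s in lib) {
    diffs <- which(strsplit(s, "")[[1]] != strsplit(tgt, "")[[1]])
    expect_true(all(diffs %in% subs$position))
    for (d in diffs)
      expect_equal(substr(s, d, d), subs$to[match(d, subs$position)])
  }
  # zero substitutions: only the target
  none <- consensusSubstitutions(tgt, tgt)
  expect_equal(unname(enumerateLibrary(tgt, none, "full")), tgt)
})

test_that("library sampling draws distinct variants reproducibly", {
  withr::with_seed(51, {
    tgt <- paste(sample(proteinAlphabet()[1:20], 50, TRUE), collapse = "")
    cons <- strsplit(tgt, "")[[1]]
    flip <- sort(sample(50, 18))
    cons[flip] <- vapply(cons[flip], function(l)
      sample(setdiff(proteinAlphabet()[1:20], l), 1), character(1))
    subs <- consensusSubstitutions(paste(cons, collapse = ""), tgt)
  })
  picks <- enumerateLibrary(tgt, subs, mode = "sample", n = 91, seed = 6)
  expect_length(picks, 91L)
  expect_false(any(duplicated(picks)))
  expect_identical(picks,
                   enumerateLibrary(tgt, subs, mode = "sample", n = 91,
                                    seed = 6))
  expect_error(enumerateLibrary(tgt, subs[1:2, ], "sample", n = 5),
               "distinct")
})
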