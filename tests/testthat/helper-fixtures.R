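# Shared fixtures. Heavy objects (trained toy models) are built lazily and
# cached for the session so every test file can use them without retraining.

.cache <- new.env(parent = emptyenv())

# A small handmade alignment with known gap structure.
toyAlignment <- function() {
  FamilyAlignment(
    ids = c("wt", "a", "b", "c"),
    seqs = c("ACDEF", "ACDEF", "AC-EF", "GCDEF"),
    targetId = "wt")
}

# Random gap-free alignment over the full alphabet.
randomAlignment <- function(N, L, seed = 1, gapFrac = 0) {
  withr::with_seed(seed, {
    aa <- proteinAlphabet()
    letters <- if (gapFrac > 0) aa else aa[1:20]
    seqs <- replicate(N, paste(sample(letters, L, replace = TRUE),
                               collapse = ""))
    FamilyAlignment(ids = c("wt", sprintf("s%03d", seq_len(N - 1L))),
                    seqs = seqs, targetId = "wt")
  })
}

# A quickly trained toy VAE on a small synthetic family; cached per session.
tinyTrainedModel <- function() {
  if (!is.null(.cache$tiny)) return(.cache$tiny)
  cfg <- familyConfig(L = 32, N = 400, nCoupledPairs = 1, seed = 5)
  aln <- generateFamily(cfg)
  mcfg <- vaeConfig(32, latentDim = 8,
                    encoderFilters = c(12, 10, 8),
                    decoderFilters = c(8, 10, 12))
  model <- buildVAE(mcfg, seed = 1)
  model <- trainVAE(model, aln, splitTrainTest(aln, seed = 2),
                    trainingWeights(aln), epochs = 8, batchSize = 64,
                    seed = 3)
  .cache$tiny <- list(model = model, aln = aln, cfg = cfg)
  .cache$tiny
}

# The end-to-end study-condition model: synthetic family of 2000 sequences,
# width 64, one designed coupled pair, 20 epochs. Trained once; reused by
# the sampling and fidelity acceptance checks.
acceptanceModel <- function() {
  if (!is.null(.cache$acc)) return(.cache$acc)
  cfg <- familyConfig(L = 64, N = 2000, nCoupledPairs = 1, seed = 100)
  aln <- generateFamily(cfg)
  mcfg <- vaeConfig(64, latentDim = 16,
                    encoderFilters = c(16, 12, 8),
                    decoderFilters = c(8, 12, 16))
  model <- buildVAE(mcfg, seed = 1)
  model <- trainVAE(model, aln, splitTrainTest(aln, seed = 2),
                    trainingWeights(aln), epochs = 20, batchSize = 128,
                    seed = 3)
  .cache$acc <- list(model = model, aln = aln, cfg = cfg)
  .cache$acc
}

writeTempFasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
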