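#' One-hot encode an aligned sequence
#'
#' Each position becomes an indicator row over the fixed 21-letter alphabet
#' (20 amino acids then gap), so an `L`-column row maps to an `L x 21` binary
#' matrix with exactly one 1 per position.
#'
#' @param seq A single aligned row (character scalar).
#' @param alphabet Letter order; defaults to [proteinAlphabet()].
#' @return An `L x |alphabet|` binary matrix.
#' @export
#' @examples
#' oneHotEncode("A-")[, c("A", "-")]
oneHotEncode <- function(seq, alphabet = proteinAlphabet()) {
  letters <- strsplit(seq, "")[[1L]]
  idx <- match(letters, alphabet)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop(sprintf("letter '%s' at position %d is not in the alphabet",
                 letters[p], p))
  }
  m <- matrix(0L, nrow = length(idx), ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot or probability matrix back to a sequence by argmax
#'
#' @param mat An `L x |alphabet|` matrix (binary or probabilities).
#' @inheritParams oneHotEncode
#' @return Character scalar of length-`L`.
#' @export
oneHotDecode <- function(mat, alphabet = proteinAlphabet()) {
  stopifnot(ncol(mat) == length(alphabet))
  paste(alphabet[max.col(mat, ties.method = "first")], collapse = "")
}

# Internal: one-hot a set of rows into an (L, A, B) array.
oneHotBatchArray <- function(seqs, alphabet = proteinAlphabet()) {
  L <- nchar(seqs[1L])
  A <- length(alphabet)
  B <- length(seqs)
  idx <- match(unlist(strsplit(seqs, ""), use.names = FALSE), alphabet)
  if (anyNA(idx)) stop("letter outside alphabet in batch")
  x <- array(0, dim = c(L, A, B))
  pos <- rep(seq_len(L), times = B)
  b <- rep(seq_len(B), each = L)
  x[cbind(pos, idx, b)] <- 1
  x
}

#' Fraction of identical columns between two aligned rows
#'
#' Gap-gap columns count as matches and gap-letter columns as mismatches;
#' the denominator is the full alignment width.
#'
#' @param a,b Equal-length aligned rows.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' sequenceIdentity("AAAA", "AAAT")
sequenceIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop(sprintf("length mismatch: %d vs %d", nchar(a), nchar(b)))
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  mean(av == bv)
}

#' Hamming distance between two equal-length rows
#'
#' @inheritParams sequenceIdentity
#' @return Integer count of differing columns.
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop(sprintf("length mismatch: %d vs %d", nchar(a), nchar(b)))
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Similarity-based training weights
#'
#' Each sequence is weighted by its identity fraction to the reference
#' (target) raised to a power (default 2.25), which down-weights distant
#' homologs during batch sampling. Weights are not normalized; the batch
#' sampler normalizes internally.
#'
#' @param aln A [FamilyAlignment-class].
#' @param exponent Positive power applied to the identity fraction.
#' @param referenceId Reference sequence id; defaults to the alignment's
#'   target.
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
trainingWeights <- function(aln, exponent = 2.25, referenceId = targetId(aln)) {
  stopifnot(exponent > 0)
  ref <- aln@seqs[match(referenceId, aln@ids)]
  if (is.na(ref)) stop("reference id not present in the alignment")
  refv <- strsplit(ref, "")[[1L]]
  m <- alignmentCharMatrix(aln)
  ident <- rowMeans(m == matrix(refv, nrow(m), ncol(m), byrow = TRUE))
  stats::setNames(ident^exponent, aln@ids)
}

#' Seed-reproducible train/test split
#'
#' Splits ids into disjoint, exhaustive train and test sets. The target is
#' always forced into the training split (its encoding anchors variant
#' sampling).
#'
#' @param aln A [FamilyAlignment-class].
#' @param testFraction Fraction held out for testing (default 0.10).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
splitTrainTest <- function(aln, testFraction = 0.10, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1)
  n <- numSequences(aln)
  if (n < 10L) stop("need at least 10 sequences to split")
  nTest <- max(1L, round(n * testFraction))
  candidates <- setdiff(aln@ids, aln@targetId)
  testIds <- withSeed(seed, sample(candidates, nTest))
  list(train = setdiff(aln@ids, testIds), test = testIds)
}

#' Weighted-with-replacement batch index stream
#'
#' Draws `nBatches` batches of `batchSize` indices i.i.d. with probability
#' proportional to the weights, reproducibly for a given seed.
#'
#' @param ids Character or integer vector being sampled.
#' @param weights Nonnegative sampling weights, parallel to `ids`.
#' @param batchSize Draws per batch.
#' @param nBatches Number of batches.
#' @param seed Integer seed.
#' @return List of `nBatches` vectors of elements of `ids`.
#' @export
weightedBatches <- function(ids, weights, batchSize, nBatches, seed = 1L) {
  stopifnot(length(ids) == length(weights), batchSize >= 1, nBatches >= 1)
  if (any(weights < 0)) stop("negative weights")
  if (all(weights == 0)) stop("all-zero weights")
  withSeed(seed, {
    lapply(seq_len(nBatches), function(i) {
      ids[sample.int(length(ids), batchSize, replace = TRUE, prob = weights)]
    })
  })
}

#' Export weights and split assignment as a TSV-ready data frame
#'
#' @param aln A [FamilyAlignment-class].
#' @param weights Named weights from [trainingWeights()].
#' @param split List from [splitTrainTest()].
#' @return `data.frame` with columns id, weight, split.
#' @export
weightTable <- function(aln, weights, split) {
  data.frame(id = aln@ids,
             weight = unname(weights[aln@ids]),
             split = ifelse(aln@ids %in% split$test, "test", "train"),
             stringsAsFactors = FALSE)
}

# Internal: evaluate expr under a temporary RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
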