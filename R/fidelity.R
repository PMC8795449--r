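#' Per-column letter frequencies
#'
#' Plain empirical frequencies `n_j^a / N` with the gap counted as a 21st
#' letter and no pseudocounts or rare-event corrections.
#'
#' @param x A [FamilyAlignment-class] or character vector of equal-length
#'   rows.
#' @param alphabet Letter order.
#' @return `L x |alphabet|` matrix; rows sum to 1.
#' @export
columnFrequencies <- function(x, alphabet = proteinAlphabet()) {
  seqs <- if (is(x, "FamilyAlignment")) x@seqs else x
  L <- nchar(seqs[1L])
  idx <- match(unlist(strsplit(seqs, ""), use.names = FALSE), alphabet)
  if (anyNA(idx)) stop("letter outside alphabet")
  counts <- table(factor(rep(seq_len(L), times = length(seqs)),
                         levels = seq_len(L)),
                  factor(idx, levels = seq_along(alphabet)))
  freq <- unclass(counts) / length(seqs)
  dimnames(freq) <- list(NULL, alphabet)
  freq
}

#' Shannon entropy of a frequency vector (nats by default)
#'
#' `0 log 0` is taken as 0.
#'
#' @param p Frequency vector (sums to 1) or a frequency matrix (rowwise).
#' @param base Logarithm base; default `exp(1)` for nats, use 2 for bits.
#' @return Scalar entropy, or a vector for a matrix input.
#' @export
columnEntropy <- function(p, base = exp(1)) {
  ent <- function(v) {
    v <- v[v > 0]
    -sum(v * log(v)) / log(base)
  }
  if (is.matrix(p)) apply(p, 1L, ent) else ent(p)
}

#' Pairwise mutual information across alignment columns
#'
#' For columns j, k: `I[j,k] = sum_ab p(a,b) log(p(a,b) / (p(a) p(b)))` over
#' the empirical pair frequencies, with the gap as a 21st letter. Computed
#' via the equivalent entropy form `H_j + H_k - H_jk`, which is numerically
#' identical to the double sum (the package's tests verify the two forms
#' against each other). The diagonal holds the site entropies `H_j`.
#'
#' @inheritParams columnFrequencies
#' @param base Logarithm base (default nats).
#' @return Symmetric `L x L` matrix in the chosen units.
#' @export
mutualInformation <- function(x, alphabet = proteinAlphabet(),
                              base = exp(1)) {
  seqs <- if (is(x, "FamilyAlignment")) x@seqs else x
  N <- length(seqs)
  if (N < 1L) stop("empty alignment")
  idxMat <- t(vapply(strsplit(seqs, ""), match, integer(nchar(seqs[1L])),
                     table = alphabet))
  L <- ncol(idxMat)
  A <- length(alphabet)
  # one-hot indicator matrix (N x L*A): joint counts are a crossproduct
  ind <- matrix(0, N, L * A)
  ind[cbind(rep(seq_len(N), L),
            rep((seq_len(L) - 1L) * A, each = N) + as.vector(idxMat))] <- 1
  H <- columnEntropy(columnFrequencies(seqs, alphabet), base = exp(1))
  mi <- matrix(0, L, L)
  plogp <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  joint <- crossprod(ind) / N     # (L*A) x (L*A) blockwise joint frequencies
  for (j in seq_len(L - 1L)) {
    rows <- (j - 1L) * A + seq_len(A)
    for (k in (j + 1L):L) {
      cols <- (k - 1L) * A + seq_len(A)
      Hjk <- plogp(joint[rows, cols])
      mi[j, k] <- mi[k, j] <- H[j] + H[k] - Hjk
    }
  }
  diag(mi) <- H
  mi / log(base)
}

# Internal oracle-style double-sum MI for a single column pair.
pairwiseMIDirect <- function(colA, colB, alphabet = proteinAlphabet()) {
  N <- length(colA)
  tab <- table(factor(colA, levels = alphabet),
               factor(colB, levels = alphabet)) / N
  pa <- rowSums(tab)
  pb <- colSums(tab)
  s <- 0
  for (a in seq_along(alphabet)) for (b in seq_along(alphabet)) {
    p <- tab[a, b]
    if (p > 0) s <- s + p * log(p / (pa[a] * pb[b]))
  }
  unname(s)
}

squaredPearson <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Frequency and mutual-information agreement between data and samples
#'
#' Pools all `L x |A|` per-position letter frequencies and all
#' upper-triangle MI values and reports the squared Pearson correlation of
#' each scatter (training data vs model samples).
#'
#' @param train Training alignment ([FamilyAlignment-class] or character
#'   rows).
#' @param samples Model-sampled rows of the same width.
#' @param alphabet Letter order.
#' @return A [FidelityReport-class] with `freqR2` and `miR2` filled in;
#'   `details` carries the underlying matrices.
#' @export
fidelityR2 <- function(train, samples, alphabet = proteinAlphabet()) {
  fTrain <- columnFrequencies(train, alphabet)
  fSamp <- columnFrequencies(samples, alphabet)
  if (!all(dim(fTrain) == dim(fSamp)))
    stop("train and sample widths differ")
  miTrain <- mutualInformation(train, alphabet)
  miSamp <- mutualInformation(samples, alphabet)
  ut <- upper.tri(miTrain)
  new("FidelityReport",
      freqR2 = squaredPearson(as.vector(fTrain), as.vector(fSamp)),
      miR2 = squaredPearson(miTrain[ut], miSamp[ut]),
      details = list(freqTrain = fTrain, freqSamples = fSamp,
                     miTrain = miTrain, miSamples = miSamp))
}

#' Correlation between Hamming distance and latent-space distance
#'
#' For every sequence, computes the Hamming distance to the target and the
#' Euclidean distance between the latent means (mu) of the sequence and the
#' target, then reports squared Pearson correlations over all sequences and
#' over the closest 5% by Hamming distance (ceiling count, ties broken by
#' input order). Subsets with fewer than 3 sequences or zero variance yield
#' `NA`.
#'
#' @param model A trained [SequenceVAE-class].
#' @param aln A [FamilyAlignment-class] of the model's width.
#' @param target Target row; defaults to the alignment's target sequence.
#' @return List with `r2All`, `r2Closest5`, and the per-sequence `hamming`
#'   and `latent` distance vectors.
#' @export
hammingLatentCorrelation <- function(model, aln,
                                     target = targetSequence(aln)) {
  seqs <- alignmentSeqs(aln)
  enc <- encodeSequences(model, unname(seqs))
  encT <- encodeTarget(model, target)
  ham <- vapply(unname(seqs), hammingDistance, integer(1L), b = target,
                USE.NAMES = FALSE)
  lat <- sqrt(colSums((t(enc$mu) - encT$mu)^2))
  r2All <- if (length(ham) >= 3L) squaredPearson(ham, lat) else NA_real_
  nClose <- ceiling(0.05 * length(ham))
  ord <- order(ham)[seq_len(nClose)]
  r2Close <- if (nClose >= 3L) squaredPearson(ham[ord], lat[ord]) else
    NA_real_
  list(r2All = r2All, r2Closest5 = r2Close, hamming = ham, latent = lat)
}

#' Full model-fidelity diagnostic report
#'
#' Samples `nSamples` sequences from the model (posterior-predictive by
#' default: latent draws around encodings of family members, categorical
#' letter realization) and computes frequency and MI agreement with the
#' training alignment plus the Hamming-vs-latent correlations.
#'
#' @param model A trained [SequenceVAE-class].
#' @param train Training [FamilyAlignment-class].
#' @param nSamples Number of model samples (default the training depth).
#' @param method Sequence realization; see [sampleSequences()].
#' @param zSource Latent source; see [sampleSequences()].
#' @param seed Integer seed.
#' @return A [FidelityReport-class].
#' @export
fidelityReport <- function(model, train, nSamples = numSequences(train),
                           method = "categorical", zSource = "posterior",
                           seed = 1L) {
  samples <- sampleSequences(model, nSamples, method = method,
                             zSource = zSource,
                             sourceSeqs = unname(alignmentSeqs(train)),
                             seed = seed)
  rep <- fidelityR2(train, samples)
  hl <- hammingLatentCorrelation(model, train)
  new("FidelityReport", freqR2 = rep@freqR2, miR2 = rep@miR2,
      hammingLatentAll = hl$r2All, hammingLatentClosest = hl$r2Closest5,
      details = c(rep@details, list(samples = samples, hamming = hl$hamming,
                                    latent = hl$latent)))
}
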