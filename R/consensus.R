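#' Family consensus sequence
#'
#' Per column, the most frequent non-gap letter; ties break by the fixed
#' alphabet order. A column that is majority-gap still yields its most
#' frequent non-gap letter; a column that is entirely gap is an error.
#'
#' @param aln A [FamilyAlignment-class].
#' @return Character scalar of the alignment width.
#' @export
consensusSequence <- function(aln) {
  freq <- columnFrequencies(aln)
  aaFreq <- freq[, -ncol(freq), drop = FALSE]     # drop the gap column
  if (any(rowSums(aaFreq) == 0))
    stop(sprintf("column %d is entirely gap; no consensus letter exists",
                 which(rowSums(aaFreq) == 0)[1L]))
  # max.col with ties.method = "first" realizes the alphabet-order tie-break
  paste(colnames(aaFreq)[max.col(aaFreq, ties.method = "first")],
        collapse = "")
}

#' Substitutions converting the target to the consensus
#'
#' @param consensus,target Equal-width rows.
#' @return `data.frame` with columns `position` (1-based), `from` (target
#'   letter), `to` (consensus letter), `name` (e.g. `"A135T"`), ordered by
#'   position. Positions where the target has a gap are skipped (a consensus
#'   protein cannot substitute into a gap).
#' @export
consensusSubstitutions <- function(consensus, target) {
  if (nchar(consensus) != nchar(target))
    stop("consensus and target widths differ")
  cv <- strsplit(consensus, "")[[1L]]
  tv <- strsplit(target, "")[[1L]]
  idx <- which(cv != tv & tv != "-" & cv != "-")
  data.frame(position = idx, from = tv[idx], to = cv[idx],
             name = paste0(tv[idx], idx, cv[idx]),
             stringsAsFactors = FALSE)
}

#' Enumerate or sample the combinatorial consensus library
#'
#' Each substitution is an independent on/off choice, so k substitutions
#' define a library of `2^k` amino-acid sequences (including the unmodified
#' target). `mode = "sample"` draws `n` distinct on/off combinations
#' uniformly without replacement.
#'
#' @param target Target row.
#' @param substitutions `data.frame` from [consensusSubstitutions()].
#' @param mode `"full"` or `"sample"`.
#' @param n Number of variants for `mode = "sample"`.
#' @param seed Integer seed for sampling.
#' @return Character vector of variant rows, named `cons_0001`, ... (full
#'   mode names the all-off member `cons_0000` = target first).
#' @export
enumerateLibrary <- function(target, substitutions,
                             mode = c("full", "sample"), n = NULL,
                             seed = 1L) {
  mode <- match.arg(mode)
  k <- nrow(substitutions)
  build <- function(mask) {
    v <- strsplit(target, "")[[1L]]
    on <- which(mask)
    v[substitutions$position[on]] <- substitutions$to[on]
    paste(v, collapse = "")
  }
  if (mode == "full") {
    if (k > 25L)
      stop(sprintf("refusing full enumeration of 2^%d variants", k))
    masks <- if (k == 0L) list(logical(0)) else
      lapply(seq_len(2^k) - 1L, function(i)
        as.logical(bitwAnd(i, bitwShiftL(1L, seq_len(k) - 1L))))
    seqs <- vapply(masks, build, character(1L))
  } else {
    if (is.null(n)) stop("n is required in sample mode")
    total <- 2^k
    if (n > total)
      stop(sprintf("cannot draw %d distinct variants from a library of %g",
                   n, total))
    codes <- withSeed(seed, {
      if (total <= 2^31 - 1) sample.int(total, n) - 1L
      else stop("library too large to sample by index")
    })
    seqs <- vapply(codes, function(i)
      build(as.logical(bitwAnd(i, bitwShiftL(1L, seq_len(k) - 1L)))),
      character(1L))
  }
  names(seqs) <- sprintf("cons_%04d", seq_along(seqs) - as.integer(mode == "full"))
  seqs
}

#' One-call consensus design
#'
#' Derives the consensus, lists substitutions relative to the target, and
#' reports the combinatorial library size.
#'
#' @param aln A [FamilyAlignment-class].
#' @param target Target row; defaults to the alignment's target sequence.
#' @return List with `consensus`, `substitutions` and `librarySize` (`2^k`).
#' @export
consensusDesign <- function(aln, target = targetSequence(aln)) {
  cons <- consensusSequence(aln)
  subs <- consensusSubstitutions(cons, target)
  list(consensus = cons, substitutions = subs,
       librarySize = 2^nrow(subs))
}
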