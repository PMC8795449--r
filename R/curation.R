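#' Per-sequence gappiness scores
#'
#' Scores how much each sequence contributes to heavily gapped alignment
#' columns. With column gap fraction `g_j = N_gap_j / N`, a sequence's score
#' is the sum of `g_j` over the columns where that sequence itself has a gap
#' *and* `g_j` strictly exceeds the threshold `w`. Columns at exactly
#' fraction `w` contribute nothing. Sequences that force many mostly-gap
#' columns (structurally dissimilar homologs) score high.
#'
#' @param aln A [FamilyAlignment-class].
#' @param w Gap-fraction threshold in `[0, 1]` (default 0.9).
#' @return Named numeric vector of scores, one per sequence, in input order.
#' @export
#' @examples
#' aln <- FamilyAlignment(c("t", "a", "b", "c"),
#'                        c("A-CD", "A-CD", "A-CD", "AACD"), "t")
#' gappinessScores(aln, w = 0.5)  # column 2 has gap fraction 0.75
gappinessScores <- function(aln, w = 0.9) {
  stopifnot(w >= 0, w <= 1)
  gapMat <- alignmentCharMatrix(aln) == "-"
  gapFrac <- colMeans(gapMat)
  scored <- ifelse(gapFrac > w, gapFrac, 0)
  drop(gapMat %*% scored)
}

#' Curation parameters for filterAlignment
#'
#' Defaults reproduce the package's standard curation recipe: gappiness
#' threshold `w = 0.9` with score cutoff 10, minimum ungapped length 290, and
#' a case-sensitive description keyword (disabled unless supplied).
#'
#' @param w Gap-fraction threshold in `[0, 1]`.
#' @param scoreCutoff Sequences with gappiness score strictly above this are
#'   removed.
#' @param minUngappedLength Sequences whose ungapped length is below this are
#'   removed.
#' @param keyword Optional case-sensitive substring that must appear in the
#'   FASTA description; `NULL` disables the filter.
#' @return A list of class `GappinessParams`.
#' @export
gappinessParams <- function(w = 0.9, scoreCutoff = 10,
                            minUngappedLength = 290, keyword = NULL) {
  stopifnot(w >= 0, w <= 1, scoreCutoff > 0, minUngappedLength >= 1)
  structure(list(w = w, scoreCutoff = scoreCutoff,
                 minUngappedLength = minUngappedLength, keyword = keyword),
            class = "GappinessParams")
}

#' Filter an alignment by gappiness, length and description keyword
#'
#' Removes, in order: (1) sequences whose gappiness score exceeds
#' `scoreCutoff` (scores computed once, on the input alignment);
#' (2) sequences whose ungapped length is below `minUngappedLength`;
#' (3) sequences whose description lacks the configured keyword
#' (case-sensitive substring). The target sequence defines the family and
#' must survive every filter.
#'
#' @param aln A [FamilyAlignment-class].
#' @param params A [gappinessParams()] list.
#' @return A list with elements `alignment` (filtered) and `report`
#'   (a [CurationReport-class]).
#' @export
filterAlignment <- function(aln, params = gappinessParams()) {
  stopifnot(inherits(params, "GappinessParams"))
  n0 <- numSequences(aln)
  s <- gappinessScores(aln, params$w)

  gappy <- s > params$scoreCutoff
  ungapped <- nchar(gsub("-", "", aln@seqs, fixed = TRUE))
  short <- !gappy & ungapped < params$minUngappedLength
  if (!is.null(params$keyword)) {
    nokey <- !gappy & !short &
      !grepl(params$keyword, aln@descriptions, fixed = TRUE)
  } else {
    nokey <- rep(FALSE, n0)
  }

  isTarget <- aln@ids == aln@targetId
  if (any((gappy | short | nokey) & isTarget))
    stop(sprintf("target sequence '%s' would be removed by the filters",
                 aln@targetId))
  keep <- !(gappy | short | nokey)
  if (!any(keep)) stop("filtering removed every sequence")

  report <- new("CurationReport",
                nInput = n0,
                nRemovedGappy = sum(gappy),
                nRemovedShort = sum(short),
                nRemovedKeyword = sum(nokey),
                nOutput = sum(keep),
                removedIds = list(gappy = aln@ids[gappy],
                                  short = aln@ids[short],
                                  keyword = aln@ids[nokey]),
                slicedColumns = integer())
  list(alignment = subsetAlignment(aln, keep), report = report)
}

#' Slice alignment columns to the target's ungapped positions
#'
#' Drops every column where the target row carries a gap, so the target row
#' becomes fully ungapped and column indices map one-to-one onto target
#' residue positions. Other rows may still contain gaps (future deletions).
#' Idempotent. Dropped column indices are reported 0-based.
#'
#' @param aln A [FamilyAlignment-class].
#' @return A list with elements `alignment` and `report`
#'   (a [CurationReport-class] whose `slicedColumns` holds the dropped,
#'   0-based column indices).
#' @export
sliceToTarget <- function(aln) {
  tgt <- strsplit(targetSequence(aln), "")[[1L]]
  dropCols <- which(tgt == "-")
  if (length(dropCols)) {
    keepCols <- setdiff(seq_along(tgt), dropCols)
    m <- alignmentCharMatrix(aln)[, keepCols, drop = FALSE]
    seqs <- apply(m, 1L, paste, collapse = "")
    out <- FamilyAlignment(ids = aln@ids, seqs = unname(seqs),
                           targetId = aln@targetId,
                           descriptions = aln@descriptions)
  } else {
    out <- aln
  }
  report <- new("CurationReport",
                nInput = numSequences(aln), nOutput = numSequences(aln),
                nRemovedGappy = 0L, nRemovedShort = 0L, nRemovedKeyword = 0L,
                removedIds = list(gappy = character(), short = character(),
                                  keyword = character()),
                slicedColumns = as.integer(dropCols - 1L))
  list(alignment = out, report = report)
}

#' One-call curation: filter then slice to the target
#'
#' @inheritParams filterAlignment
#' @return A list with `alignment`, `filterReport` and `sliceReport`.
#' @export
curateAlignment <- function(aln, params = gappinessParams()) {
  f <- filterAlignment(aln, params)
  s <- sliceToTarget(f$alignment)
  list(alignment = s$alignment, filterReport = f$report,
       sliceReport = s$report)
}

#' Serialize a CurationReport to JSON
#'
#' @param report A [CurationReport-class].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
curationReportJSON <- function(report, path = NULL) {
  x <- list(n_input = report@nInput,
            n_removed_gappy = report@nRemovedGappy,
            n_removed_short = report@nRemovedShort,
            n_removed_keyword = report@nRemovedKeyword,
            n_output = report@nOutput,
            removed_ids = report@removedIds,
            sliced_columns = report@slicedColumns)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
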