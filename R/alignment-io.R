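#' Read an aligned protein FASTA into a FamilyAlignment
#'
#' Records must all have the same aligned length. Letters are uppercased and
#' `.` gap characters are normalized to `-`. Ambiguity/rare codes
#' (B, J, X, Z, U, O) are rejected by default or, with
#' `ambiguous = "gap"`, mapped to the gap letter.
#'
#' @param path Path to an aligned FASTA file.
#' @param targetId Identifier of the designated wildtype sequence; matched
#'   against the first whitespace-delimited token of each FASTA header.
#' @param ambiguous Either `"error"` (default) or `"gap"`: what to do with
#'   the ambiguity codes B, J, X, Z, U, O.
#'
#' @return A [FamilyAlignment-class] object, preserving input order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">wt target", "ACD-", ">s1", "ACDE"), fa)
#' readFamilyAlignment(fa, targetId = "wt")
readFamilyAlignment <- function(path, targetId, ambiguous = c("error", "gap")) {
  ambiguous <- match.arg(ambiguous)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(ss))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)

  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    ref <- widths[1L]
    bad <- which(widths != ref)[1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 ids[bad], widths[bad], ref))
  }
  amb <- c("B", "J", "X", "Z", "U", "O")
  if (ambiguous == "gap") {
    seqs <- gsub(paste0("[", paste(amb, collapse = ""), "]"), "-", seqs)
  } else {
    hit <- regexpr(paste0("[", paste(amb, collapse = ""), "]"), seqs)
    if (any(hit > 0L)) {
      i <- which(hit > 0L)[1L]
      stop(sprintf(
        "unknown letter '%s' in record '%s' at position %d (use ambiguous = \"gap\" to map rare codes to the gap letter)",
        substr(seqs[i], hit[i], hit[i]), ids[i], hit[i]))
    }
  }
  if (!targetId %in% ids)
    stop(sprintf("target id '%s' not found among the %d records", targetId,
                 length(ids)))
  FamilyAlignment(ids = ids, seqs = seqs, targetId = targetId,
                  descriptions = headers)
}

#' Write a FamilyAlignment (or plain sequences) to FASTA
#'
#' @param x A [FamilyAlignment-class], or a named character vector of
#'   sequences.
#' @param path Output file path.
#' @param ungap Drop gap letters before writing (useful for variant output).
#' @return `path`, invisibly.
#' @export
writeFamilyFasta <- function(x, path, ungap = FALSE) {
  if (is(x, "FamilyAlignment")) {
    seqs <- x@seqs
    names(seqs) <- x@descriptions
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  if (ungap) seqs <- gsub("-", "", seqs, fixed = TRUE)
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

# Internal: alignment as an N x L character matrix (rows named by id).
alignmentCharMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln@seqs, ""))
  rownames(m) <- aln@ids
  m
}

# Internal: alignment as an N x L integer matrix of alphabet indices.
alignmentIndexMatrix <- function(aln, alphabet = proteinAlphabet()) {
  m <- alignmentCharMatrix(aln)
  idx <- match(m, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1L, ]
    stop(sprintf("letter '%s' (sequence '%s', column %d) is not in the alphabet",
                 m[bad[1L], bad[2L]], rownames(m)[bad[1L]], bad[2L]))
  }
  matrix(idx, nrow = nrow(m), dimnames = dimnames(m))
}

# Internal: keep a subset of sequences, preserving order.
subsetAlignment <- function(aln, keep) {
  idx <- if (is.character(keep)) match(keep, aln@ids) else which(keep)
  FamilyAlignment(ids = aln@ids[idx], seqs = aln@seqs[idx],
                  targetId = aln@targetId,
                  descriptions = aln@descriptions[idx])
}
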