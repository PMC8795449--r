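#' Amino-acid alphabet used throughout the package
#'
#' Twenty amino acids in a fixed order followed by the gap letter `-`.
#' The alphabet order is part of every model checkpoint and is the tie-break
#' order for consensus calling, so it is deliberately frozen.
#'
#' @return Character vector of 21 single letters.
#' @export
#' @examples
#' proteinAlphabet()
proteinAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' @rdname FamilyAlignment-class
#' @export
setClass("FamilyAlignment",
  representation(
    ids = "character",
    seqs = "character",
    descriptions = "character",
    targetId = "character"
  )
)

setValidity("FamilyAlignment", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@seqs) != n)
    msg <- c(msg, "ids and seqs must have equal length")
  if (length(object@descriptions) != n)
    msg <- c(msg, "descriptions must parallel ids")
  if (n == 0L)
    msg <- c(msg, "alignment must contain at least one sequence")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "sequence identifiers must be unique")
  if (length(object@targetId) != 1L || !(object@targetId %in% object@ids))
    msg <- c(msg, "targetId must name exactly one sequence present in the alignment")
  if (n > 0L) {
    w <- nchar(object@seqs)
    if (length(unique(w)) > 1L) {
      bad <- object@ids[which(w != w[1L])[1L]]
      msg <- c(msg, sprintf("ragged alignment: record '%s' has length %d, expected %d",
                            bad, nchar(object@seqs[object@ids == bad][1L]), w[1L]))
    } else {
      letters_seen <- unique(strsplit(paste(object@seqs, collapse = ""), "")[[1L]])
      extra <- setdiff(letters_seen, proteinAlphabet())
      if (length(extra))
        msg <- c(msg, sprintf("letters outside the 21-letter alphabet: %s",
                              paste(extra, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' FamilyAlignment: a rectangular protein alignment with a designated target
#'
#' Holds equal-length aligned rows over the 21-letter alphabet (20 amino acids
#' plus the gap letter `-`), unique identifiers, FASTA descriptions, and the
#' id of the designated target (wildtype) sequence that anchors curation,
#' weighting, sampling and mutation naming.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of equal-length aligned rows.
#' @param targetId Identifier of the designated wildtype; must be in `ids`.
#' @param descriptions Optional character vector of record descriptions
#'   (defaults to the ids).
#'
#' @return A `FamilyAlignment` object.
#' @seealso [readFamilyAlignment()], [filterAlignment()], [sliceToTarget()]
#' @export
#' @examples
#' aln <- FamilyAlignment(c("t", "s1"), c("ACD-", "ACDE"), targetId = "t")
#' alignmentWidth(aln)
FamilyAlignment <- function(ids, seqs, targetId, descriptions = ids) {
  new("FamilyAlignment",
      ids = as.character(ids),
      seqs = toupper(as.character(seqs)),
      descriptions = as.character(descriptions),
      targetId = as.character(targetId))
}

#' Report produced by the curation steps
#'
#' Tallies input/output depths, removals per reason (with the removed ids),
#' and the 0-based indices of columns dropped when slicing to the target.
#'
#' @export
setClass("CurationReport",
  representation(
    nInput = "integer",
    nRemovedGappy = "integer",
    nRemovedShort = "integer",
    nRemovedKeyword = "integer",
    nOutput = "integer",
    removedIds = "list",
    slicedColumns = "integer"
  ),
  prototype(
    nInput = 0L, nRemovedGappy = 0L, nRemovedShort = 0L,
    nRemovedKeyword = 0L, nOutput = 0L,
    removedIds = list(gappy = character(), short = character(),
                      keyword = character()),
    slicedColumns = integer()
  )
)

setValidity("CurationReport", function(object) {
  if (object@nInput !=
      object@nOutput + object@nRemovedGappy + object@nRemovedShort +
      object@nRemovedKeyword)
    return("removal tallies do not sum to nInput")
  TRUE
})

#' A trained (or initialized) convolutional sequence VAE
#'
#' Bundles the architecture configuration, the 21-letter alphabet, the
#' alignment width it was built for, the network parameters, and the
#' per-epoch training history.
#'
#' @export
setClass("SequenceVAE",
  representation(
    config = "list",
    alphabet = "character",
    width = "integer",
    params = "list",
    history = "data.frame",
    trained = "logical"
  )
)

#' A deduplicated set of sampled variants of the target sequence
#'
#' Rows are unique sequences (alignment coordinates; gaps mark deletions)
#' with their generating variance scale, Hamming distance to the target, and
#' mutation names in 1-based target coordinates (deletions carry a Greek
#' Delta prefix, e.g. `ΔK70`).
#'
#' @export
setClass("VariantSet",
  representation(
    target = "character",
    variants = "data.frame",
    perScale = "data.frame"
  )
)

setValidity("VariantSet", function(object) {
  v <- object@variants
  need <- c("id", "sequence", "scale", "hamming", "mutations")
  if (!all(need %in% names(v)))
    return(sprintf("variants table must have columns: %s",
                   paste(need, collapse = ", ")))
  if (nrow(v) && anyDuplicated(v$sequence))
    return("variant sequences must be unique")
  if (nrow(v) && any(v$sequence == object@target))
    return("the target itself may not appear as a variant")
  TRUE
})

#' Model-fidelity diagnostics report
#'
#' Frequency and mutual-information agreement between training data and model
#' samples, plus Hamming-versus-latent-distance correlations.
#'
#' @export
setClass("FidelityReport",
  representation(
    freqR2 = "numeric",
    miR2 = "numeric",
    hammingLatentAll = "numeric",
    hammingLatentClosest = "numeric",
    details = "list"
  ),
  prototype(freqR2 = NA_real_, miR2 = NA_real_,
            hammingLatentAll = NA_real_, hammingLatentClosest = NA_real_,
            details = list())
)

#' Ridge regression result for one response
#'
#' Standardized coefficients per predictor (mutations plus the library
#' covariate), the unpenalized intercept, the penalty used, fitted values and
#' residuals, and the design that produced them.
#'
#' @export
setClass("RegressionResult",
  representation(
    coefficients = "numeric",
    intercept = "numeric",
    lambda = "numeric",
    fitted = "numeric",
    residuals = "numeric",
    response = "character",
    design = "matrix"
  )
)
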