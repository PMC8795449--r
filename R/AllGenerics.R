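#' @rdname FamilyAlignment-class
#' @param x,object A package object.
#' @export
setGeneric("alignmentIds", function(x) standardGeneric("alignmentIds"))

#' @rdname FamilyAlignment-class
#' @export
setGeneric("alignmentSeqs", function(x) standardGeneric("alignmentSeqs"))

#' @rdname FamilyAlignment-class
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname FamilyAlignment-class
#' @export
setGeneric("numSequences", function(x) standardGeneric("numSequences"))

#' @rdname FamilyAlignment-class
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' @rdname FamilyAlignment-class
#' @export
setGeneric("targetSequence", function(x) standardGeneric("targetSequence"))

#' @rdname VariantSet-class
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

setMethod("alignmentIds", "FamilyAlignment", function(x) x@ids)
setMethod("alignmentSeqs", "FamilyAlignment", function(x) {
  stats::setNames(x@seqs, x@ids)
})
setMethod("alignmentWidth", "FamilyAlignment", function(x) nchar(x@seqs[1L]))
setMethod("numSequences", "FamilyAlignment", function(x) length(x@ids))
setMethod("targetId", "FamilyAlignment", function(x) x@targetId)
setMethod("targetSequence", "FamilyAlignment", function(x) {
  x@seqs[match(x@targetId, x@ids)]
})

#' @rdname VariantSet-class
#' @aliases variantTable,VariantSet-method
setMethod("variantTable", "VariantSet", function(x) x@variants)

setMethod("show", "FamilyAlignment", function(object) {
  cat(sprintf("FamilyAlignment: %d sequences x %d columns (target '%s')\n",
              numSequences(object), alignmentWidth(object), targetId(object)))
  gap <- mean(strsplit(paste(object@seqs, collapse = ""), "")[[1L]] == "-")
  cat(sprintf("  gap fraction: %.3f\n", gap))
})

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  cat(sprintf("  input:            %d\n", object@nInput))
  cat(sprintf("  removed (gappy):  %d\n", object@nRemovedGappy))
  cat(sprintf("  removed (short):  %d\n", object@nRemovedShort))
  cat(sprintf("  removed (keyword):%d\n", object@nRemovedKeyword))
  cat(sprintf("  output:           %d\n", object@nOutput))
  if (length(object@slicedColumns))
    cat(sprintf("  sliced columns:   %d (0-based indices)\n",
                length(object@slicedColumns)))
})

setMethod("show", "SequenceVAE", function(object) {
  cfg <- object@config
  cat(sprintf("SequenceVAE (%s): L=%d, |A|=%d, latent=%d\n",
              if (object@trained) "trained" else "untrained",
              object@width, length(object@alphabet), cfg$latentDim))
  cat(sprintf("  encoder filters: %s; decoder filters: %s\n",
              paste(cfg$encoderFilters, collapse = "/"),
              paste(cfg$decoderFilters, collapse = "/")))
  if (nrow(object@history))
    cat(sprintf("  last epoch: train total %.4f, test total %.4f\n",
                utils::tail(object@history$trainTotal, 1L),
                utils::tail(object@history$testTotal, 1L)))
})

setMethod("show", "VariantSet", function(object) {
  v <- object@variants
  cat(sprintf("VariantSet: %d unique variants of a %d-residue target\n",
              nrow(v), nchar(object@target)))
  if (nrow(v))
    cat(sprintf("  Hamming distance to target: %d-%d (mean %.2f)\n",
                min(v$hamming), max(v$hamming), mean(v$hamming)))
})

setMethod("show", "FidelityReport", function(object) {
  cat("FidelityReport\n")
  cat(sprintf("  frequency R^2:          %s\n", fmtOrNA(object@freqR2)))
  cat(sprintf("  mutual information R^2: %s\n", fmtOrNA(object@miR2)))
  cat(sprintf("  Hamming~latent R^2 (all / closest 5%%): %s / %s\n",
              fmtOrNA(object@hammingLatentAll),
              fmtOrNA(object@hammingLatentClosest)))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult for '%s' (lambda = %g, n = %d, p = %d)\n",
              object@response, object@lambda, length(object@fitted),
              length(object@coefficients)))
  top <- utils::head(order(abs(object@coefficients), decreasing = TRUE), 5L)
  for (i in top)
    cat(sprintf("  %-12s % .4f\n", names(object@coefficients)[i],
                object@coefficients[i]))
})

fmtOrNA <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)
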