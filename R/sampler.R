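#' Encode the target (wildtype) sequence
#'
#' Deterministic latent Gaussian parameters for the designated target; the
#' anchor for near-wildtype variant sampling.
#'
#' @param model A trained [SequenceVAE-class].
#' @param target Target row (aligned, model width).
#' @return List with numeric vectors `mu` and `logVar`.
#' @export
encodeTarget <- function(model, target) {
  if (nchar(target) != model@config$L)
    stop(sprintf("target length %d does not match model width %d",
                 nchar(target), model@config$L))
  enc <- encodeSequences(model, target)
  list(mu = drop(enc$mu), logVar = drop(enc$logVar))
}

#' Decode samples around an encoding at a given variance scale
#'
#' Draws `z ~ N(mu, scale * diag(exp(logVar)))` and argmax-decodes each draw.
#' Scale 0 decodes the maximum a posteriori latent point, so all draws are
#' identical. By default the scale multiplies the variance; `scaleSigma=TRUE`
#' multiplies the standard deviation instead.
#'
#' @param model A trained [SequenceVAE-class].
#' @param enc Encoding list from [encodeTarget()].
#' @param scale Nonnegative variance multiplier.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param scaleSigma Interpret `scale` as a standard-deviation multiplier.
#' @return Character vector of `n` decoded sequences (alignment width; gap
#'   letters mark deletions).
#' @export
sampleAtScale <- function(model, enc, scale, n, seed = 1L,
                          scaleSigma = FALSE) {
  stopifnot(scale >= 0)
  latentDim <- length(enc$mu)
  sdVec <- exp(0.5 * enc$logVar) * if (scaleSigma) scale else sqrt(scale)
  withSeed(seed, {
    eps <- matrix(stats::rnorm(n * latentDim), n, latentDim)
    z <- sweep(eps, 2L, sdVec, "*")
    z <- sweep(z, 2L, enc$mu, "+")
    out <- character(n)
    for (start in seq(1L, n, by = 256L)) {
      idx <- start:min(start + 255L, n)
      dec <- decoderForward(model@params, model@config,
                            z[idx, , drop = FALSE])
      out[idx] <- probsToSequences(dec$probs, model@alphabet, "argmax")
    }
    out
  })
}

#' Sampling schedule for the variance sweep
#'
#' @param scales Increasing nonnegative variance multipliers (default a
#'   geometric ladder starting at 0).
#' @param samplesPerScale Draws per scale (default 100).
#' @param maxMutations Per-variant mutation cap (default 16).
#' @param maxVariants Optional cap on the total retained variants.
#' @param seed Integer seed.
#' @param stopRule `"first-overflow"` stops after the first scale that yields
#'   any over-cap sequence; `"filter-and-continue"` keeps sweeping all scales
#'   and just drops over-cap sequences.
#' @return A list of class `SamplingSchedule`.
#' @export
samplingSchedule <- function(scales = c(0, 0.25, 0.5, 1, 2, 4, 8, 16),
                             samplesPerScale = 100L, maxMutations = 16L,
                             maxVariants = NULL, seed = 1L,
                             stopRule = c("first-overflow",
                                          "filter-and-continue")) {
  stopifnot(all(scales >= 0), !is.unsorted(scales), samplesPerScale >= 1L,
            maxMutations >= 1L)
  structure(list(scales = scales, samplesPerScale = as.integer(samplesPerScale),
                 maxMutations = as.integer(maxMutations),
                 maxVariants = maxVariants, seed = as.integer(seed),
                 stopRule = match.arg(stopRule)),
            class = "SamplingSchedule")
}

#' Sweep the variance scale and collect near-target variants
#'
#' Encodes the target, then iterates the schedule's scales: at each scale it
#' argmax-decodes samples around the target encoding, keeps sequences that
#' differ from the target, drops sequences exceeding the mutation cap,
#' and deduplicates exactly (first occurrence keeps its generating scale).
#' With the default stop rule the sweep ends at the first scale that
#' produces any over-cap sequence.
#'
#' @param model A trained [SequenceVAE-class].
#' @param target Target row (aligned, model width).
#' @param schedule A [samplingSchedule()].
#' @return A [VariantSet-class]; its `perScale` slot tallies draws, unique
#'   new variants and over-cap counts per scale.
#' @export
varianceSweep <- function(model, target, schedule = samplingSchedule()) {
  stopifnot(inherits(schedule, "SamplingSchedule"))
  enc <- encodeTarget(model, target)
  seen <- character()
  rows <- list()
  tally <- list()
  for (si in seq_along(schedule$scales)) {
    sc <- schedule$scales[si]
    seqs <- sampleAtScale(model, enc, sc, schedule$samplesPerScale,
                          seed = schedule$seed + si)
    ham <- vapply(seqs, hammingDistance, integer(1L), b = target,
                  USE.NAMES = FALSE)
    over <- ham > schedule$maxMutations
    keep <- !over & ham > 0L & !(seqs %in% seen) & !duplicated(seqs)
    newSeqs <- seqs[keep]
    seen <- c(seen, newSeqs)
    if (length(newSeqs))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = newSeqs, scale = sc, hamming = ham[keep],
        stringsAsFactors = FALSE)
    tally[[si]] <- data.frame(scale = sc, drawn = length(seqs),
                              overCap = sum(over), newUnique = sum(keep))
    if (schedule$stopRule == "first-overflow" && any(over)) break
  }
  v <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), scale = numeric(),
               hamming = integer(), stringsAsFactors = FALSE)
  if (!is.null(schedule$maxVariants) && nrow(v) > schedule$maxVariants)
    v <- v[seq_len(schedule$maxVariants), , drop = FALSE]
  if (nrow(v) == 0L)
    warning("variance sweep produced no variants distinct from the target")
  v$id <- sprintf("vae_%04d", seq_len(nrow(v)))
  v$mutations <- vapply(v$sequence, function(s)
    paste(mutationCalls(s, target), collapse = ","), character(1L),
    USE.NAMES = FALSE)
  rownames(v) <- NULL
  new("VariantSet", target = target,
      variants = v[, c("id", "sequence", "scale", "hamming", "mutations")],
      perScale = do.call(rbind, tally))
}

#' Name the mutations separating a variant from the target
#'
#' Positions are 1-based target (wildtype) coordinates. Substitutions are
#' written `XnY` (target letter, position, variant letter); a gap in the
#' variant at target letter X, position n is the deletion `ΔXn`.
#'
#' @param variant,target Equal-width aligned rows.
#' @return Character vector of mutation names (empty if identical).
#' @export
#' @examples
#' mutationCalls("SRA", "SKA")   # "K2R"
#' mutationCalls("S-A", "SKA")   # deletion at position 2
mutationCalls <- function(variant, target) {
  if (nchar(variant) != nchar(target))
    stop("variant and target widths differ")
  tv <- strsplit(target, "")[[1L]]
  vv <- strsplit(variant, "")[[1L]]
  idx <- which(tv != vv)
  vapply(idx, function(i) {
    if (vv[i] == "-") paste0("Δ", tv[i], i)
    else paste0(tv[i], i, vv[i])
  }, character(1L))
}

#' Apply named mutations to the target sequence
#'
#' Inverse of [mutationCalls()]: substitutions `XnY` place letter Y at
#' position n, deletions `ΔXn` place a gap. The stated target letter is
#' checked against the actual target.
#'
#' @param target Target row.
#' @param mutations Character vector of mutation names.
#' @return The mutated row (alignment coordinates).
#' @export
applyMutations <- function(target, mutations) {
  v <- strsplit(target, "")[[1L]]
  for (m in mutations) {
    if (startsWith(m, "Δ")) {
      wt <- substr(m, 2L, 2L)
      pos <- as.integer(substring(m, 3L))
      newLetter <- "-"
    } else {
      wt <- substr(m, 1L, 1L)
      pos <- as.integer(substr(m, 2L, nchar(m) - 1L))
      newLetter <- substr(m, nchar(m), nchar(m))
    }
    if (is.na(pos) || pos < 1L || pos > length(v))
      stop("malformed mutation name: ", m)
    if (v[pos] != wt)
      stop(sprintf("mutation %s: target has '%s' at position %d", m,
                   v[pos], pos))
    v[pos] <- newLetter
  }
  paste(v, collapse = "")
}

#' Euclidean distance between latent vectors
#'
#' @param z1,z2 Numeric vectors of equal dimension.
#' @return Nonnegative scalar.
#' @export
latentDistance <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("latent dimension mismatch")
  sqrt(sum((z1 - z2)^2))
}

#' Export a VariantSet as FASTA (ungapped) and a variant table
#'
#' @param vs A [VariantSet-class].
#' @param fastaPath,tsvPath Output paths (either may be `NULL` to skip).
#' @return The variant `data.frame`, invisibly.
#' @export
writeVariantSet <- function(vs, fastaPath = NULL, tsvPath = NULL) {
  v <- variantTable(vs)
  if (!is.null(fastaPath))
    writeFamilyFasta(stats::setNames(v$sequence, v$id), fastaPath,
                     ungap = TRUE)
  if (!is.null(tsvPath))
    utils::write.table(v, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(v)
}
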