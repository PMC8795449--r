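#' Configuration for the synthetic protein family generator
#'
#' Builds an explicit generative description of a family: a target
#' (wildtype) row, per-column site profiles over non-target letters, a set
#' of coupled column pairs with designed joint distributions (hence exactly
#' known mutual information), a per-sequence mutation-rate distribution
#' producing a 40-100% identity gradient to the target, and a per-column
#' gap rate. All randomness in the construction derives from `seed`.
#'
#' Each non-target sequence is generated by (1) drawing a mutation rate
#' uniformly from `mutationRateRange`, (2) at uncoupled columns replacing
#' the target letter with that probability by a draw from the column's site
#' profile (profiles exclude the target letter, so a "mutation" always
#' changes the letter), (3) at coupled pairs drawing the letter pair jointly
#' from the designed joint distribution, and (4) inserting gaps at
#' `gapRate` at uncoupled columns (coupled columns stay gap-free so their
#' mutual information equals the designed value exactly in expectation).
#'
#' @param L Alignment width.
#' @param N Number of sequences (including the target, always first).
#' @param nCoupledPairs Number of disjoint coupled column pairs.
#' @param couplingJoint Joint distribution template for each coupled pair: a
#'   named numeric vector over letter pairs such as
#'   `c(AB = 0.5, CD = 0.5)` meaning P(col j = 'A', col k = 'B') = 0.5.
#'   Letters are re-drawn per pair from the 20 amino acids.
#' @param mutationRateRange Range of the uniform per-sequence mutation rate.
#' @param gapRate Per-column gap insertion probability at uncoupled columns.
#' @param profileSize Number of distinct non-target letters per site
#'   profile.
#' @param target Optional explicit target row; generated uniformly over the
#'   20 amino acids when `NULL`.
#' @param seed Integer seed.
#' @return A list of class `FamilyConfig` with fields `L`, `N`, `target`,
#'   `siteProfiles` (L x 21 matrix of probabilities), `coupledPairs` (list
#'   of `list(j, k, joint)` with `joint` a named-letter matrix), `gapRate`,
#'   `mutationRateRange`, `seed`.
#' @export
familyConfig <- function(L = 64L, N = 2000L, nCoupledPairs = 1L,
                         couplingJoint = c(0.5, 0.5),
                         mutationRateRange = c(0, 0.6), gapRate = 0.01,
                         profileSize = 3L, target = NULL, seed = 100L) {
  stopifnot(L >= 4L, N >= 2L, nCoupledPairs >= 0L,
            2L * nCoupledPairs <= L, gapRate >= 0, gapRate < 1,
            all(mutationRateRange >= 0), all(mutationRateRange <= 1))
  aa <- proteinAlphabet()[1:20]
  withSeed(seed, {
    if (is.null(target))
      target <- paste(sample(aa, L, replace = TRUE), collapse = "")
    tv <- strsplit(target, "")[[1L]]
    stopifnot(length(tv) == L, all(tv %in% aa))
    coupledCols <- if (nCoupledPairs > 0L)
      sample(L, 2L * nCoupledPairs) else integer()
    pairs <- lapply(seq_len(nCoupledPairs), function(i) {
      j <- coupledCols[2L * i - 1L]
      k <- coupledCols[2L * i]
      nStates <- length(couplingJoint)
      lettersJ <- sample(aa, nStates)
      lettersK <- sample(aa, nStates)
      joint <- diag(couplingJoint / sum(couplingJoint), nStates)
      dimnames(joint) <- list(lettersJ, lettersK)
      list(j = j, k = k, joint = joint)
    })
    profiles <- matrix(0, L, 21L,
                       dimnames = list(NULL, proteinAlphabet()))
    for (col in setdiff(seq_len(L), coupledCols)) {
      letters <- sample(setdiff(aa, tv[col]), profileSize)
      w <- stats::runif(profileSize)
      profiles[col, letters] <- w / sum(w)
    }
    structure(list(L = as.integer(L), N = as.integer(N), target = target,
                   siteProfiles = profiles, coupledPairs = pairs,
                   gapRate = gapRate, mutationRateRange = mutationRateRange,
                   seed = as.integer(seed)),
              class = "FamilyConfig")
  })
}

#' Generate a synthetic family alignment from a FamilyConfig
#'
#' @param cfg A [familyConfig()].
#' @return A [FamilyAlignment-class] with the target as first record
#'   (id `"target"`), bit-reproducible for a fixed config.
#' @export
generateFamily <- function(cfg) {
  stopifnot(inherits(cfg, "FamilyConfig"))
  L <- cfg$L
  N <- cfg$N
  tv <- strsplit(cfg$target, "")[[1L]]
  coupledCols <- unlist(lapply(cfg$coupledPairs, function(p) c(p$j, p$k)))
  freeCols <- setdiff(seq_len(L), coupledCols)
  alphabet <- colnames(cfg$siteProfiles)
  withSeed(cfg$seed + 1L, {
    m <- matrix(rep(tv, N - 1L), nrow = N - 1L, byrow = TRUE)
    rates <- stats::runif(N - 1L, cfg$mutationRateRange[1L],
                          cfg$mutationRateRange[2L])
    for (col in freeCols) {
      hit <- stats::runif(N - 1L) < rates
      nHit <- sum(hit)
      if (nHit)
        m[hit, col] <- sample(alphabet, nHit, replace = TRUE,
                              prob = cfg$siteProfiles[col, ])
      gap <- stats::runif(N - 1L) < cfg$gapRate
      m[gap, col] <- "-"
    }
    for (p in cfg$coupledPairs) {
      states <- length(p$joint)
      pick <- sample.int(states, N - 1L, replace = TRUE,
                         prob = as.vector(p$joint))
      m[, p$j] <- rownames(p$joint)[(pick - 1L) %% nrow(p$joint) + 1L]
      m[, p$k] <- colnames(p$joint)[(pick - 1L) %/% nrow(p$joint) + 1L]
    }
    seqs <- c(cfg$target, apply(m, 1L, paste, collapse = ""))
    FamilyAlignment(ids = c("target", sprintf("syn_%05d", seq_len(N - 1L))),
                    seqs = seqs, targetId = "target")
  })
}

#' Analytic expectations for a synthetic family
#'
#' Expected per-column letter frequencies and the exact mutual information
#' of each designed coupled pair, computed from the config (no simulation),
#' for use as test oracles.
#'
#' @param cfg A [familyConfig()].
#' @return List with `frequencies` (L x 21 expected frequencies under the
#'   generator, target row excluded) and `pairMI` (numeric vector, nats, one
#'   entry per coupled pair).
#' @export
familyGroundTruth <- function(cfg) {
  stopifnot(inherits(cfg, "FamilyConfig"))
  L <- cfg$L
  alphabet <- colnames(cfg$siteProfiles)
  rBar <- mean(cfg$mutationRateRange)
  tv <- strsplit(cfg$target, "")[[1L]]
  freq <- matrix(0, L, length(alphabet), dimnames = list(NULL, alphabet))
  for (col in seq_len(L)) {
    p <- (1 - rBar) * (alphabet == tv[col]) +
      rBar * cfg$siteProfiles[col, ]
    p <- (1 - cfg$gapRate) * p
    p[length(alphabet)] <- p[length(alphabet)] + cfg$gapRate
    freq[col, ] <- p
  }
  for (p in cfg$coupledPairs) {
    freq[p$j, ] <- 0
    freq[p$j, rownames(p$joint)] <- rowSums(p$joint)
    freq[p$k, ] <- 0
    freq[p$k, colnames(p$joint)] <- colSums(p$joint)
  }
  pairMI <- vapply(cfg$coupledPairs, function(p) {
    pj <- rowSums(p$joint)
    pk <- colSums(p$joint)
    s <- 0
    for (a in seq_along(pj)) for (b in seq_along(pk)) {
      q <- p$joint[a, b]
      if (q > 0) s <- s + q * log(q / (pj[a] * pk[b]))
    }
    s
  }, numeric(1L))
  list(frequencies = freq, pairMI = pairMI)
}

#' Configuration for simulated phenotypes
#'
#' Phenotypes follow the linear model the regression stage assumes:
#' `y = sum(beta[mutations present]) + libraryEffect * [consensus] + noise`,
#' with independent Gaussian noise per replicate.
#'
#' @param betaActivity,betaTm Named effect-size vectors (mutation name ->
#'   effect) for the two responses.
#' @param noiseSd Length-2 named vector `c(activity = , tm = )` of noise
#'   standard deviations.
#' @param libraryEffect Length-2 named additive offsets for consensus-library
#'   variants.
#' @param nReplicates Replicates per variant (default 3).
#' @param seed Integer seed.
#' @return A list of class `PhenotypeConfig`.
#' @export
phenotypeConfig <- function(betaActivity, betaTm,
                            noiseSd = c(activity = 0.5, tm = 0.5),
                            libraryEffect = c(activity = 0, tm = 0),
                            nReplicates = 3L, seed = 7L) {
  stopifnot(all(noiseSd >= 0), nReplicates >= 1L)
  structure(list(betaActivity = betaActivity, betaTm = betaTm,
                 noiseSd = noiseSd, libraryEffect = libraryEffect,
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)),
            class = "PhenotypeConfig")
}

#' Simulate replicate phenotypes for a set of variants
#'
#' @param variantIds Variant identifiers.
#' @param mutationLists List of mutation-name vectors (or comma-joined
#'   character vector) parallel to `variantIds`.
#' @param libraryLabels `"vae"` or `"consensus"` per variant.
#' @param pcfg A [phenotypeConfig()].
#' @return `data.frame` with variant_id, library and
#'   `activity_rep*` / `tm_rep*` columns; attribute `truth` holds the
#'   noiseless response means.
#' @export
generatePhenotypes <- function(variantIds, mutationLists, libraryLabels,
                               pcfg) {
  stopifnot(inherits(pcfg, "PhenotypeConfig"))
  if (is.character(mutationLists))
    mutationLists <- strsplit(mutationLists, ",", fixed = TRUE)
  n <- length(variantIds)
  stopifnot(length(mutationLists) == n, length(libraryLabels) == n)
  isCons <- as.character(libraryLabels) == "consensus"
  meanOf <- function(beta, libEff) {
    vapply(seq_len(n), function(i) {
      mu <- sum(beta[intersect(names(beta), mutationLists[[i]])])
      mu + libEff * isCons[i]
    }, numeric(1L))
  }
  muAct <- meanOf(pcfg$betaActivity, pcfg$libraryEffect[["activity"]])
  muTm <- meanOf(pcfg$betaTm, pcfg$libraryEffect[["tm"]])
  r <- pcfg$nReplicates
  withSeed(pcfg$seed, {
    act <- matrix(stats::rnorm(n * r, mean = rep(muAct, r),
                               sd = pcfg$noiseSd[["activity"]]), n, r)
    tmm <- matrix(stats::rnorm(n * r, mean = rep(muTm, r),
                               sd = pcfg$noiseSd[["tm"]]), n, r)
    out <- data.frame(variant_id = variantIds,
                      library = as.character(libraryLabels),
                      stringsAsFactors = FALSE)
    colnames(act) <- paste0("activity_rep", seq_len(r))
    colnames(tmm) <- paste0("tm_rep", seq_len(r))
    out <- cbind(out, act, tmm)
    attr(out, "truth") <- data.frame(variant_id = variantIds,
                                     activity = muAct, tm = muTm)
    out
  })
}

#' Simulate a combined VAE + consensus mutation library
#'
#' Draws variants carrying random subsets of a fixed mutation universe, the
#' input structure the mutation-effect regression expects (binary mutation
#' indicators plus a library label).
#'
#' @param mutationUniverse Character vector of mutation names.
#' @param nVae,nConsensus Variants per library.
#' @param mutationsPerVariant Expected mutations per variant (Poisson,
#'   truncated to at least 1).
#' @param seed Integer seed.
#' @return `data.frame` with variant_id, library, mutations (comma-joined).
#' @export
simulateMutationLibrary <- function(mutationUniverse, nVae = 90L,
                                    nConsensus = 90L,
                                    mutationsPerVariant = 8, seed = 11L) {
  n <- nVae + nConsensus
  withSeed(seed, {
    muts <- vapply(seq_len(n), function(i) {
      k <- min(length(mutationUniverse),
               max(1L, stats::rpois(1L, mutationsPerVariant)))
      paste(sample(mutationUniverse, k), collapse = ",")
    }, character(1L))
    data.frame(variant_id = sprintf("sim_%04d", seq_len(n)),
               library = rep(c("vae", "consensus"), c(nVae, nConsensus)),
               mutations = muts, stringsAsFactors = FALSE)
  })
}
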