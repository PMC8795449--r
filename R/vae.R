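#' Architecture configuration for the sequence VAE
#'
#' The encoder is three blocks of 3x3 same-padding convolution, ELU and 2x
#' max pooling along the length dimension; flattened features feed two affine
#' heads producing the latent mean and log-variance. The decoder mirrors it
#' with an affine map from the latent vector, three blocks of 2x
#' nearest-neighbour length upsampling, convolution and ELU, a final
#' convolution to one channel, and a softmax over the alphabet dimension.
#' The length is padded internally to the next multiple of 8 with gap-letter
#' columns and cropped on output.
#'
#' @param width Alignment width L the model consumes.
#' @param latentDim Latent dimensionality (default 64).
#' @param encoderFilters Three filter counts for the encoder blocks
#'   (default `c(128, 96, 64)`).
#' @param decoderFilters Three filter counts for the decoder blocks
#'   (default `c(64, 96, 128)`).
#' @param alphabet Letter order; defaults to [proteinAlphabet()].
#' @return A list of class `VAEConfig`.
#' @export
vaeConfig <- function(width, latentDim = 64L,
                      encoderFilters = c(128L, 96L, 64L),
                      decoderFilters = c(64L, 96L, 128L),
                      alphabet = proteinAlphabet()) {
  stopifnot(length(encoderFilters) == 3L, length(decoderFilters) == 3L,
            latentDim >= 1L, width >= 1L)
  lpad <- 8L * as.integer(ceiling(width / 8))
  if (lpad < 8L)
    stop("alignment width too small for three 2x poolings")
  structure(list(
    L = as.integer(width), A = length(alphabet), Lpad = lpad,
    latentDim = as.integer(latentDim),
    encoderFilters = as.integer(encoderFilters),
    decoderFilters = as.integer(decoderFilters),
    alphabet = alphabet
  ), class = "VAEConfig")
}

#' Build an untrained sequence VAE with Kaiming-normal weights
#'
#' @param config A [vaeConfig()].
#' @param seed Integer seed controlling initialization.
#' @return An untrained [SequenceVAE-class].
#' @export
buildVAE <- function(config, seed = 1L) {
  stopifnot(inherits(config, "VAEConfig"))
  params <- withSeed(seed, initVAEParams(config))
  new("SequenceVAE", config = unclass(config), alphabet = config$alphabet,
      width = config$L, params = params,
      history = emptyHistory(), trained = FALSE)
}

initVAEParams <- function(cfg) {
  f <- cfg$encoderFilters
  g <- cfg$decoderFilters
  h8 <- cfg$Lpad %/% 8L
  dEnc <- h8 * cfg$A * f[3L]
  dDec <- h8 * cfg$A * g[1L]
  p <- list()
  addLayer <- function(p, nm, layer) {
    p[[paste0(nm, ".W")]] <- layer$W
    p[[paste0(nm, ".b")]] <- layer$b
    p
  }
  p <- addLayer(p, "enc1", convInit(1L, f[1L]))
  p <- addLayer(p, "enc2", convInit(f[1L], f[2L]))
  p <- addLayer(p, "enc3", convInit(f[2L], f[3L]))
  p <- addLayer(p, "encMu", denseInit(dEnc, cfg$latentDim))
  p <- addLayer(p, "encLv", denseInit(dEnc, cfg$latentDim))
  p <- addLayer(p, "decFc", denseInit(cfg$latentDim, dDec))
  p <- addLayer(p, "dec1", convInit(g[1L], g[1L]))
  p <- addLayer(p, "dec2", convInit(g[1L], g[2L]))
  p <- addLayer(p, "dec3", convInit(g[2L], g[3L]))
  p <- addLayer(p, "decOut", convInit(g[3L], 1L))
  p
}

emptyHistory <- function() {
  data.frame(epoch = integer(), beta = numeric(),
             trainRecon = numeric(), trainKL = numeric(),
             trainTotal = numeric(),
             testRecon = numeric(), testKL = numeric(),
             testTotal = numeric(), testTotalBeta1 = numeric())
}

# Pad a (L, A, B) one-hot array to (Lpad, A, B, 1) with gap-letter columns.
padOneHot <- function(x, cfg) {
  d <- dim(x)
  if (d[1L] != cfg$L || d[2L] != cfg$A)
    stop(sprintf("batch shape (%d, %d) does not match model (%d, %d)",
                 d[1L], d[2L], cfg$L, cfg$A))
  xp <- array(0, dim = c(cfg$Lpad, cfg$A, d[3L], 1L))
  xp[seq_len(cfg$L), , , 1L] <- x
  if (cfg$Lpad > cfg$L)
    xp[(cfg$L + 1L):cfg$Lpad, cfg$A, , 1L] <- 1
  xp
}

encoderForward <- function(params, cfg, x4) {
  c1 <- convForward(x4, params$enc1.W, params$enc1.b)
  e1 <- eluForward(c1$out)
  p1 <- poolForward(e1$out)
  c2 <- convForward(p1$out, params$enc2.W, params$enc2.b)
  e2 <- eluForward(c2$out)
  p2 <- poolForward(e2$out)
  c3 <- convForward(p2$out, params$enc3.W, params$enc3.b)
  e3 <- eluForward(c3$out)
  p3 <- poolForward(e3$out)
  feat <- flattenMap(p3$out)
  mu <- denseForward(feat, params$encMu.W, params$encMu.b)
  logVar <- denseForward(feat, params$encLv.W, params$encLv.b)
  logVar <- pmin(pmax(logVar, -15), 15)   # numerical guard on exp()
  list(mu = mu, logVar = logVar, feat = feat,
       c1 = c1, e1 = e1, p1 = p1, c2 = c2, e2 = e2, p2 = p2,
       c3 = c3, e3 = e3, p3 = p3)
}

decoderForward <- function(params, cfg, z) {
  g <- cfg$decoderFilters
  h8 <- cfg$Lpad %/% 8L
  f0 <- denseForward(z, params$decFc.W, params$decFc.b)
  a0 <- eluForward(f0)
  u0 <- unflattenMap(a0$out, h8, cfg$A, g[1L])
  up1 <- upsampleForward(u0)
  c4 <- convForward(up1, params$dec1.W, params$dec1.b)
  e4 <- eluForward(c4$out)
  up2 <- upsampleForward(e4$out)
  c5 <- convForward(up2, params$dec2.W, params$dec2.b)
  e5 <- eluForward(c5$out)
  up3 <- upsampleForward(e5$out)
  c6 <- convForward(up3, params$dec3.W, params$dec3.b)
  e6 <- eluForward(c6$out)
  c7 <- convForward(e6$out, params$decOut.W, params$decOut.b)
  logits <- c7$out[seq_len(cfg$L), , , 1L, drop = FALSE]
  dim(logits) <- dim(logits)[1:3]
  probs <- softmaxAlphabet(logits)
  list(probs = probs, a0 = a0, c4 = c4, e4 = e4, c5 = c5, e5 = e5,
       c6 = c6, e6 = e6, c7 = c7)
}

# Full forward + backward pass for one batch; returns losses and gradients.
vaeStep <- function(params, cfg, x, eps, beta) {
  B <- dim(x)[3L]
  x4 <- padOneHot(x, cfg)
  enc <- encoderForward(params, cfg, x4)
  sd_ <- exp(0.5 * enc$logVar)
  z <- enc$mu + sd_ * eps
  dec <- decoderForward(params, cfg, z)

  # losses
  A <- cfg$A; L <- cfg$L
  Pm <- `dim<-`(aperm(dec$probs, c(2L, 1L, 3L)), c(A, L * B))
  Xm <- `dim<-`(aperm(x, c(2L, 1L, 3L)), c(A, L * B))
  pTrue <- colSums(Pm * Xm)
  recon <- -sum(log(pmax(pTrue, 1e-8))) / B
  klTerm <- 0.5 * sum(exp(enc$logVar) + enc$mu^2 - 1 - enc$logVar) / B
  total <- recon + beta * klTerm

  # backward: softmax + cross-entropy
  dLogits <- (dec$probs - x) / B
  g <- cfg$decoderFilters
  dL4 <- array(0, dim = c(cfg$Lpad, A, B, 1L))
  dL4[seq_len(L), , , 1L] <- dLogits
  grads <- list()
  bk <- convBackward(dL4, dec$c7, params$decOut.W)
  grads$decOut.W <- bk$dW; grads$decOut.b <- bk$db
  d6 <- eluBackward(bk$dX, dec$e6)
  bk <- convBackward(d6, dec$c6, params$dec3.W)
  grads$dec3.W <- bk$dW; grads$dec3.b <- bk$db
  d5 <- eluBackward(upsampleBackward(bk$dX), dec$e5)
  bk <- convBackward(d5, dec$c5, params$dec2.W)
  grads$dec2.W <- bk$dW; grads$dec2.b <- bk$db
  d4 <- eluBackward(upsampleBackward(bk$dX), dec$e4)
  bk <- convBackward(d4, dec$c4, params$dec1.W)
  grads$dec1.W <- bk$dW; grads$dec1.b <- bk$db
  dU0 <- upsampleBackward(bk$dX)
  dF0 <- eluBackward(flattenMap(dU0), dec$a0)
  bk <- denseBackward(dF0, z, params$decFc.W)
  grads$decFc.W <- bk$dW; grads$decFc.b <- bk$db
  dz <- bk$dX

  dMu <- dz + beta * enc$mu / B
  dLv <- dz * eps * 0.5 * sd_ + beta * 0.5 * (exp(enc$logVar) - 1) / B
  dLv[enc$logVar <= -15 | enc$logVar >= 15] <- 0

  bkMu <- denseBackward(dMu, enc$feat, params$encMu.W)
  grads$encMu.W <- bkMu$dW; grads$encMu.b <- bkMu$db
  bkLv <- denseBackward(dLv, enc$feat, params$encLv.W)
  grads$encLv.W <- bkLv$dW; grads$encLv.b <- bkLv$db
  h8 <- cfg$Lpad %/% 8L
  f <- cfg$encoderFilters
  dFeat <- unflattenMap(bkMu$dX + bkLv$dX, h8, cfg$A, f[3L])
  d3 <- eluBackward(poolBackward(dFeat, enc$p3), enc$e3)
  bk <- convBackward(d3, enc$c3, params$enc3.W)
  grads$enc3.W <- bk$dW; grads$enc3.b <- bk$db
  d2 <- eluBackward(poolBackward(bk$dX, enc$p2), enc$e2)
  bk <- convBackward(d2, enc$c2, params$enc2.W)
  grads$enc2.W <- bk$dW; grads$enc2.b <- bk$db
  d1 <- eluBackward(poolBackward(bk$dX, enc$p1), enc$e1)
  bk <- convBackward(d1, enc$c1, params$enc1.W)
  grads$enc1.W <- bk$dW; grads$enc1.b <- bk$db

  list(recon = recon, kl = klTerm, total = total, grads = grads)
}

# Forward-only loss evaluation (noise supplied by current RNG state).
vaeEvalLoss <- function(params, cfg, x, beta) {
  B <- dim(x)[3L]
  enc <- encoderForward(params, cfg, padOneHot(x, cfg))
  eps <- matrix(stats::rnorm(B * cfg$latentDim), B, cfg$latentDim)
  z <- enc$mu + exp(0.5 * enc$logVar) * eps
  dec <- decoderForward(params, cfg, z)
  elboLoss(dec$probs, x, enc$mu, enc$logVar, beta)
}

#' ELBO loss components
#'
#' Reconstruction is the mean per-sequence cross-entropy (in nats) of the
#' decoder's categorical outputs against the one-hot truth, with
#' probabilities clamped at 1e-8. The KL term is the closed-form divergence
#' of the diagonal-Gaussian posterior from the standard-normal prior,
#' `0.5 * sum(exp(logVar) + mu^2 - 1 - logVar)` per sequence. The total is
#' `reconstruction + beta * kl`.
#'
#' @param probs Decoder output, an `(L, A, B)` array (or `L x A` matrix for a
#'   single sequence) of categorical probabilities.
#' @param x Matching one-hot array.
#' @param mu,logVar Latent Gaussian parameters, `B x latentDim` matrices.
#' @param beta KL annealing scalar in `[0, 1]`.
#' @return List with `reconstruction`, `kl`, `beta`, `total` (nats).
#' @export
elboLoss <- function(probs, x, mu, logVar, beta = 1) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (length(dim(probs)) == 2L) {
    probs <- array(probs, dim = c(dim(probs), 1L))
    x <- array(x, dim = dim(probs))
  }
  stopifnot(all(dim(probs) == dim(x)))
  B <- dim(x)[3L]
  pTrue <- probs[x == 1]
  recon <- -sum(log(pmax(pTrue, 1e-8))) / B
  kl <- 0.5 * sum(exp(logVar) + mu^2 - 1 - logVar) / B
  list(reconstruction = recon, kl = kl, beta = beta,
       total = recon + beta * kl)
}

#' Linearly annealed KL weight
#'
#' Rises linearly from 0 on the first epoch to 1 on the last; with fewer
#' than two epochs the weight is fixed at 1.
#'
#' @param epoch 0-based epoch index.
#' @param totalEpochs Number of training epochs.
#' @return Scalar beta in `[0, 1]`.
#' @export
klAnneal <- function(epoch, totalEpochs) {
  if (totalEpochs < 2L) return(1)
  stopifnot(epoch >= 0, epoch < totalEpochs)
  epoch / (totalEpochs - 1)
}

#' Reparameterized Gaussian sample
#'
#' Draws `z = mu + exp(logVar / 2) * eps` with `eps ~ N(0, I)`.
#'
#' @param mu,logVar Matrices (`B x latentDim`) or vectors.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return Matrix (or vector) of samples, same shape as `mu`.
#' @export
reparameterize <- function(mu, logVar, seed = NULL) {
  draw <- function() {
    eps <- stats::rnorm(length(mu))
    dim(eps) <- dim(mu)
    mu + exp(0.5 * logVar) * eps
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Encode aligned sequences to latent Gaussian parameters
#'
#' @param model A [SequenceVAE-class].
#' @param seqs Character vector of aligned rows of the model's width.
#' @param chunkSize Sequences per forward pass (memory control).
#' @return List with matrices `mu` and `logVar` (rows named by `names(seqs)`).
#' @export
encodeSequences <- function(model, seqs, chunkSize = 256L) {
  cfg <- model@config
  if (any(nchar(seqs) != cfg$L))
    stop(sprintf("sequence length must equal the model width %d", cfg$L))
  n <- length(seqs)
  mu <- matrix(NA_real_, n, cfg$latentDim)
  lv <- matrix(NA_real_, n, cfg$latentDim)
  for (start in seq(1L, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    x <- oneHotBatchArray(seqs[idx], model@alphabet)
    enc <- encoderForward(model@params, cfg, padOneHot(x, cfg))
    mu[idx, ] <- enc$mu
    lv[idx, ] <- enc$logVar
  }
  rownames(mu) <- rownames(lv) <- names(seqs)
  list(mu = mu, logVar = lv)
}

#' Decode latent vectors to per-position categorical distributions
#'
#' @param model A [SequenceVAE-class].
#' @param z Matrix `B x latentDim` (or a single latent vector).
#' @return `(L, A, B)` array of probabilities (rows of each slice sum to 1).
#' @export
decodeLatent <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  cfg <- model@config
  stopifnot(ncol(z) == cfg$latentDim)
  out <- NULL
  for (start in seq(1L, nrow(z), by = 256L)) {
    idx <- start:min(start + 255L, nrow(z))
    dec <- decoderForward(model@params, cfg, z[idx, , drop = FALSE])
    out <- if (is.null(out)) dec$probs else {
      comb <- array(0, dim = c(cfg$L, cfg$A, dim(out)[3L] + length(idx)))
      comb[, , seq_len(dim(out)[3L])] <- out
      comb[, , dim(out)[3L] + seq_along(idx)] <- dec$probs
      comb
    }
  }
  out
}

#' Turn decoder probabilities into sequences
#'
#' @param probs `(L, A, B)` array from [decodeLatent()].
#' @param alphabet Letter order.
#' @param method `"argmax"` picks the modal letter per position;
#'   `"categorical"` samples each position from its distribution (uses the
#'   current RNG state).
#' @return Character vector of `B` sequences.
#' @export
probsToSequences <- function(probs, alphabet = proteinAlphabet(),
                             method = c("argmax", "categorical")) {
  method <- match.arg(method)
  d <- dim(probs)
  M <- `dim<-`(aperm(probs, c(2L, 1L, 3L)), c(d[2L], d[1L] * d[3L]))
  if (method == "argmax") {
    pick <- max.col(t(M), ties.method = "first")
  } else {
    cum <- apply(M, 2L, cumsum)
    u <- stats::runif(ncol(M)) * cum[d[2L], ]
    pick <- colSums(cum < rep(u, each = d[2L])) + 1L
  }
  apply(matrix(alphabet[pick], d[1L], d[3L]), 2L, paste, collapse = "")
}

#' Sample sequences from the trained generative model
#'
#' Draws latent vectors and converts the decoded categorical outputs to
#' sequences. With `zSource = "prior"` latent vectors come from the
#' standard-normal prior (pure generative sampling). With
#' `zSource = "posterior"` each draw encodes a sequence picked uniformly
#' with replacement from `sourceSeqs` and samples its latent Gaussian —
#' the model's posterior-predictive distribution over the family, which is
#' what the fidelity diagnostics compare against training statistics.
#' Letters are sampled per position from the decoder's distributions by
#' default; `method = "argmax"` takes modal letters instead.
#'
#' @param model A trained [SequenceVAE-class].
#' @param n Number of sequences.
#' @param method Passed to [probsToSequences()].
#' @param zSource `"prior"` or `"posterior"`.
#' @param sourceSeqs Aligned rows to encode when `zSource = "posterior"`.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences of the model's width.
#' @export
sampleSequences <- function(model, n, method = c("categorical", "argmax"),
                            zSource = c("prior", "posterior"),
                            sourceSeqs = NULL, seed = 1L) {
  method <- match.arg(method)
  zSource <- match.arg(zSource)
  cfg <- model@config
  withSeed(seed, {
    if (zSource == "prior") {
      z <- matrix(stats::rnorm(n * cfg$latentDim), n, cfg$latentDim)
    } else {
      if (is.null(sourceSeqs))
        stop("posterior sampling requires sourceSeqs")
      pick <- sample.int(length(sourceSeqs), n, replace = TRUE)
      enc <- encodeSequences(model, sourceSeqs[pick])
      z <- enc$mu + exp(0.5 * enc$logVar) *
        matrix(stats::rnorm(n * cfg$latentDim), n, cfg$latentDim)
    }
    out <- character(n)
    for (start in seq(1L, n, by = 256L)) {
      idx <- start:min(start + 255L, n)
      dec <- decoderForward(model@params, cfg, z[idx, , drop = FALSE])
      out[idx] <- probsToSequences(dec$probs, model@alphabet, method)
    }
    out
  })
}

#' Train the sequence VAE
#'
#' Minimizes the (annealed) negative ELBO with Adam over
#' weighted-with-replacement batches. The KL weight rises linearly from 0 to
#' 1 across epochs. Per-epoch train and test loss components are recorded;
#' test loss is reported both at the epoch's annealed beta and at beta = 1.
#' Fully seed-reproducible.
#'
#' @param model An untrained (or further-trainable) [SequenceVAE-class].
#' @param aln A [FamilyAlignment-class] whose width matches the model.
#' @param split List with `train`/`test` id vectors from [splitTrainTest()].
#' @param weights Named sampling weights from [trainingWeights()].
#' @param epochs Training epochs (default 30).
#' @param batchSize Batch size (default 128).
#' @param lr Adam learning rate (default 1e-3).
#' @param anneal `TRUE` (default) anneals the KL weight linearly from 0 to
#'   1; `FALSE` fixes beta = 1 throughout; a number in `[0, 1]` fixes beta
#'   at that value.
#' @param seed Integer seed for batches, noise and shuffling.
#' @param verbose Print per-epoch losses.
#' @return The trained [SequenceVAE-class] with a populated history.
#' @export
trainVAE <- function(model, aln, split = splitTrainTest(aln),
                     weights = trainingWeights(aln), epochs = 30L,
                     batchSize = 128L, lr = 1e-3, anneal = TRUE,
                     seed = 1L, verbose = FALSE) {
  cfg <- model@config
  seqs <- alignmentSeqs(aln)
  if (alignmentWidth(aln) != cfg$L)
    stop("alignment width does not match the model")
  trainSeqs <- seqs[split$train]
  testSeqs <- seqs[split$test]
  w <- weights[split$train]
  if (any(is.na(w))) stop("weights missing for some training ids")

  xTrain <- oneHotBatchArray(unname(trainSeqs), model@alphabet)
  xTest <- oneHotBatchArray(unname(testSeqs), model@alphabet)
  nTrain <- length(trainSeqs)
  nBatch <- max(1L, ceiling(nTrain / batchSize))

  params <- model@params
  state <- adamInit(params)
  hist <- emptyHistory()

  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      beta <- if (is.numeric(anneal)) anneal
              else if (isTRUE(anneal)) klAnneal(ep - 1L, epochs) else 1
      accR <- accK <- accT <- 0
      for (bi in seq_len(nBatch)) {
        take <- sample.int(nTrain, batchSize, replace = TRUE, prob = w)
        xb <- xTrain[, , take, drop = FALSE]
        eps <- matrix(stats::rnorm(batchSize * cfg$latentDim),
                      batchSize, cfg$latentDim)
        st <- vaeStep(params, cfg, xb, eps, beta)
        if (!is.finite(st$total))
          stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                       ep, bi))
        upd <- adamStep(params, st$grads, state, lr = lr)
        params <- upd$params
        state <- upd$state
        accR <- accR + st$recon; accK <- accK + st$kl; accT <- accT + st$total
      }
      testLoss <- evalInChunks(params, cfg, xTest, beta, batchSize)
      hist <- rbind(hist, data.frame(
        epoch = ep, beta = beta,
        trainRecon = accR / nBatch, trainKL = accK / nBatch,
        trainTotal = accT / nBatch,
        testRecon = testLoss$reconstruction, testKL = testLoss$kl,
        testTotal = testLoss$total,
        testTotalBeta1 = testLoss$reconstruction + testLoss$kl))
      if (verbose)
        message(sprintf(
          "epoch %3d  beta %.3f  train %.3f (rec %.3f, kl %.3f)  test %.3f",
          ep, beta, accT / nBatch, accR / nBatch, accK / nBatch,
          testLoss$total))
    }
  })
  new("SequenceVAE", config = model@config, alphabet = model@alphabet,
      width = model@width, params = params,
      history = rbind(model@history, hist), trained = TRUE)
}

evalInChunks <- function(params, cfg, x, beta, chunk) {
  n <- dim(x)[3L]
  tot <- c(reconstruction = 0, kl = 0, total = 0)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    l <- vaeEvalLoss(params, cfg, x[, , idx, drop = FALSE], beta)
    wgt <- length(idx)
    tot <- tot + wgt * c(l$reconstruction, l$kl, l$total)
  }
  as.list(tot / n)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding a format version, the
#' architecture configuration, the alphabet, the alignment width, all
#' parameters and the training history, so reloaded models reproduce
#' encodings exactly.
#'
#' @param model A [SequenceVAE-class].
#' @param path File path.
#' @return `saveVAE`: `path` invisibly. `loadVAE`: the restored model.
#' @export
saveVAE <- function(model, path) {
  saveRDS(list(format = "FamilyVAE-checkpoint-1",
               config = model@config, alphabet = model@alphabet,
               width = model@width, params = model@params,
               history = model@history, trained = model@trained),
          path)
  invisible(path)
}

#' @rdname saveVAE
#' @export
loadVAE <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "FamilyVAE-checkpoint-1"))
    stop("not a FamilyVAE checkpoint")
  new("SequenceVAE", config = ck$config, alphabet = ck$alphabet,
      width = ck$width, params = ck$params, history = ck$history,
      trained = ck$trained)
}
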