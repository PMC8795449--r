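ns <- asNamespace("FamilyVAE")

test_that("model construction is seed-reproducible and shape-correct", {
  cfg <- vaeConfig(322, latentDim = 64)
  expect_equal(cfg$Lpad, 328L)   # next multiple of 8
  expect_error(vaeConfig(0), "width")

  cfgSmall <- vaeConfig(16, latentDim = 4,
                        encoderFilters = c(6, 5, 4),
                        decoderFilters = c(4, 5, 6))
  m1 <- buildVAE(cfgSmall, seed = 7)
  m2 <- buildVAE(cfgSmall, seed = 7)
  expect_identical(m1@params, m2@params)
  m3 <- buildVAE(cfgSmall, seed = 8)
  expect_false(identical(m1@params, m3@params))

  # decoder output is a categorical distribution at every position
  z <- matrix(rnorm(3 * 4), 3, 4)
  probs <- decodeLatent(m1, z)
  expect_equal(dim(probs), c(16L, 21L, 3L))
  expect_true(all(probs >= 0))
  expect_equal(apply(probs, c(1, 3), sum),
               matrix(1, 16, 3), tolerance = 1e-6)
})

test_that("encoding is deterministic and injective on distinct inputs", {
  tm <- tinyTrainedModel()
  tgt <- targetSequence(tm$aln)
  e1 <- encodeSequences(tm$model, c(tgt, tgt))
  expect_equal(e1$mu[1, ], e1$mu[2, ])   # identical inputs, identical codes
  e2 <- encodeSequences(tm$model, tgt)
  expect_equal(e1$mu[1, ], drop(e2$mu))  # deterministic across calls
  expect_true(all(is.finite(e1$mu)), all(is.finite(e1$logVar)))

  # perturbing residues moves a trained model's encoding
  mutant <- paste0("CC", substr(tgt, 3, nchar(tgt)))
  e3 <- encodeSequences(tm$model, mutant)
  expect_gt(latentDistance(drop(e2$mu), drop(e3$mu)), 0)
  expect_error(encodeSequences(tm$model, "AC"), "width")
})

test_that("reparameterized samples have the prescribed moments", {
  mu <- c(0.5, -1, 2)
  logVar <- c(0, log(4), log(0.25))
  # degenerate variance collapses to the mean
  expect_equal(reparameterize(mu, -1e10, seed = 1), mu)
  z <- withr::with_seed(2, {
    sapply(1:3, function(j)
      reparameterize(rep(mu[j], 1e5), rep(logVar[j], 1e5)))
  })
  sdTrue <- exp(0.5 * logVar)
  for (j in 1:3) {
    expect_lt(abs(mean(z[, j]) - mu[j]), 4 * sdTrue[j] / sqrt(1e5))
    # sample variance concentrates around exp(logVar)
    seVar <- sdTrue[j]^2 * sqrt(2 / (1e5 - 1))
    expect_lt(abs(var(z[, j]) - sdTrue[j]^2), 4 * seVar)
  }
})

test_that("ELBO components match closed forms and decompose exactly", {
  # perfect one-hot predictions give zero reconstruction loss
  x <- array(0, dim = c(4, 21, 2))
  x[cbind(rep(1:4, 2), c(1, 5, 9, 2, 3, 3, 3, 21), rep(1:2, each = 4))] <- 1
  mu0 <- matrix(0, 2, 64)
  l <- elboLoss(x, x, mu0, mu0, beta = 1)
  expect_equal(l$reconstruction, 0)
  expect_equal(l$kl, 0)          # posterior equals the prior
  expect_equal(l$total, 0)

  # mu = 1 in all 64 dims, logVar = 0: KL = 0.5 * 64 = 32 nats
  l2 <- elboLoss(x, x, mu0 + 1, mu0, beta = 0.5)
  expect_equal(l2$kl, 32)
  expect_equal(l2$total, l2$reconstruction + 0.5 * l2$kl)
  expect_error(elboLoss(x, x, mu0, mu0, beta = 1.5), "beta")

  # closed-form Gaussian KL agrees with a Monte-Carlo estimate within 3 SE
  withr::with_seed(11, {
    d <- 5
    mu <- rnorm(d)
    logVar <- rnorm(d, sd = 0.5)
    nmc <- 1e5
    eps <- matrix(rnorm(nmc * d), nmc, d)
    zs <- sweep(sweep(eps, 2, exp(0.5 * logVar), "*"), 2, mu, "+")
    logq <- sapply(1:d, function(j)
      dnorm(zs[, j], mu[j], exp(0.5 * logVar[j]), log = TRUE))
    logp <- dnorm(zs, log = TRUE)
    samples <- rowSums(logq) - rowSums(logp)
    klMC <- mean(samples)
    klSE <- sd(samples) / sqrt(nmc)
    klClosed <- 0.5 * sum(exp(logVar) + mu^2 - 1 - logVar)
    expect_lt(abs(klMC - klClosed), 3 * klSE)
  })
})

test_that("KL annealing rises linearly from 0 to 1 across epochs", {
  expect_equal(klAnneal(0, 30), 0)
  expect_equal(klAnneal(29, 30), 1)
  # linear symmetry about the midpoint
  for (k in 0:14) expect_equal(klAnneal(k, 30) + klAnneal(29 - k, 30), 1)
  expect_equal(klAnneal(0, 1), 1)   # degenerate schedule pins beta at 1
  expect_error(klAnneal(30, 30))
})

test_that("analytic gradients agree with finite differences", {
  # width 8 avoids padding so pooling ties from duplicated gap columns
  # cannot blur max-pool subgradients
  cfg <- vaeConfig(8, latentDim = 3, encoderFilters = c(4, 3, 3),
                   decoderFilters = c(3, 3, 4))
  model <- buildVAE(cfg, seed = 2)
  params <- model@params
  withr::with_seed(5, {
    for (nm in names(params))
      params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = 1e-2)
    seqs <- replicate(2, paste(sample(proteinAlphabet()[1:20], 8, TRUE),
                               collapse = ""))
    x <- ns$oneHotBatchArray(seqs)
    eps <- matrix(rnorm(2 * 3), 2, 3)
    st <- ns$vaeStep(params, unclass(cfg), x, eps, beta = 0.7)
    expect_equal(st$total, st$recon + 0.7 * st$kl)
    h <- 1e-5
    for (nm in c("enc1.W", "enc2.W", "encMu.W", "encLv.b", "decFc.W",
                 "dec2.W", "decOut.W")) {
      idx <- sample(length(st$grads[[nm]]), 3)
      for (i in idx) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
        fd <- (ns$vaeStep(p1, unclass(cfg), x, eps, 0.7)$total -
               ns$vaeStep(p2, unclass(cfg), x, eps, 0.7)$total) / (2 * h)
        g <- st$grads[[nm]][i]
        expect_lt(abs(fd - g) / max(1e-6, abs(fd) + abs(g)), 1e-4)
      }
    }
  })
})

test_that("training reduces loss and checkpoints round-trip exactly", {
  tm <- tinyTrainedModel()
  hist <- tm$model@history
  expect_true(tm$model@trained)
  expect_equal(nrow(hist), 8L)
  expect_lt(tail(hist$trainRecon, 1), hist$trainRecon[1])
  expect_equal(hist$beta, seq(0, 1, length.out = 8))

  path <- tempfile(fileext = ".rds")
  saveVAE(tm$model, path)
  back <- loadVAE(path)
  expect_identical(back@params, tm$model@params)
  tgt <- targetSequence(tm$aln)
  expect_identical(encodeSequences(back, tgt),
                   encodeSequences(tm$model, tgt))
})

test_that("an unconstrained (beta = 0) run reconstructs at least as well", {
  # beta = 0 throughout optimizes reconstruction unconstrained, so after the
  # same number of epochs its train reconstruction is no worse than the
  # annealed run's
  tm <- tinyTrainedModel()
  m0 <- buildVAE(vaeConfig(32, latentDim = 8,
                           encoderFilters = c(12, 10, 8),
                           decoderFilters = c(8, 10, 12)), seed = 1)
  sp <- splitTrainTest(tm$aln, seed = 2)
  w <- trainingWeights(tm$aln)
  mFree <- trainVAE(m0, tm$aln, sp, w, epochs = 8, batchSize = 64,
                    seed = 3, anneal = 0)
  expect_lte(tail(mFree@history$trainRecon, 1),
             tail(tm$model@history$trainRecon, 1))
})
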