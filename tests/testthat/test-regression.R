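test_that("the design matrix codes mutations and the library covariate", {
  X <- buildDesign(c("v1", "v2", "v3"),
                   list(c("A5T", "K7R"), "A5T", character(0)),
                   c("vae", "vae", "consensus"))
  expect_equal(dim(X), c(3L, 3L))
  expect_equal(colnames(X), c("A5T", "K7R", "library"))
  expect_equal(unname(X[, "A5T"]), c(1, 1, 0))   # shared mutation: two 1s
  expect_equal(unname(X[, "library"]), c(0, 0, 1))
  expect_equal(unname(X["v3", ]), c(0, 0, 1))    # target-like: zero mutations
  expect_true(all(X %in% c(0, 1)))
  expect_error(buildDesign(c("a", "a"), list("A1C", "A1C"), c("vae", "vae")),
               "duplicate")
  # comma-joined input and deletion names are accepted
  X2 <- buildDesign(c("v1", "v2"), c("ΔK7,A5T", ""), c("vae", "consensus"))
  expect_true(all(c("A5T", "ΔK7") %in% colnames(X2)))
})

test_that("standardization averages replicates then z-scores with n-1 sd", {
  z <- standardizeResponses(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_error(standardizeResponses(c(2, 2, 2)), "zero variance")
  # idempotence
  expect_equal(as.numeric(standardizeResponses(as.numeric(z))),
               as.numeric(z))
  # replicate averaging happens before scaling
  reps <- rbind(v1 = c(0.9, 1.1, 1.0), v2 = c(2.1, 1.9, 2.0),
                v3 = c(3.0, 3.0, 3.0))
  expect_equal(as.numeric(standardizeResponses(reps)), c(-1, 0, 1))
  expect_equal(mean(standardizeResponses(reps)), 0, tolerance = 1e-10)
  expect_equal(sd(standardizeResponses(reps)), 1, tolerance = 1e-10)
  # rows with no finite data are dropped and flagged
  reps2 <- rbind(v1 = c(1, NA, NA), v2 = c(NA, NA, NA), v3 = c(3, 3, 3))
  z2 <- standardizeResponses(reps2)
  expect_equal(attr(z2, "kept"), c(v1 = TRUE, v2 = FALSE, v3 = TRUE))
})

test_that("ridge at lambda 0 matches ordinary least squares", {
  withr::with_seed(61, {
    n <- 20; p <- 3
    X <- matrix(rbinom(n * p, 1, 0.4), n, p,
                dimnames = list(NULL, c("A1C", "D2E", "library")))
    z <- rnorm(n)
    fit <- ridgeFit(X, z, lambda = 0)
    ols <- lm(z ~ X)
    expect_equal(unname(fit@coefficients), unname(coef(ols)[-1]),
                 tolerance = 1e-8)
    expect_equal(fit@intercept, unname(coef(ols)[1]), tolerance = 1e-8)
    expect_equal(fit@residuals, unname(residuals(ols)), tolerance = 1e-8)
  })
})

test_that("ridge shrinkage is monotone and the optimum is stationary", {
  withr::with_seed(62, {
    n <- 40; p <- 6
    X <- matrix(rbinom(n * p, 1, 0.3), n, p,
                dimnames = list(NULL, c(paste0("A", 1:5, "C"), "library")))
    z <- rnorm(n)
    lambdas <- c(0.01, 0.1, 1, 10, 100, 1e6)
    norms <- vapply(lambdas, function(l)
      sqrt(sum(ridgeFit(X, z, l)@coefficients^2)), numeric(1))
    expect_true(all(diff(norms) <= 1e-12))
    # enormous penalty crushes the coefficients
    expect_lt(norms[6], 1e-3 * sqrt(sum(ridgeFit(X, z, 1e-8)@coefficients^2)))
    # zero response gives exactly zero coefficients
    expect_equal(unname(ridgeFit(X, rep(0, n), 1)@coefficients), rep(0, p))
    # gradient of the penalized objective vanishes at the solution
    fit <- ridgeFit(X, z, lambda = 2.5)
    Xc <- sweep(X, 2, colMeans(X))
    zc <- z - mean(z)
    grad <- -2 * crossprod(Xc, zc - Xc %*% fit@coefficients) +
      2 * 2.5 * fit@coefficients
    expect_lt(max(abs(grad)), 1e-8)
  })
  # collinear design at lambda 0 errors with advice
  Xbad <- cbind(A1C = c(1, 1, 0, 0), D2E = c(1, 1, 0, 0),
                library = c(0, 0, 1, 1))
  expect_error(ridgeFit(Xbad, rnorm(4), 0), "lambda > 0")
})

test_that("closed-form LOO-CV equals brute-force refitting", {
  withr::with_seed(63, {
    n <- 15; p <- 4
    X <- matrix(rbinom(n * p, 1, 0.5), n, p,
                dimnames = list(NULL, c(paste0("K", 1:3, "R"), "library")))
    z <- rnorm(n)
    lambdas <- c(0.5, 5)
    cv <- ridgeLOOCV(X, z, lambdas)
    brute <- vapply(lambdas, function(lam) {
      mean(vapply(seq_len(n), function(i) {
        fit <- ridgeFit(X[-i, ], z[-i], lam)
        pred <- sum(X[i, ] * fit@coefficients) + fit@intercept
        (z[i] - pred)^2
      }, numeric(1)))
    }, numeric(1))
    expect_equal(cv$cvError, brute, tolerance = 1e-8)
  })
})

test_that("quadrant assignment follows coefficient signs", {
  mk <- function(beta) new("RegressionResult",
                           coefficients = beta, intercept = 0, lambda = 1,
                           fitted = numeric(2), residuals = numeric(2),
                           response = "x",
                           design = matrix(0, 2, length(beta)))
  beta1 <- c(A1C = 0.5, D2E = -0.3, K3R = 0.2, ΔL4 = 0, library = 1)
  beta2 <- c(A1C = 0.4, D2E = 0.2, K3R = -0.1, ΔL4 = 0, library = -1)
  q <- coefficientQuadrants(mk(beta1), mk(beta2))
  expect_false("library" %in% q$mutation)
  expect_equal(q$quadrant[q$mutation == "A1C"], "++")
  expect_equal(q$quadrant[q$mutation == "D2E"], "-+")
  expect_equal(q$quadrant[q$mutation == "K3R"], "+-")
  expect_equal(q$quadrant[q$mutation == "ΔL4"], "neutral")
  # sorted by magnitude, largest first
  expect_equal(q$mutation[1], "A1C")
  # flipping one response's signs flips that axis of the quadrant
  q2 <- coefficientQuadrants(mk(beta1), mk(-beta2))
  expect_equal(q2$quadrant[q2$mutation == "A1C"], "+-")
  expect_error(coefficientQuadrants(mk(beta1), mk(beta1[-1])),
               "mismatched")
})

test_that("the full attribution pipeline recovers planted effects exactly without noise", {
  lib <- simulateMutationLibrary(paste0("A", 1:10, "C"), nVae = 30,
                                 nConsensus = 30, seed = 3)
  beta <- setNames(seq(-0.9, 0.9, length.out = 10), paste0("A", 1:10, "C"))
  pcfg <- phenotypeConfig(beta, -beta, noiseSd = c(activity = 0, tm = 0),
                          libraryEffect = c(activity = 0.5, tm = 0),
                          seed = 4)
  ph <- generatePhenotypes(lib$variant_id, lib$mutations, lib$library, pcfg)
  res <- mutationEffectRegression(
    lib$variant_id, lib$mutations, lib$library,
    activity = as.matrix(ph[, grep("activity", names(ph))]),
    tm = as.matrix(ph[, grep("tm_", names(ph))]),
    lambda = 1e-8)
  # noiseless: standardized coefficients proportional to planted effects
  got <- res$activity@coefficients[names(beta)]
  expect_equal(unname(got / got[10]), unname(beta / beta[10]),
               tolerance = 1e-6)
  # activity and tm were planted with opposite signs
  expect_equal(sign(unname(res$tm@coefficients[names(beta)])),
               -sign(unname(got)))
  expect_equal(res$n, 60L)
})
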