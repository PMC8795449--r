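#' Binary mutation design matrix with a library covariate
#'
#' One column per distinct mutation observed in at least one variant
#' (substitutions `XnY` and deletions `ΔXn`, all in 1-based target
#' coordinates), plus a single `library` column that is 0 for the generative
#' (VAE) library and 1 for the consensus library. Rows are variants; the
#' unmutated target itself maps to an all-zero mutation row.
#'
#' @param variantIds Unique variant identifiers.
#' @param mutationLists List (parallel to `variantIds`) of character vectors
#'   of mutation names; or a character vector of comma-joined names.
#' @param libraryLabels Factor/character parallel to `variantIds`; values
#'   `"vae"` (coded 0) or `"consensus"` (coded 1).
#' @return `n x p` binary matrix with rownames = variant ids and the
#'   `library` column last.
#' @export
buildDesign <- function(variantIds, mutationLists, libraryLabels) {
  n <- length(variantIds)
  if (anyDuplicated(variantIds)) stop("duplicate variant ids")
  if (is.character(mutationLists))
    mutationLists <- strsplit(mutationLists, ",", fixed = TRUE)
  mutationLists <- lapply(mutationLists, function(m) m[nzchar(m)])
  stopifnot(length(mutationLists) == n, length(libraryLabels) == n)
  lib <- match(as.character(libraryLabels), c("vae", "consensus")) - 1L
  if (anyNA(lib)) stop("library labels must be 'vae' or 'consensus'")
  mutations <- unique(unlist(mutationLists, use.names = FALSE))
  mutations <- mutations[order(mutationPosition(mutations), mutations)]
  X <- matrix(0, n, length(mutations) + 1L,
              dimnames = list(variantIds, c(mutations, "library")))
  for (i in seq_len(n))
    X[i, mutationLists[[i]]] <- 1
  X[, "library"] <- lib
  X
}

mutationPosition <- function(names) {
  as.integer(sub("^Δ?[A-Z](\\d+).*$", "\\1", names))
}

#' Average replicates and standardize responses to z-scores
#'
#' Replicate measurements are averaged per variant, then standardized as
#' `z = (y - mean(y)) / sd(y)` over the included variants, using the sample
#' (n-1) standard deviation. Variants with any missing replicate average
#' over the observed replicates; variants with no observed replicate are
#' dropped (reported in the `kept` attribute).
#'
#' @param responses Numeric matrix or data.frame (variants x replicates), or
#'   a numeric vector of already-averaged responses.
#' @return Numeric vector of z-scores, named like the input rows, with
#'   attribute `kept` (logical: rows retained).
#' @export
standardizeResponses <- function(responses) {
  y <- if (is.null(dim(responses))) as.numeric(responses)
       else rowMeans(as.matrix(responses), na.rm = TRUE)
  names(y) <- if (is.null(dim(responses))) names(responses)
              else rownames(responses)
  kept <- is.finite(y)
  y <- y[kept]
  if (length(y) < 2L) stop("need at least two observed responses")
  s <- stats::sd(y)
  if (s == 0) stop("responses have zero variance; cannot standardize")
  z <- (y - mean(y)) / s
  attr(z, "kept") <- kept
  z
}

#' Ridge regression with an unpenalized intercept
#'
#' Minimizes `||z - b0 - X beta||^2 + lambda * ||beta||^2` by the
#' closed-form normal equations on centered data:
#' `beta = (Xc' Xc + lambda I)^-1 Xc' zc`, with the intercept recovered from
#' the means. `lambda = 0` is ordinary least squares and errors on singular
#' designs.
#'
#' @param X Design matrix (`n x p`) from [buildDesign()].
#' @param z Standardized response vector of length `n`.
#' @param lambda Nonnegative ridge penalty (default 1).
#' @param response Label stored with the result.
#' @return A [RegressionResult-class].
#' @export
ridgeFit <- function(X, z, lambda = 1, response = "response") {
  stopifnot(is.matrix(X), nrow(X) == length(z), lambda >= 0, nrow(X) >= 2L)
  xBar <- colMeans(X)
  zBar <- mean(z)
  Xc <- sweep(X, 2L, xBar)
  zc <- z - zBar
  G <- crossprod(Xc) + diag(lambda, ncol(X))
  beta <- tryCatch(drop(solve(G, crossprod(Xc, zc))),
                   error = function(e)
                     stop(paste0("singular system; with lambda = 0 and a ",
                                 "collinear design, use lambda > 0"),
                          call. = FALSE))
  names(beta) <- colnames(X)
  intercept <- zBar - sum(xBar * beta)
  fitted <- drop(X %*% beta) + intercept
  new("RegressionResult", coefficients = beta, intercept = intercept,
      lambda = lambda, fitted = fitted, residuals = z - fitted,
      response = response, design = X)
}

#' Leave-one-out cross-validation over a lambda grid
#'
#' Uses the closed-form LOO residual `e_i / (1 - h_ii)` of the ridge
#' smoother (intercept plus penalized centered design), so no refitting per
#' observation is needed.
#'
#' @param X Design matrix.
#' @param z Response vector.
#' @param lambdas Candidate penalties (default a log grid 1e-3..1e3).
#' @return List with `lambda` (the minimizer), `cvError` (mean squared LOO
#'   residual per candidate) and `lambdas`.
#' @export
ridgeLOOCV <- function(X, z, lambdas = 10^seq(-3, 3, length.out = 25)) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  zc <- z - mean(z)
  sv <- svd(Xc)
  # hat diagonal: 1/n (intercept) + sum_k d_k^2/(d_k^2+lambda) u_ik^2
  U2 <- sv$u^2
  d2 <- sv$d^2
  cvError <- vapply(lambdas, function(lam) {
    shrink <- d2 / (d2 + lam)
    h <- 1 / n + drop(U2 %*% shrink)
    fit <- drop(sv$u %*% (shrink * crossprod(sv$u, zc)))
    e <- (zc - fit) / (1 - h)
    mean(e^2)
  }, numeric(1L))
  list(lambda = lambdas[which.min(cvError)], cvError = cvError,
       lambdas = lambdas)
}

#' Coefficient quadrants across two responses
#'
#' Classifies each mutation by the signs of its activity and melting-
#' temperature coefficients: `++` improves both, `+-`/`-+` trade off, `--`
#' harms both; exact zeros are `neutral`. Sorted by Euclidean coefficient
#' magnitude, largest first. The `library` covariate is excluded.
#'
#' @param resultActivity,resultTm [RegressionResult-class] objects fitted on
#'   the same design.
#' @return `data.frame` with columns mutation, betaActivity, betaTm,
#'   quadrant.
#' @export
coefficientQuadrants <- function(resultActivity, resultTm) {
  a <- resultActivity@coefficients
  b <- resultTm@coefficients
  if (!identical(names(a), names(b)))
    stop("the two results have mismatched predictors")
  keep <- names(a) != "library"
  a <- a[keep]; b <- b[keep]
  quad <- ifelse(a == 0 | b == 0, "neutral",
          ifelse(a > 0 & b > 0, "++",
          ifelse(a > 0 & b < 0, "+-",
          ifelse(a < 0 & b > 0, "-+", "--"))))
  out <- data.frame(mutation = names(a), betaActivity = unname(a),
                    betaTm = unname(b), quadrant = unname(quad),
                    stringsAsFactors = FALSE)
  out[order(-sqrt(out$betaActivity^2 + out$betaTm^2)), , drop = FALSE]
}

#' Full mutation-effect attribution for two responses
#'
#' Builds the design, standardizes both responses, fits ridge models
#' (optionally at a LOO-CV-chosen penalty), and tabulates quadrants.
#'
#' @param variantIds,mutationLists,libraryLabels See [buildDesign()].
#' @param activity,tm Replicate matrices (variants x replicates) or vectors,
#'   rows parallel to `variantIds`.
#' @param lambda Penalty, or `"loocv"` to select by cross-validation.
#' @return List with `activity` and `tm` [RegressionResult-class]s,
#'   `quadrants`, `lambda` used per response, and `n` (rows fitted).
#' @export
mutationEffectRegression <- function(variantIds, mutationLists,
                                     libraryLabels, activity, tm,
                                     lambda = 1) {
  X <- buildDesign(variantIds, mutationLists, libraryLabels)
  fitOne <- function(resp, label) {
    z <- standardizeResponses(resp)
    Xz <- X[attr(z, "kept"), , drop = FALSE]
    lam <- if (identical(lambda, "loocv")) ridgeLOOCV(Xz, z)$lambda
           else lambda
    ridgeFit(Xz, z, lambda = lam, response = label)
  }
  fa <- fitOne(activity, "activity")
  ft <- fitOne(tm, "tm")
  list(activity = fa, tm = ft,
       quadrants = coefficientQuadrants(fa, ft),
       lambda = c(activity = fa@lambda, tm = ft@lambda),
       n = length(fa@fitted))
}
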