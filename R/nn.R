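# Internal neural-network primitives for the sequence VAE.
#
# Activations are 4-d arrays with dimensions (length, alphabet, batch,
# channels). The heavy layers (3x3 same-padding convolution via im2col +
# GEMM, ELU, 2x length max-pool / nearest-neighbour upsample) live in
# compiled code (src/layers.cpp); this file holds initialization, the dense
# heads, softmax and the Adam optimizer. All randomness flows through the
# caller's RNG state.

convInit <- function(cIn, cOut) {
  # Kaiming-normal: sd = sqrt(2 / fan_in), fan_in = 3*3*cIn
  list(W = array(stats::rnorm(9 * cIn * cOut, sd = sqrt(2 / (9 * cIn))),
                 dim = c(3, 3, cIn, cOut)),
       b = numeric(cOut))
}

denseInit <- function(dIn, dOut) {
  list(W = matrix(stats::rnorm(dIn * dOut, sd = sqrt(2 / dIn)), dIn, dOut),
       b = numeric(dOut))
}

convForward <- function(X, W, b) {
  d <- dim(X)
  c(.cppConvForward(X, W, b, as.integer(d), dim(W)[4L]), list(dims = d))
}

convBackward <- function(dY, cache, W) {
  .cppConvBackward(cache$col, W, dY, as.integer(cache$dims), dim(W)[4L])
}

eluForward <- function(X) {
  list(out = .cppElu(X))
}

eluBackward <- function(dY, cache) {
  .cppEluBackward(dY, cache$out)
}

poolForward <- function(X) {
  d <- dim(X)
  c(.cppPoolForward(X, as.integer(d)), list(dims = d))
}

poolBackward <- function(dY, cache) {
  .cppPoolBackward(dY, cache$top, as.integer(cache$dims))
}

upsampleForward <- function(X) {
  .cppUpsampleForward(X, as.integer(dim(X)))
}

upsampleBackward <- function(dY) {
  .cppUpsampleBackward(dY, as.integer(dim(dY)))
}

denseForward <- function(X, W, b) {
  sweep(X %*% W, 2L, b, "+")
}

denseBackward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# (H, A, B, C) feature map -> (B, H*A*C) matrix, and its inverse.
flattenMap <- function(X) {
  d <- dim(X)
  t(`dim<-`(aperm(X, c(1L, 2L, 4L, 3L)), c(d[1L] * d[2L] * d[4L], d[3L])))
}

unflattenMap <- function(M, H, A, C) {
  B <- nrow(M)
  aperm(`dim<-`(t(M), c(H, A, C, B)), c(1L, 2L, 4L, 3L))
}

# Softmax over the alphabet dimension of a (L, A, B) logits array.
softmaxAlphabet <- function(logits) {
  d <- dim(logits)
  M <- `dim<-`(aperm(logits, c(2L, 1L, 3L)), c(d[2L], d[1L] * d[3L]))
  mx <- M[1L, ]
  for (a in seq_len(d[2L])[-1L]) mx <- pmax(mx, M[a, ])
  E <- exp(M - rep(mx, each = d[2L]))
  P <- E / rep(colSums(E), each = d[2L])
  aperm(`dim<-`(P, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
}

adamInit <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
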