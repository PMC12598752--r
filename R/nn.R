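# Internal network machinery for the pair classifier.
#
# Architecture: a length-preserving 1-D convolution (F filters, odd kernel)
# over each protein's assembled input row, ReLU, then a residual step that
# re-adds the raw input row to every filter channel. Pair features are the
# elementwise absolute differences of the two proteins' feature maps and of
# their raw input rows; the F feature channels and the one input channel
# are concatenated, flattened, and passed through three fully connected
# layers ending in a logistic unit. Convolution cost scales with the number
# of proteins, not pairs: each protein row is convolved once and reused by
# every pair it participates in.

# column-shift with zero fill: result[, t] = M[, t + o]
shift_cols <- function(M, o) {
  Tn <- ncol(M)
  out <- matrix(0, nrow(M), Tn)
  if (o >= 0) {
    if (o < Tn) out[, seq_len(Tn - o)] <- M[, (1 + o):Tn, drop = FALSE]
  } else {
    if (-o < Tn) out[, (1 - o):Tn] <- M[, seq_len(Tn + o), drop = FALSE]
  }
  out
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init <- function(cfg, input_len, n_proteins, use_embedding, seq_len = 256L) {
  set.seed(cfg$seed)
  K <- cfg$kernel_width; F_ <- cfg$n_filters
  fc <- cfg$fc_sizes
  d0 <- input_len * (F_ + 1L)
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  params <- list(
    Wc = glorot(K, F_), bc = numeric(F_),
    W1 = glorot(d0, fc[1]), b1 = numeric(fc[1]),
    W2 = glorot(fc[1], fc[2]), b2 = numeric(fc[2]),
    W3 = glorot(fc[2], 1L), b3 = numeric(1L)
  )
  if (use_embedding)
    params$C <- matrix(stats::runif(n_proteins * seq_len, -0.01, 0.01),
                       n_proteins, seq_len)
  params
}

# Convolutional feature maps for all protein rows: one convolution pass
# per protein, reusable across any number of pairs.
nn_feature_maps <- function(params, X) {
  N <- nrow(X); Tn <- ncol(X)
  K <- nrow(params$Wc); F_ <- ncol(params$Wc)
  ctr <- (K + 1L) %/% 2L
  Xsh <- lapply(seq_len(K), function(k) shift_cols(X, k - ctr))
  P <- vector("list", F_)   # pre-activation per filter
  H <- vector("list", F_)   # post-residual feature map per filter
  for (f in seq_len(F_)) {
    Pf <- matrix(params$bc[f], N, Tn)
    for (k in seq_len(K)) Pf <- Pf + params$Wc[k, f] * Xsh[[k]]
    P[[f]] <- Pf
    H[[f]] <- relu(Pf) + X
  }
  list(Xsh = Xsh, P = P, H = H, n_conv = N)
}

# Forward pass. X: N x T assembled input; pairs: np x 2 index matrix.
# Returns scores plus the cache needed for backprop. n_conv records how
# many rows were convolved (one per protein, independent of pair count);
# pass a precomputed `fmaps` to skip the convolution entirely.
nn_forward <- function(params, X, pairs, training = FALSE,
                       dropout_rate = 0, keep_cache = TRUE, fmaps = NULL) {
  N <- nrow(X); Tn <- ncol(X)
  F_ <- ncol(params$Wc)
  np <- nrow(pairs)
  if (any(pairs < 1 | pairs > N)) stop("pair index out of range")

  conv_done <- is.null(fmaps)
  if (is.null(fmaps)) fmaps <- nn_feature_maps(params, X)
  P <- fmaps$P; H <- fmaps$H; Xsh <- fmaps$Xsh

  ii <- pairs[, 1]; jj <- pairs[, 2]
  Z <- matrix(0, np, Tn * (F_ + 1L))
  Sgn <- if (keep_cache) vector("list", F_ + 1L)
  for (f in seq_len(F_)) {
    Df <- H[[f]][ii, , drop = FALSE] - H[[f]][jj, , drop = FALSE]
    if (keep_cache) Sgn[[f]] <- sign(Df)
    Z[, ((f - 1L) * Tn + 1L):(f * Tn)] <- abs(Df)
  }
  Din <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
  if (keep_cache) Sgn[[F_ + 1L]] <- sign(Din)
  Z[, (F_ * Tn + 1L):((F_ + 1L) * Tn)] <- abs(Din)

  drop_mask <- list(m1 = NULL, m2 = NULL)
  U1 <- sweep(Z %*% params$W1, 2, params$b1, "+")
  A1 <- relu(U1)
  if (training && dropout_rate > 0) {
    drop_mask$m1 <- matrix(stats::runif(length(A1)) >= dropout_rate,
                           nrow(A1), ncol(A1))
    A1 <- A1 * drop_mask$m1 / (1 - dropout_rate)
  }
  U2 <- sweep(A1 %*% params$W2, 2, params$b2, "+")
  A2 <- relu(U2)
  if (training && dropout_rate > 0) {
    drop_mask$m2 <- matrix(stats::runif(length(A2)) >= dropout_rate,
                           nrow(A2), ncol(A2))
    A2 <- A2 * drop_mask$m2 / (1 - dropout_rate)
  }
  U3 <- drop(A2 %*% params$W3) + params$b3
  scores <- sigmoid(U3)
  out <- list(scores = scores, n_conv = if (conv_done) fmaps$n_conv else 0L)
  if (keep_cache)
    out$cache <- list(X = X, Xsh = Xsh, P = P, H = H, Z = Z, Sgn = Sgn,
                      U1 = U1, A1 = A1, U2 = U2, A2 = A2, U3 = U3,
                      pairs = pairs, drop_mask = drop_mask,
                      dropout_rate = if (training) dropout_rate else 0)
  out
}

# Backward pass from an upstream gradient on the logit U3.
# Returns parameter gradients and, when requested, the gradient with
# respect to the input rows X (through both the convolutional feature path
# and the direct input-difference path).
nn_backward <- function(params, fwd, dU3, need_input_grad = FALSE,
                        need_param_grads = TRUE) {
  cache <- fwd$cache
  X <- cache$X; Tn <- ncol(X); N <- nrow(X)
  K <- nrow(params$Wc); F_ <- ncol(params$Wc)
  ctr <- (K + 1L) %/% 2L
  pairs <- cache$pairs
  ii <- pairs[, 1]; jj <- pairs[, 2]
  dr <- cache$dropout_rate

  dA2 <- matrix(dU3, ncol = 1) %*% t(params$W3)
  if (!is.null(cache$drop_mask$m2))
    dA2 <- dA2 * cache$drop_mask$m2 / (1 - dr)
  dU2 <- dA2 * (cache$U2 > 0)
  dA1 <- dU2 %*% t(params$W2)
  if (!is.null(cache$drop_mask$m1))
    dA1 <- dA1 * cache$drop_mask$m1 / (1 - dr)
  dU1 <- dA1 * (cache$U1 > 0)
  dZ <- dU1 %*% t(params$W1)

  grads <- NULL
  if (need_param_grads) {
    grads <- list(
      W3 = crossprod(cache$A2, matrix(dU3, ncol = 1)), b3 = sum(dU3),
      W2 = crossprod(cache$A1, dU2), b2 = colSums(dU2),
      W1 = crossprod(cache$Z, dU1), b1 = colSums(dU1)
    )
  }

  # scatter pair-level gradients back to protein-level feature maps
  dX <- matrix(0, N, Tn)
  dWc <- matrix(0, K, F_); dbc <- numeric(F_)
  group <- c(ii, jj)
  for (f in seq_len(F_)) {
    dDf <- dZ[, ((f - 1L) * Tn + 1L):(f * Tn), drop = FALSE] * cache$Sgn[[f]]
    agg <- rowsum(rbind(dDf, -dDf), group = group)
    dHf <- matrix(0, N, Tn)
    rows <- as.integer(rownames(agg))
    dHf[rows, ] <- agg
    # residual: raw input was added to every channel
    dX <- dX + dHf
    dPf <- dHf * (cache$P[[f]] > 0)
    if (need_param_grads) {
      for (k in seq_len(K)) dWc[k, f] <- sum(cache$Xsh[[k]] * dPf)
      dbc[f] <- sum(dPf)
    }
    if (need_input_grad || need_param_grads) {
      for (k in seq_len(K))
        dX <- dX + params$Wc[k, f] * shift_cols(dPf, -(k - ctr))
    }
  }
  # direct input-difference channel
  dDin <- dZ[, (F_ * Tn + 1L):((F_ + 1L) * Tn), drop = FALSE] *
    cache$Sgn[[F_ + 1L]]
  agg <- rowsum(rbind(dDin, -dDin), group = group)
  rows <- as.integer(rownames(agg))
  dX[rows, ] <- dX[rows, ] + agg

  if (need_param_grads) { grads$Wc <- dWc; grads$bc <- dbc }
  list(grads = grads, dX = dX)
}

# One Adam step; state carries first/second moments and the step counter.
adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  decayed <- c("Wc", "W1", "W2", "W3")
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm %in% decayed && wd > 0) g <- g + wd * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

bce_loss <- function(scores, y) {
  eps <- 1e-12
  -mean(y * log(scores + eps) + (1 - y) * log(1 - scores + eps))
}
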