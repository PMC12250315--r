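## Convolutional LSTM reference network.
##
## Topology: two 1-D convolution blocks over the time axis of the
## feature sequence (kernel 3, same padding, ReLU), a single LSTM layer,
## dropout on the final hidden state, and a sigmoid head. Forward and
## backward passes are written directly in (vectorized) base R: batches
## are matrices, the time loop is over T ~ 15 steps, so all heavy work
## is BLAS matrix products. Optimized with Adam on a weighted
## binary cross-entropy.
##
## Gate layout in the 4H-wide LSTM blocks: input, forget, cell, output.

convlstm_init <- function(n_feat, conv_widths = c(16L, 32L), hidden = 32L,
                          seed = 1L) {
  set.seed(seed)
  glorot <- function(nin, nout) matrix(stats::runif(nin * nout, -1, 1) *
                                         sqrt(6 / (nin + nout)), nin, nout)
  c1 <- conv_widths[1]; c2 <- conv_widths[2]; h <- hidden
  params <- list(
    W1 = lapply(1:3, function(o) glorot(n_feat, c1)), b1 = numeric(c1),
    W2 = lapply(1:3, function(o) glorot(c1, c2)), b2 = numeric(c2),
    Wx = glorot(c2, 4L * h), Wh = glorot(h, 4L * h),
    bl = rep(c(0, 1, 0, 0), each = h),      # forget-gate bias 1
    wo = matrix(glorot(h, 1L), h, 1L), bo = 0)
  attr(params, "dims") <- list(n_feat = n_feat, conv = conv_widths, hidden = h)
  params
}

## Temporal convolution (kernel 3, same padding): X is a list of T
## B x nin matrices; returns list of T B x nout matrices (pre-activation).
conv3_forward <- function(X, W, b) {
  T_ <- length(X); B <- nrow(X[[1]])
  zero <- matrix(0, B, ncol(W[[1]]))
  out <- vector("list", T_)
  for (t in seq_len(T_)) {
    a <- zero
    for (o in 1:3) {
      s <- t + o - 2L                       # offsets -1, 0, +1
      if (s >= 1L && s <= T_) a <- a + X[[s]] %*% W[[o]]
    }
    out[[t]] <- sweep(a, 2, b, "+")
  }
  out
}

conv3_backward <- function(dA, X, W) {
  T_ <- length(X)
  dW <- lapply(W, function(w) w * 0)
  db <- numeric(ncol(W[[1]]))
  dX <- lapply(X, function(x) x * 0)
  for (t in seq_len(T_)) {
    db <- db + colSums(dA[[t]])
    for (o in 1:3) {
      s <- t + o - 2L
      if (s >= 1L && s <= T_) {
        dW[[o]] <- dW[[o]] + crossprod(X[[s]], dA[[t]])
        dX[[s]] <- dX[[s]] + dA[[t]] %*% t(W[[o]])
      }
    }
  }
  list(dW = dW, db = db, dX = dX)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Full forward pass. x: B x T x F array. Returns probabilities and,
## when keep_cache, everything backward() needs.
convlstm_forward <- function(params, x, dropout = 0, keep_cache = FALSE) {
  dims <- attr(params, "dims"); h <- dims$hidden
  B <- dim(x)[1]; T_ <- dim(x)[2]
  X <- lapply(seq_len(T_), function(t) matrix(x[, t, ], B, dim(x)[3]))
  A1 <- conv3_forward(X, params$W1, params$b1)
  Z1 <- lapply(A1, function(a) a * (a > 0))
  A2 <- conv3_forward(Z1, params$W2, params$b2)
  Z2 <- lapply(A2, function(a) a * (a > 0))
  ## LSTM
  hs <- cs <- gates <- vector("list", T_)
  h_prev <- matrix(0, B, h); c_prev <- matrix(0, B, h)
  for (t in seq_len(T_)) {
    G <- sweep(Z2[[t]] %*% params$Wx + h_prev %*% params$Wh, 2, params$bl, "+")
    gi <- sigmoid(G[, 1:h, drop = FALSE])
    gf <- sigmoid(G[, h + 1:h, drop = FALSE])
    gg <- tanh(G[, 2 * h + 1:h, drop = FALSE])
    go <- sigmoid(G[, 3 * h + 1:h, drop = FALSE])
    c_t <- gf * c_prev + gi * gg
    h_t <- go * tanh(c_t)
    gates[[t]] <- list(i = gi, f = gf, g = gg, o = go)
    hs[[t]] <- h_t; cs[[t]] <- c_t
    h_prev <- h_t; c_prev <- c_t
  }
  hT <- hs[[T_]]
  mask <- NULL
  if (dropout > 0) {
    mask <- matrix(stats::rbinom(B * h, 1L, 1 - dropout), B, h) / (1 - dropout)
    hT <- hT * mask
  }
  z <- as.numeric(hT %*% params$wo) + params$bo
  p <- sigmoid(z)
  if (!keep_cache) return(p)
  list(p = p, z = z, X = X, A1 = A1, Z1 = Z1, A2 = A2, Z2 = Z2,
       hs = hs, cs = cs, gates = gates, hT = hT, mask = mask)
}

## Backward pass of the weighted BCE loss
##   L = -mean(w * (y log p + (1-y) log(1-p))).
convlstm_backward <- function(params, cache, y, w) {
  dims <- attr(params, "dims"); h <- dims$hidden
  B <- length(y); T_ <- length(cache$X)
  dz <- w * (cache$p - y) / B               # scalar chain through sigmoid
  dwo <- crossprod(cache$hT, matrix(dz, B, 1))
  dbo <- sum(dz)
  dhT <- matrix(dz, B, 1) %*% t(params$wo)
  if (!is.null(cache$mask)) dhT <- dhT * cache$mask

  dWx <- params$Wx * 0; dWh <- params$Wh * 0; dbl <- numeric(4L * h)
  dZ2 <- lapply(cache$Z2, function(m) m * 0)
  dh_next <- dhT; dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(T_))) {
    g <- cache$gates[[t]]
    c_t <- cache$cs[[t]]
    c_prev <- if (t > 1) cache$cs[[t - 1]] else matrix(0, B, h)
    h_prev <- if (t > 1) cache$hs[[t - 1]] else matrix(0, B, h)
    tc <- tanh(c_t)
    do_ <- dh_next * tc
    dc <- dc_next + dh_next * g$o * (1 - tc^2)
    di <- dc * g$g; dg <- dc * g$i; df <- dc * c_prev
    dG <- cbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                dg * (1 - g$g^2),
                do_ * g$o * (1 - g$o))
    dWx <- dWx + crossprod(cache$Z2[[t]], dG)
    dWh <- dWh + crossprod(h_prev, dG)
    dbl <- dbl + colSums(dG)
    dZ2[[t]] <- dG %*% t(params$Wx)
    dh_next <- dG %*% t(params$Wh)
    dc_next <- dc * g$f
  }
  dA2 <- lapply(seq_len(T_), function(t) dZ2[[t]] * (cache$A2[[t]] > 0))
  bk2 <- conv3_backward(dA2, cache$Z1, params$W2)
  dA1 <- lapply(seq_len(T_), function(t) bk2$dX[[t]] * (cache$A1[[t]] > 0))
  bk1 <- conv3_backward(dA1, cache$X, params$W1)
  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       Wx = dWx, Wh = dWh, bl = dbl, wo = dwo, bo = dbo)
}

convlstm_loss <- function(p, y, w) {
  eps <- 1e-12
  -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

## Adam update; params and grads share structure (lists of matrices /
## vectors, W1/W2 are lists of 3 matrices).
adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  dims <- attr(params, "dims")
  for (nm in names(grads)) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  attr(params, "dims") <- dims
  list(params = params, state = state)
}
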