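# Neural-network primitives with hand-written reverse-mode gradients.
# No deep-learning backend is assumed: convolutions are im2col + BLAS
# matmuls, attention loops over (instance, head) pairs of small matrices.
# Every *_fwd returns list(out, cache); every *_bwd takes (dout, cache) and
# returns list(dx, <param gradients>). All tensors are base-R arrays in
# (batch, position, [embed,] channel) order; matrices collapse the leading
# dims column-major, so array <-> matrix reshapes are zero-cost views.

BN_EPS <- 1e-5
LN_EPS <- 1e-5

# column-wise add/mul/sub without sweep()'s aperm overhead
addcol <- function(X, v) X + rep(v, each = nrow(X))
subcol <- function(X, v) X - rep(v, each = nrow(X))
mulcol <- function(X, v) X * rep(v, each = nrow(X))

## ---- 2D convolution (sequence branch), SAME padding, stride 1 ----
# X: (B, L, E, Cin); W: (kh*kw*Cin, F) with taps ordered (dm, dn, cin); b: F.

im2col2d <- function(X, kh, kw) {
  cpp_im2col2d(X, dim(X), kh, kw)
}

col2im2d <- function(dcols, dims, kh, kw) {
  cpp_col2im2d(dcols, as.integer(dims), kh, kw)
}

conv2d_fwd <- function(X, W, b, kh = 5L, kw = 5L) {
  d <- dim(X)
  cols <- im2col2d(X, kh, kw)
  out <- addcol(cols %*% W, b)
  dim(out) <- c(d[1], d[2], d[3], ncol(W))
  list(out = out, cache = list(cols = cols, dims = d, W = W, kh = kh, kw = kw))
}

conv2d_bwd <- function(dout, cache) {
  Fo <- dim(dout)[4]
  dmat <- matrix(dout, ncol = Fo)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, cache$W)
  dx <- col2im2d(dcols, cache$dims, cache$kh, cache$kw)
  list(dx = dx, dW = dW, db = db)
}

## ---- 1D convolution (density branch), SAME padding, stride 1 ----
# X: (B, L, Cin); W: (k*Cin, F); taps ordered (dm, cin).

im2col1d <- function(X, k) {
  cpp_im2col1d(X, dim(X), k)
}

col2im1d <- function(dcols, dims, k) {
  cpp_col2im1d(dcols, as.integer(dims), k)
}

conv1d_fwd <- function(X, W, b, k = 5L) {
  d <- dim(X)
  cols <- im2col1d(X, k)
  out <- addcol(cols %*% W, b)
  dim(out) <- c(d[1], d[2], ncol(W))
  list(out = out, cache = list(cols = cols, dims = d, W = W, k = k))
}

conv1d_bwd <- function(dout, cache) {
  Fo <- dim(dout)[3]
  dmat <- matrix(dout, ncol = Fo)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dx <- col2im1d(tcrossprod(dmat, cache$W), cache$dims, cache$k)
  list(dx = dx, dW = dW, db = db)
}

## ---- batch normalization over the channel axis ----
# x: (N, F) matrix; normalizes each channel over N (batch x positions).

bn_fwd <- function(x, gamma, beta, run, train, momentum = 0.9) {
  if (train) {
    mu <- colMeans(x)
    xc <- subcol(x, mu)
    v <- colMeans(xc * xc)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean
    v <- run$var
    xc <- subcol(x, mu)
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- mulcol(xc, invstd)
  out <- addcol(mulcol(xhat, gamma), beta)
  list(out = out, run = run,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    train = train))
}

bn_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  N <- nrow(xhat)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- mulcol(dout, cache$gamma)
  if (cache$train) {
    # dx = invstd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- subcol(N * dxhat, s1) - mulcol(xhat, s2)
    dx <- mulcol(dx, cache$invstd / N)
  } else {
    dx <- mulcol(dxhat, cache$invstd)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- pointwise fully connected stage with ReLU (per conv block) ----
# out = ReLU(x %*% Wfc); no bias (batch-norm beta precedes it).

pointwise_relu_fwd <- function(x, Wfc) {
  z <- x %*% Wfc
  out <- z * (z > 0)
  list(out = out, cache = list(x = x, Wfc = Wfc, mask = z > 0))
}

pointwise_relu_bwd <- function(dout, cache) {
  dz <- dout * cache$mask
  list(dx = tcrossprod(dz, cache$Wfc), dW = crossprod(cache$x, dz))
}

## ---- multi-head scaled dot-product attention ----
# X: (B, L, C); Wq/Wk/Wv: (C, H*K), head h occupies columns (h-1)*K + 1:K.
# a_ij = softmax_j(q_i . k_j / sqrt(K)); h_i = sum_j a_ij v_j; heads are
# concatenated -> (B, L, H*K). Dropout (inverted) acts on the attention
# probabilities in training mode only.

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

attention_fwd <- function(X, Wq, Wk, Wv, H, K, dropout = 0, train = FALSE) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  Xm <- matrix(X, B * L, C)
  Q <- Xm %*% Wq; dim(Q) <- c(B, L, K, H)
  Kt <- Xm %*% Wk; dim(Kt) <- c(B, L, K, H)
  V <- Xm %*% Wv; dim(V) <- c(B, L, K, H)
  M <- NULL                        # dropout mask / keep-prob scale
  drop_on <- train && dropout > 0
  if (drop_on) M <- array(stats::rbinom(B * L * L * H, 1L, 1 - dropout) /
                            (1 - dropout), c(B, L, L, H))
  core <- cpp_att_fwd(Q, Kt, V, B, L, K, H,
                      if (drop_on) M else numeric(0))
  A <- core$A                      # attention probabilities (pre-dropout)
  out <- core$O; dim(out) <- c(B, L, K * H)
  list(out = out,
       cache = list(Xm = Xm, Q = Q, Kt = Kt, V = V, A = A, M = M,
                    Wq = Wq, Wk = Wk, Wv = Wv, H = H, K = K, B = B, L = L,
                    C = C, drop_on = drop_on))
}

attention_bwd <- function(dout, cache) {
  B <- cache$B; L <- cache$L; K <- cache$K; H <- cache$H; C <- cache$C
  dO <- dout; dim(dO) <- c(B, L, K, H)
  core <- cpp_att_bwd(dO, cache$A, cache$Q, cache$Kt, cache$V, B, L, K, H,
                      if (cache$drop_on) cache$M else numeric(0))
  dQm <- matrix(core$dQ, B * L, K * H)
  dKm <- matrix(core$dK, B * L, K * H)
  dVm <- matrix(core$dV, B * L, K * H)
  dXm <- tcrossprod(dQm, cache$Wq) + tcrossprod(dKm, cache$Wk) +
    tcrossprod(dVm, cache$Wv)
  dx <- array(dXm, c(B, L, C))
  list(dx = dx,
       dWq = crossprod(cache$Xm, dQm),
       dWk = crossprod(cache$Xm, dKm),
       dWv = crossprod(cache$Xm, dVm))
}

## ---- feed-forward: dense -> layer norm -> ReLU ----
# x: (N, Cin) -> (N, F)

ff_fwd <- function(x, W, b, gamma, beta) {
  y <- addcol(x %*% W, b)
  Fo <- ncol(y)
  mu <- rowMeans(y)
  yc <- y - mu
  v <- rowMeans(yc * yc)
  invstd <- 1 / sqrt(v + LN_EPS)
  yhat <- yc * invstd
  z <- addcol(mulcol(yhat, gamma), beta)
  out <- z * (z > 0)
  list(out = out,
       cache = list(x = x, W = W, yhat = yhat, invstd = invstd,
                    gamma = gamma, mask = z > 0, Fo = Fo))
}

ff_bwd <- function(dout, cache) {
  dz <- dout * cache$mask
  dgamma <- colSums(dz * cache$yhat)
  dbeta <- colSums(dz)
  dyhat <- mulcol(dz, cache$gamma)
  Fo <- cache$Fo
  # layer-norm backward, per row
  s1 <- rowSums(dyhat)
  s2 <- rowSums(dyhat * cache$yhat)
  dy <- (dyhat - s1 / Fo - cache$yhat * (s2 / Fo)) * cache$invstd
  dW <- crossprod(cache$x, dy)
  db <- colSums(dy)
  dx <- tcrossprod(dy, cache$W)
  list(dx = dx, dW = dW, db = db, dgamma = dgamma, dbeta = dbeta)
}

## ---- pooling ----

# (B, L, E, F) -> (B, L, F), mean over the embedding axis. Rows of the
# (B*L*E, F) matrix view are ordered (b, l, e), so grouping rows by
# (b, l) averages out the embedding axis without any aperm copy.
pool_embed_fwd <- function(X) {
  d <- dim(X)
  grp <- rep(seq_len(d[1] * d[2]), d[3])
  out <- rowsum(matrix(X, ncol = d[4]), grp, reorder = FALSE) / d[3]
  dim(out) <- c(d[1], d[2], d[4])
  list(out = out, cache = d)
}

pool_embed_bwd <- function(dout, dims) {
  grp <- rep(seq_len(dims[1] * dims[2]), dims[3])
  dX <- matrix(dout, ncol = dims[4])[grp, , drop = FALSE] / dims[3]
  dim(dX) <- dims
  dX
}

# (B, L, F) -> (B, F), mean over positions
pool_pos_fwd <- function(X) {
  d <- dim(X)
  grp <- rep(seq_len(d[1]), d[2])
  out <- rowsum(matrix(X, ncol = d[3]), grp, reorder = FALSE) / d[2]
  dim(out) <- c(d[1], d[3])
  list(out = out, cache = d)
}

pool_pos_bwd <- function(dout, dims) {
  grp <- rep(seq_len(dims[1]), dims[2])
  dX <- dout[grp, , drop = FALSE] / dims[2]
  dim(dX) <- dims
  dX
}
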