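# The two-branch density regression model. Branch 1 embeds the codon window
# and extracts motifs with 2D conv blocks; branch 2 processes the log
# reference-density window with 1D conv blocks. Each branch then runs
# multi-head attention, a feed-forward stage and a global average over
# positions, yielding a feature vector per branch. The vectors are merged by
# element-wise multiplication through a ReLU head that predicts the
# (gene-mean-normalized, linear-scale) density of the center codon in the
# target condition.

#' Model architecture configuration
#'
#' Defaults follow the published architecture: 8-dim codon embedding, 5
#' convolution blocks (kernel 5x5 for the sequence branch, 5 for the density
#' branch, 32 filters), one attention block with 10 heads of key/query
#' dimension 8 and dropout 0.1, and 32-dim branch outputs.
#'
#' @param W half-window in codons (window length `2W+1`).
#' @param embed_dim codon embedding dimension.
#' @param conv_blocks number of convolution blocks per branch.
#' @param conv_kernel kernel size (used as `(k, k)` in 2D, `k` in 1D).
#' @param filters number of convolution filters (= branch output dim).
#' @param attention_heads number of attention heads.
#' @param key_dim key/query/value dimension per head.
#' @param dropout dropout rate on attention probabilities (training only).
#' @return a `ribocast_model_config`.
#' @export
model_config <- function(W = 20L, embed_dim = 8L, conv_blocks = 5L,
                         conv_kernel = 5L, filters = 32L,
                         attention_heads = 10L, key_dim = 8L,
                         dropout = 0.1) {
  cfg <- list(W = as.integer(W), embed_dim = as.integer(embed_dim),
              conv_blocks = as.integer(conv_blocks),
              conv_kernel = as.integer(conv_kernel),
              filters = as.integer(filters),
              attention_heads = as.integer(attention_heads),
              key_dim = as.integer(key_dim), dropout = dropout,
              branch_out_dim = as.integer(filters))
  with(cfg, abort_if(W < 1 || embed_dim < 1 || conv_blocks < 1 ||
                       conv_kernel < 1 || filters < 1 ||
                       attention_heads < 1 || key_dim < 1 ||
                       dropout < 0 || dropout >= 1,
                     "invalid model configuration"))
  structure(cfg, class = "ribocast_model_config")
}

#' Training configuration
#'
#' Adam with a cosine learning-rate decay from `start_lr` to 0 over the
#' planned training steps, mean-squared-error loss, and early stopping when
#' the validation loss has not decreased for `patience` epochs.
#'
#' @param start_lr initial learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return a `ribocast_train_config`.
#' @export
train_config <- function(start_lr = 5e-4, batch_size = 128L,
                         max_epochs = 200L, patience = 10L, seed = 1L) {
  abort_if(start_lr <= 0, "start_lr must be > 0")
  abort_if(patience < 1, "patience must be >= 1")
  structure(list(start_lr = start_lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ribocast_train_config")
}

#' Cosine learning-rate schedule
#'
#' `lr(s) = start_lr * (1 + cos(pi * s)) / 2` for normalized training
#' progress `s` in `[0, 1]` (current step / total planned steps).
#' Out-of-range fractions are clamped with a warning.
#'
#' @param step_fraction normalized progress in `[0, 1]`.
#' @param start_lr initial learning rate.
#' @return the learning rate.
#' @export
#' @examples
#' cosine_lr(0)    # 5e-4
#' cosine_lr(0.5)  # 2.5e-4
#' cosine_lr(1)    # 0
cosine_lr <- function(step_fraction, start_lr = 5e-4) {
  if (any(step_fraction < 0 | step_fraction > 1)) {
    warning("step_fraction clamped to [0, 1]", call. = FALSE)
    step_fraction <- pmin(pmax(step_fraction, 0), 1)
  }
  start_lr * (1 + cos(pi * step_fraction)) / 2
}

glorot <- function(nin, nout, dims = c(nin, nout)) {
  l <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -l, l), dims)
}

init_params <- function(cfg) {
  E <- cfg$embed_dim; Fo <- cfg$filters; k <- cfg$conv_kernel
  H <- cfg$attention_heads; K <- cfg$key_dim
  p <- list()
  p$emb <- matrix(stats::rnorm(64 * E, sd = 0.1), 64, E)
  for (br in c("seq", "ref")) {
    taps <- if (br == "seq") k * k else k
    for (i in seq_len(cfg$conv_blocks)) {
      cin <- if (i == 1L) 1L else Fo
      p[[paste0(br, "_conv", i, "_W")]] <- glorot(taps * cin, Fo)
      p[[paste0(br, "_conv", i, "_b")]] <- numeric(Fo)
      p[[paste0(br, "_conv", i, "_gamma")]] <- rep(1, Fo)
      p[[paste0(br, "_conv", i, "_beta")]] <- numeric(Fo)
      p[[paste0(br, "_conv", i, "_fc")]] <- glorot(Fo, Fo)
    }
    p[[paste0(br, "_att_Wq")]] <- glorot(Fo, K, c(Fo, H * K))
    p[[paste0(br, "_att_Wk")]] <- glorot(Fo, K, c(Fo, H * K))
    p[[paste0(br, "_att_Wv")]] <- glorot(Fo, K, c(Fo, H * K))
    p[[paste0(br, "_ff_W")]] <- glorot(H * K, Fo)
    p[[paste0(br, "_ff_b")]] <- numeric(Fo)
    p[[paste0(br, "_ln_gamma")]] <- rep(1, Fo)
    p[[paste0(br, "_ln_beta")]] <- numeric(Fo)
  }
  p$head_w <- glorot(Fo, 1L)
  p$head_b <- 1
  p$ref_mask <- rep(0.5, Fo)  # learned stand-in for a masked reference branch
  p
}

init_bn_state <- function(cfg) {
  st <- list()
  for (br in c("seq", "ref")) {
    for (i in seq_len(cfg$conv_blocks)) {
      st[[paste0(br, "_conv", i)]] <- list(mean = numeric(cfg$filters),
                                           var = rep(1, cfg$filters))
    }
  }
  st
}

# one branch forward; X0 is (B,L,E,1) for "seq", (B,L,1) for "ref"
branch_fwd <- function(X0, p, bn, cfg, br, train, keep_cache = FALSE) {
  caches <- list()
  x <- X0
  for (i in seq_len(cfg$conv_blocks)) {
    nm <- paste0(br, "_conv", i)
    cv <- if (br == "seq") {
      conv2d_fwd(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                 cfg$conv_kernel, cfg$conv_kernel)
    } else {
      conv1d_fwd(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                 cfg$conv_kernel)
    }
    d <- dim(cv$out)
    xm <- matrix(cv$out, ncol = cfg$filters)
    bnr <- bn_fwd(xm, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                  bn[[nm]], train)
    bn[[nm]] <- bnr$run
    pw <- pointwise_relu_fwd(bnr$out, p[[paste0(nm, "_fc")]])
    x <- array(pw$out, d)
    if (keep_cache) caches[[nm]] <- list(conv = cv$cache, bn = bnr$cache,
                                         pw = pw$cache, dims = d)
  }
  if (br == "seq") {
    pe <- pool_embed_fwd(x)
    x <- pe$out
    if (keep_cache) caches$pool_embed <- pe$cache
  }
  at <- attention_fwd(x, p[[paste0(br, "_att_Wq")]], p[[paste0(br, "_att_Wk")]],
                      p[[paste0(br, "_att_Wv")]], cfg$attention_heads,
                      cfg$key_dim, cfg$dropout, train)
  if (keep_cache) caches$att <- at$cache
  d3 <- dim(at$out)
  ffin <- matrix(at$out, ncol = d3[3])
  ff <- ff_fwd(ffin, p[[paste0(br, "_ff_W")]], p[[paste0(br, "_ff_b")]],
               p[[paste0(br, "_ln_gamma")]], p[[paste0(br, "_ln_beta")]])
  if (keep_cache) caches$ff <- ff$cache
  xarr <- array(ff$out, c(d3[1], d3[2], cfg$filters))
  pp <- pool_pos_fwd(xarr)
  if (keep_cache) caches$pool_pos <- pp$cache
  list(out = pp$out, bn = bn, caches = caches)
}

branch_bwd <- function(dout, caches, p, cfg, br) {
  g <- list()
  dx <- pool_pos_bwd(dout, caches$pool_pos)
  d3 <- dim(dx)
  ffb <- ff_bwd(matrix(dx, ncol = cfg$filters), caches$ff)
  g[[paste0(br, "_ff_W")]] <- ffb$dW
  g[[paste0(br, "_ff_b")]] <- ffb$db
  g[[paste0(br, "_ln_gamma")]] <- ffb$dgamma
  g[[paste0(br, "_ln_beta")]] <- ffb$dbeta
  datt <- array(ffb$dx, c(d3[1], d3[2], cfg$attention_heads * cfg$key_dim))
  ab <- attention_bwd(datt, caches$att)
  g[[paste0(br, "_att_Wq")]] <- ab$dWq
  g[[paste0(br, "_att_Wk")]] <- ab$dWk
  g[[paste0(br, "_att_Wv")]] <- ab$dWv
  dx <- ab$dx
  if (br == "seq") dx <- pool_embed_bwd(dx, caches$pool_embed)
  for (i in rev(seq_len(cfg$conv_blocks))) {
    nm <- paste0(br, "_conv", i)
    cc <- caches[[nm]]
    dmat <- matrix(dx, ncol = cfg$filters)
    pwb <- pointwise_relu_bwd(dmat, cc$pw)
    g[[paste0(nm, "_fc")]] <- pwb$dW
    bnb <- bn_bwd(pwb$dx, cc$bn)
    g[[paste0(nm, "_gamma")]] <- bnb$dgamma
    g[[paste0(nm, "_beta")]] <- bnb$dbeta
    dconv <- array(bnb$dx, cc$dims)
    cb <- if (br == "seq") conv2d_bwd(dconv, cc$conv) else conv1d_bwd(dconv, cc$conv)
    g[[paste0(nm, "_W")]] <- cb$dW
    g[[paste0(nm, "_b")]] <- cb$db
    dx <- cb$dx
  }
  list(dx = dx, grads = g)
}

# full forward pass; seq_mat: (B, L) 0..63, ref_mat: (B, L) numeric
forward_pass <- function(p, bn, cfg, seq_mat, ref_mat, train = FALSE,
                         mask_ref = FALSE, keep_cache = FALSE) {
  B <- nrow(seq_mat); L <- ncol(seq_mat)
  abort_if(L != 2L * cfg$W + 1L, "window length ", L,
           " does not match model W=", cfg$W)
  abort_if(any(seq_mat < 0L | seq_mat > 63L), "codon index out of range 0..63")
  idx <- as.vector(seq_mat) + 1L
  X0s <- array(p$emb[idx, ], c(B, L, cfg$embed_dim, 1L))
  sb <- branch_fwd(X0s, p, bn, cfg, "seq", train, keep_cache)
  bn <- sb$bn
  if (mask_ref) {
    xref <- matrix(p$ref_mask, B, cfg$filters, byrow = TRUE)
    rb <- NULL
  } else {
    X0r <- array(ref_mat, c(B, L, 1L))
    rb <- branch_fwd(X0r, p, bn, cfg, "ref", train, keep_cache)
    bn <- rb$bn
    xref <- rb$out
  }
  M <- sb$out * xref
  z <- as.vector(M %*% p$head_w) + p$head_b
  pred <- pmax(z, 0)
  list(pred = pred, bn = bn,
       cache = if (keep_cache) list(seq_idx = idx, seqB = sb$caches,
                                    refB = if (!mask_ref) rb$caches,
                                    xseq = sb$out, xref = xref, M = M, z = z,
                                    B = B, L = L, mask_ref = mask_ref))
}

backward_pass <- function(dpred, cache, p, cfg) {
  dz <- dpred * (cache$z > 0)
  g <- list(head_w = crossprod(cache$M, dz),
            head_b = sum(dz))
  dM <- matrix(dz, ncol = 1L) %*% t(p$head_w)  # (B, F)
  dxseq <- dM * cache$xref
  dxref <- dM * cache$xseq
  sb <- branch_bwd(dxseq, cache$seqB, p, cfg, "seq")
  g <- c(g, sb$grads)
  if (cache$mask_ref) {
    g$ref_mask <- colSums(dxref)
  } else {
    rb <- branch_bwd(dxref, cache$refB, p, cfg, "ref")
    g <- c(g, rb$grads)
  }
  # embedding gradient: scatter-add rows of the (B*L, E) upstream gradient
  dX0 <- matrix(sb$dx, ncol = cfg$embed_dim)
  agg <- rowsum(dX0, cache$seq_idx)
  demb <- matrix(0, 64, cfg$embed_dim)
  demb[as.integer(rownames(agg)), ] <- agg
  g$emb <- demb
  g
}

## ---- exported layer-level operations ----

#' Embed a codon window
#'
#' Deterministic lookup of the learned codon embedding table.
#'
#' @param model a trained or initialized model (see [train_model()]).
#' @param seq_window integer vector of codon indices (0..63).
#' @return a `(length, embed_dim)` matrix.
#' @export
embed_codons <- function(model, seq_window) {
  abort_if(any(seq_window < 0L | seq_window > 63L),
           "codon index out of range 0..63")
  model$params$emb[seq_window + 1L, , drop = FALSE]
}

#' One convolution block (convolution, batch norm, pointwise ReLU stage)
#'
#' Forward evaluation of a single block:
#' `x -> conv (SAME, stride 1) -> batch norm -> ReLU(w_fc . x)`.
#' Exposed mainly for verification against brute-force oracles.
#'
#' @param x input array: `(B, L, E, Cin)` for `kind = "2D"`, `(B, L, Cin)`
#'   for `kind = "1D"`.
#' @param params list with `W` (`taps*Cin x F`), `b`, `gamma`, `beta`, `fc`
#'   (`F x F`); `W` taps are ordered (row offset, column offset, channel).
#' @param kind `"2D"` or `"1D"`.
#' @param kernel kernel size.
#' @param batchnorm set `FALSE` to skip the normalization stage.
#' @param train batch-norm mode (batch statistics vs running statistics).
#' @return feature-map array with `F` channels.
#' @export
conv_block <- function(x, params, kind = c("2D", "1D"), kernel = 5L,
                       batchnorm = TRUE, train = TRUE) {
  kind <- match.arg(kind)
  cv <- if (kind == "2D") {
    abort_if(length(dim(x)) != 4L, "2D conv_block expects a 4-d array")
    conv2d_fwd(x, params$W, params$b, kernel, kernel)
  } else {
    abort_if(length(dim(x)) != 3L, "1D conv_block expects a 3-d array")
    conv1d_fwd(x, params$W, params$b, kernel)
  }
  d <- dim(cv$out)
  Fo <- d[length(d)]
  xm <- matrix(cv$out, ncol = Fo)
  if (batchnorm) {
    bnr <- bn_fwd(xm, params$gamma, params$beta,
                  list(mean = numeric(Fo), var = rep(1, Fo)), train)
    xm <- bnr$out
  }
  pw <- pointwise_relu_fwd(xm, params$fc)
  array(pw$out, d)
}

#' Multi-head scaled dot-product attention
#'
#' `a_ij = softmax_j(q_i . k_j / sqrt(K))`, head outputs
#' `h_i = sum_j a_ij v_j`, heads concatenated. Deterministic in evaluation
#' mode; dropout acts on the attention probabilities in training mode.
#'
#' @param x input array `(B, L, C)`.
#' @param params list with `Wq`, `Wk`, `Wv` (`C x H*K`), `heads`, `key_dim`,
#'   optional `dropout`.
#' @param train logical; enables dropout.
#' @param return_attention also return the `(B, L, L, H)` attention array.
#' @return `(B, L, H*K)` array, or a list when `return_attention = TRUE`.
#' @export
multi_head_attention <- function(x, params, train = FALSE,
                                 return_attention = FALSE) {
  abort_if(dim(x)[3] != nrow(params$Wq),
           "input channels incompatible with projection matrices")
  at <- attention_fwd(x, params$Wq, params$Wk, params$Wv, params$heads,
                      params$key_dim, params$dropout %||% 0, train)
  if (return_attention) list(out = at$out, attention = at$cache$A) else at$out
}

#' Feed-forward stage (dense, layer norm, ReLU)
#'
#' @param x matrix `(N, Cin)` or array `(B, L, Cin)`.
#' @param params list with `W`, `b`, `gamma`, `beta`.
#' @return same leading shape with `ncol(W)` channels.
#' @export
feed_forward <- function(x, params) {
  d <- dim(x)
  xm <- if (length(d) == 3L) matrix(x, ncol = d[3]) else x
  out <- ff_fwd(xm, params$W, params$b, params$gamma, params$beta)$out
  if (length(d) == 3L) array(out, c(d[1], d[2], ncol(params$W))) else out
}

#' Forward pass of one branch
#'
#' Runs conv blocks, pooling, attention, feed-forward and the global average
#' over positions, yielding the branch feature vector(s).
#'
#' @param model a model object.
#' @param input for `branch = "sequence"`: integer matrix `(B, L)` of codon
#'   indices; for `branch = "reference"`: numeric matrix `(B, L)` of log
#'   densities.
#' @param branch `"sequence"` or `"reference"`.
#' @param train evaluation vs training mode.
#' @return `(B, filters)` matrix.
#' @export
branch_forward <- function(model, input, branch = c("sequence", "reference"),
                           train = FALSE) {
  branch <- match.arg(branch)
  cfg <- model$config
  B <- nrow(input); L <- ncol(input)
  abort_if(L != 2L * cfg$W + 1L, "input length does not match model window")
  if (branch == "sequence") {
    idx <- as.vector(input) + 1L
    X0 <- array(model$params$emb[idx, ], c(B, L, cfg$embed_dim, 1L))
    branch_fwd(X0, model$params, model$bn, cfg, "seq", train)$out
  } else {
    X0 <- array(input, c(B, L, 1L))
    branch_fwd(X0, model$params, model$bn, cfg, "ref", train)$out
  }
}

#' Full model forward pass
#'
#' Predicts the target-condition density of the center codon for each
#' instance. With `mask_ref = TRUE` the reference branch output is replaced
#' by a learned constant vector, turning the network into a pure
#' sequence-based model.
#'
#' @param model a model object.
#' @param seq_window integer matrix `(B, L)` (or vector, one instance).
#' @param ref_window numeric matrix `(B, L)` of log reference densities.
#' @param mask_ref logical.
#' @param train evaluation vs training mode.
#' @return numeric vector of non-negative predicted densities.
#' @export
model_forward <- function(model, seq_window, ref_window, mask_ref = FALSE,
                          train = FALSE) {
  if (is.null(dim(seq_window))) seq_window <- matrix(seq_window, nrow = 1L)
  if (is.null(dim(ref_window))) ref_window <- matrix(ref_window, nrow = 1L)
  abort_if(!all(dim(seq_window) == dim(ref_window)),
           "seq_window and ref_window shapes differ")
  forward_pass(model$params, model$bn, model$config, seq_window, ref_window,
               train = train, mask_ref = mask_ref)$pred
}
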