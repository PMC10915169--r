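# Layer-level contracts: brute-force oracles for convolution and attention,
# softmax row normalization, feed-forward stages, schedule closed forms,
# finite-difference gradient checks, checkpoint round trips.

test_that("conv_block matches the brute-force convolution oracle", {
  set.seed(101)
  for (rep in 1:30) {
    B <- sample(1:3, 1); L <- sample(4:9, 1); E <- sample(2:5, 1)
    Cin <- sample(1:3, 1); Fo <- sample(1:4, 1); k <- sample(c(3L, 5L), 1)
    X <- array(rnorm(B * L * E * Cin), c(B, L, E, Cin))
    W <- matrix(rnorm(k * k * Cin * Fo), k * k * Cin, Fo)
    b <- rnorm(Fo)
    fwd <- ribocast:::conv2d_fwd(X, W, b, k, k)$out
    for (bb in seq_len(B)) {
      xo <- array(X[bb, , , ], c(L, E, Cin))
      expect_equal(array(fwd[bb, , , ], c(L, E, Fo)),
                   oracle_conv2d(xo, W, b, k, k), tolerance = 1e-6)
    }
  }
})

test_that("1D convolution matches the brute-force oracle", {
  set.seed(102)
  for (rep in 1:30) {
    B <- sample(1:3, 1); L <- sample(4:10, 1)
    Cin <- sample(1:4, 1); Fo <- sample(1:4, 1); k <- sample(c(3L, 5L), 1)
    X <- array(rnorm(B * L * Cin), c(B, L, Cin))
    W <- matrix(rnorm(k * Cin * Fo), k * Cin, Fo)
    b <- rnorm(Fo)
    fwd <- ribocast:::conv1d_fwd(X, W, b, k)$out
    for (bb in seq_len(B)) {
      xo <- matrix(X[bb, , ], L, Cin)
      expect_equal(matrix(fwd[bb, , ], L, Fo),
                   oracle_conv1d(xo, W, b, k), tolerance = 1e-6)
    }
  }
})

test_that("conv_block edge behaviors: zero input and identity kernel", {
  Fo <- 3L
  params <- list(W = matrix(0, 25 * 1, Fo), b = numeric(Fo),
                 gamma = rep(1, Fo), beta = numeric(Fo),
                 fc = diag(Fo))
  X <- array(0, c(2, 6, 4, 1))
  out <- conv_block(X, params, "2D", batchnorm = FALSE)
  expect_true(all(out == 0))

  # identity-like single-tap kernel, batch norm off, identity pointwise:
  # output equals input on the active filter for non-negative input
  W <- matrix(0, 25, Fo)
  W[(2 * 5 + 2) * 1 + 1, 1] <- 1  # center tap (dm=2, dn=2, 0-based)
  params$W <- W
  Xp <- array(abs(rnorm(2 * 6 * 4)), c(2, 6, 4, 1))
  out2 <- conv_block(Xp, params, "2D", batchnorm = FALSE)
  expect_equal(array(out2[, , , 1], dim(Xp)[1:3]),
               array(Xp[, , , 1], dim(Xp)[1:3]), tolerance = 1e-12)
})

test_that("multi_head_attention matches the brute-force oracle", {
  set.seed(103)
  for (rep in 1:40) {
    B <- sample(1:3, 1); L <- sample(2:8, 1); C <- sample(3:16, 1)
    H <- sample(1:3, 1); K <- sample(2:5, 1)
    X <- array(rnorm(B * L * C), c(B, L, C))
    params <- list(Wq = matrix(rnorm(C * H * K), C, H * K),
                   Wk = matrix(rnorm(C * H * K), C, H * K),
                   Wv = matrix(rnorm(C * H * K), C, H * K),
                   heads = H, key_dim = K, dropout = 0)
    out <- multi_head_attention(X, params)
    for (bb in seq_len(B)) {
      xo <- matrix(X[bb, , ], L, C)
      expect_equal(matrix(out[bb, , ], L, H * K),
                   oracle_attention(xo, params$Wq, params$Wk, params$Wv,
                                    H, K), tolerance = 1e-6)
    }
  }
  # fixed-size oracle agreement at the spec's example shape (L=7, C=16)
  X <- array(rnorm(7 * 16), c(1, 7, 16))
  params <- list(Wq = matrix(rnorm(16 * 20), 16, 20),
                 Wk = matrix(rnorm(16 * 20), 16, 20),
                 Wv = matrix(rnorm(16 * 20), 16, 20),
                 heads = 4, key_dim = 5, dropout = 0)
  expect_equal(matrix(multi_head_attention(X, params)[1, , ], 7, 20),
               oracle_attention(matrix(X[1, , ], 7, 16), params$Wq,
                                params$Wk, params$Wv, 4, 5),
               tolerance = 1e-6)
})

test_that("attention rows sum to one and degenerate cases behave", {
  set.seed(104)
  for (rep in 1:20) {
    B <- sample(1:3, 1); L <- sample(1:7, 1); C <- sample(2:8, 1)
    H <- sample(1:3, 1); K <- sample(1:4, 1)
    X <- array(rnorm(B * L * C), c(B, L, C))
    params <- list(Wq = matrix(rnorm(C * H * K), C, H * K),
                   Wk = matrix(rnorm(C * H * K), C, H * K),
                   Wv = matrix(rnorm(C * H * K), C, H * K),
                   heads = H, key_dim = K, dropout = 0)
    res <- multi_head_attention(X, params, return_attention = TRUE)
    A <- res$attention
    sums <- apply(A, c(1, 2, 4), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  # all keys identical -> uniform attention 1/L
  L <- 5; C <- 4
  X <- array(rep(rnorm(C), each = L), c(1, L, C))
  params <- list(Wq = matrix(rnorm(C * 3), C, 3),
                 Wk = matrix(rnorm(C * 3), C, 3),
                 Wv = matrix(rnorm(C * 3), C, 3),
                 heads = 1, key_dim = 3, dropout = 0)
  res <- multi_head_attention(X, params, return_attention = TRUE)
  expect_true(all(abs(res$attention - 1 / L) < 1e-6))
  # L = 1 -> output equals the value projection
  X1 <- array(rnorm(C), c(1, 1, C))
  res1 <- multi_head_attention(X1, params)
  expect_equal(as.vector(res1), as.vector(matrix(X1[1, 1, ], 1) %*% params$Wv),
               tolerance = 1e-10)
  expect_error(multi_head_attention(array(rnorm(10), c(1, 2, 5)), params),
               "incompatible")
})

test_that("feed_forward obeys layer-norm and ReLU contracts", {
  set.seed(105)
  Cin <- 6L; Fo <- 5L
  params <- list(W = matrix(rnorm(Cin * Fo), Cin, Fo), b = rnorm(Fo),
                 gamma = rep(1, Fo), beta = numeric(Fo))
  x <- matrix(rnorm(40 * Cin), 40, Cin)
  out <- feed_forward(x, params)
  expect_true(all(out >= 0))
  # oracle: compose the three stages by hand
  y <- x %*% params$W + matrix(params$b, 40, Fo, byrow = TRUE)
  yhat <- t(apply(y, 1, function(r) (r - mean(r)) /
                    sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(out, pmax(yhat, 0), tolerance = 1e-6)
  # constant input row -> layer-norm core output is zero
  xc <- matrix(1, 3, Cin)
  pc <- params; pc$W <- matrix(1, Cin, Fo); pc$b <- rep(0, Fo)
  expect_true(all(abs(feed_forward(xc, pc)) < 1e-6))
})

test_that("cosine_lr matches the closed form exactly", {
  expect_identical(cosine_lr(0), 5e-4)
  expect_equal(cosine_lr(0.5), 2.5e-4, tolerance = 1e-15)
  expect_equal(cosine_lr(1), 0)
  expect_warning(out <- cosine_lr(1.5), "clamped")
  expect_equal(out, 0)
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(cosine_lr(s)) <= 0))  # monotone decay
})

test_that("model forward respects merge-head and masking contracts", {
  mc <- model_config(W = 2, embed_dim = 3, conv_blocks = 2, conv_kernel = 3,
                     filters = 4, attention_heads = 2, key_dim = 2,
                     dropout = 0)
  p <- ribocast:::with_seed(9, ribocast:::init_params(mc))
  bn <- ribocast:::init_bn_state(mc)
  model <- structure(list(config = mc, params = p, bn = bn,
                          mask_ref = FALSE,
                          meta = list(W = 2, ref_transform = "log",
                                      target_transform = "gene_mean_normalized",
                                      pseudocount = 0.5)),
                     class = "ribocast_model")
  L <- 5
  sq <- matrix(sample(0:63, 3 * L, TRUE), 3, L)
  rf <- matrix(rnorm(3 * L), 3, L)
  # deterministic repeat in eval mode, bit-identical
  expect_identical(model_forward(model, sq, rf), model_forward(model, sq, rf))
  expect_true(all(model_forward(model, sq, rf) >= 0))
  # head oracle: prediction = ReLU(w . (x_seq * x_ref) + b)
  xs <- branch_forward(model, sq, "sequence")
  xr <- branch_forward(model, rf, "reference")
  manual <- pmax(as.vector((xs * xr) %*% p$head_w) + as.numeric(p$head_b), 0)
  expect_equal(model_forward(model, sq, rf), manual, tolerance = 1e-10)
  # masked reference replaces the branch output by the learned constant
  manual_m <- pmax(as.vector((xs * matrix(p$ref_mask, 3, 4, byrow = TRUE)) %*%
                               p$head_w) + as.numeric(p$head_b), 0)
  expect_equal(model_forward(model, sq, rf, mask_ref = TRUE), manual_m,
               tolerance = 1e-10)
  # embeddings: identical windows embed identically, single-row difference
  e1 <- embed_codons(model, sq[1, ])
  e2 <- embed_codons(model, sq[1, ])
  expect_identical(e1, e2)
  sq2 <- sq[1, ]; sq2[3] <- (sq2[3] + 1) %% 64
  diffrows <- which(rowSums(abs(embed_codons(model, sq2) - e1)) > 0)
  expect_equal(diffrows, 3L)
  expect_error(model_forward(model, matrix(64, 1, L), rf[1, , drop = FALSE]),
               "range")
})

test_that("backward pass matches finite differences on a tiny model", {
  mc <- model_config(W = 3, embed_dim = 3, conv_blocks = 2, conv_kernel = 3,
                     filters = 3, attention_heads = 2, key_dim = 2,
                     dropout = 0)
  set.seed(11)
  p <- ribocast:::init_params(mc)
  bn <- ribocast:::init_bn_state(mc)
  B <- 3; L <- 7
  sq <- matrix(sample(0:63, B * L, TRUE), B, L)
  rf <- matrix(rnorm(B * L), B, L)
  y <- runif(B)
  for (mask in c(FALSE, TRUE)) {
    loss <- function(pp) {
      fw <- ribocast:::forward_pass(pp, bn, mc, sq, rf, train = TRUE,
                                    mask_ref = mask)
      mean((fw$pred - y)^2)
    }
    fw <- ribocast:::forward_pass(p, bn, mc, sq, rf, train = TRUE,
                                  mask_ref = mask, keep_cache = TRUE)
    g <- ribocast:::backward_pass(2 * (fw$pred - y) / B, fw$cache, p, mc)
    eps <- 1e-6
    for (nm in names(g)) {
      for (t in seq_len(min(3, length(p[[nm]])))) {
        i <- sample(length(p[[nm]]), 1)
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss(pp) - loss(pm)) / (2 * eps)
        ana <- as.vector(g[[nm]])[i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("grad", nm, if (mask) "(masked)"))
      }
    }
  }
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- synth_config(n_genes = 12, length_range = c(70, 80), seed = 21,
                      depth = 800)
  genes <- generate_genes(cfg)
  sim <- simulate_density(genes, cfg)
  cd <- codon_density(sim$track, genes)
  ds <- build_windows(genes, normalize_and_log(cd), normalize_gene_mean(cd),
                      W = 3)
  sp <- split_dataset(ds, "fraction", seed = 1)
  mc <- model_config(W = 3, embed_dim = 3, conv_blocks = 2, conv_kernel = 3,
                     filters = 4, attention_heads = 2, key_dim = 2)
  m <- train_model(ds, sp, mc, train_config(max_epochs = 2, seed = 5))
  dir <- tempfile("ckpt")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(m2$params, m$params)
  p1 <- predict(m, ds)
  p2 <- predict(m2, ds)
  expect_identical(as.vector(p1), as.vector(p2))
  # schema validation
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"))
  cfgj$schema <- "bogus"
  jsonlite::write_json(cfgj, file.path(dir, "config.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "schema")
  unlink(dir, recursive = TRUE)
})

test_that("predict refuses transform mismatches and is order-equivariant", {
  cfg <- synth_config(n_genes = 10, length_range = c(70, 80), seed = 22,
                      depth = 800)
  genes <- generate_genes(cfg)
  sim <- simulate_density(genes, cfg)
  cd <- codon_density(sim$track, genes)
  ds <- build_windows(genes, normalize_and_log(cd), normalize_gene_mean(cd),
                      W = 3)
  sp <- split_dataset(ds, "fraction", seed = 1)
  mc <- model_config(W = 3, embed_dim = 3, conv_blocks = 1, conv_kernel = 3,
                     filters = 4, attention_heads = 1, key_dim = 2)
  m <- train_model(ds, sp, mc, train_config(max_epochs = 1, seed = 5))
  pred <- predict(m, ds)
  expect_length(pred, n_instances(ds))
  expect_length(predict(m, subset_windows(ds, 1L)), 1L)
  # shuffling instances permutes predictions identically
  perm <- sample(n_instances(ds))
  expect_equal(as.vector(predict(m, subset_windows(ds, perm))),
               as.vector(pred)[perm], tolerance = 1e-12)
  ds_bad <- ds
  ds_bad$target_transform <- "log"
  expect_error(predict(m, ds_bad), "transform mismatch")
  ds_bad2 <- ds
  ds_bad2$ref_transform <- "raw"
  expect_error(predict(m, ds_bad2), "transform mismatch")
})

test_that("evaluate_predictions implements the standard definitions", {
  x <- c(1, 2, 3, 4)
  expect_equal(evaluate_predictions(x, x),
               list(pearson = 1, spearman = 1, mse = 0))
  expect_equal(evaluate_predictions(x, -x)$pearson, -1)
  expect_equal(evaluate_predictions(c(1, 2, 3), c(3, 2, 1))$spearman, -1)
  expect_warning(ev <- evaluate_predictions(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(ev$pearson))
  expect_error(evaluate_predictions(1:2, 1:2), "at least 3")
})
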