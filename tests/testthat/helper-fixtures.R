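# Fixtures built in code and independent brute-force oracles used by the
# unit and acceptance tests. Oracles deliberately avoid the package's own
# computational path (plain nested loops, enumeration via choose()).

make_gene_set <- function(seqs) {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  })), tmp)
  on.exit(unlink(tmp))
  read_cds_fasta(tmp)
}

# a track from explicit per-gene nt vectors
make_track <- function(counts, condition = "c1", replicate = NULL) {
  ribocast:::new_profile_track(counts, condition, replicate)
}

make_codon_density <- function(values, transform = "raw") {
  ribocast:::new_codon_density(values, transform)
}

random_cds <- function(n_codons, seed) {
  ribocast:::with_seed(seed, {
    paste(c("ATG", sample(sense_codons(), n_codons - 2L, replace = TRUE),
            sample(stop_codons(), 1L)), collapse = "")
  })
}

## ---- brute-force convolution oracle (Eq-style nested loops) ----
# x: (L, E, Cin) single instance; W taps ordered (dm, dn, cin); SAME pad.
oracle_conv2d <- function(x, W, b, kh, kw) {
  L <- dim(x)[1]; E <- dim(x)[2]; Cin <- dim(x)[3]
  Fo <- ncol(W)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  out <- array(0, c(L, E, Fo))
  for (f in seq_len(Fo)) {
    for (i in seq_len(L)) {
      for (e in seq_len(E)) {
        acc <- b[f]
        for (dm in seq_len(kh)) {
          for (dn in seq_len(kw)) {
            ii <- i + dm - 1 - ph
            ee <- e + dn - 1 - pw
            if (ii >= 1 && ii <= L && ee >= 1 && ee <= E) {
              for (cc in seq_len(Cin)) {
                wrow <- ((dm - 1) * kw + (dn - 1)) * Cin + cc
                acc <- acc + x[ii, ee, cc] * W[wrow, f]
              }
            }
          }
        }
        out[i, e, f] <- acc
      }
    }
  }
  out
}

oracle_conv1d <- function(x, W, b, k) {
  L <- dim(x)[1]; Cin <- dim(x)[2]
  Fo <- ncol(W)
  p <- (k - 1) %/% 2
  out <- array(0, c(L, Fo))
  for (f in seq_len(Fo)) {
    for (i in seq_len(L)) {
      acc <- b[f]
      for (dm in seq_len(k)) {
        ii <- i + dm - 1 - p
        if (ii >= 1 && ii <= L) {
          for (cc in seq_len(Cin)) {
            acc <- acc + x[ii, cc] * W[(dm - 1) * Cin + cc, f]
          }
        }
      }
      out[i, f] <- acc
    }
  }
  out
}

## ---- brute-force attention oracle (O(L^2) loops per head) ----
# x: (L, C) single instance; returns (L, H*K) concatenated head outputs.
oracle_attention <- function(x, Wq, Wk, Wv, H, K) {
  L <- nrow(x)
  out <- matrix(0, L, H * K)
  for (h in seq_len(H)) {
    cols <- (h - 1) * K + seq_len(K)
    q <- x %*% Wq[, cols, drop = FALSE]
    kk <- x %*% Wk[, cols, drop = FALSE]
    v <- x %*% Wv[, cols, drop = FALSE]
    for (i in seq_len(L)) {
      s <- numeric(L)
      for (j in seq_len(L)) s[j] <- sum(q[i, ] * kk[j, ]) / sqrt(K)
      a <- exp(s - max(s))
      a <- a / sum(a)
      hi <- numeric(K)
      for (j in seq_len(L)) hi <- hi + a[j] * v[j, ]
      out[i, cols] <- hi
    }
  }
  out
}

## ---- exact-test enumeration oracle via choose() ----
oracle_fisher_p <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lden <- lchoose(m + n, k)
  kk <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, kk) + lchoose(n, k - kk) - lden)
  pobs <- exp(lchoose(m, a) + lchoose(n, k - a) - lden)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# scaled-down model/training configs used by training-based tests; the
# package defaults keep the published architecture.
desk_model_config <- function(W = 5L) {
  model_config(W = W, embed_dim = 4L, conv_blocks = 3L, conv_kernel = 5L,
               filters = 8L, attention_heads = 2L, key_dim = 4L,
               dropout = 0.1)
}

desk_train_config <- function(seed, max_epochs = 30L, batch_size = 512L,
                              start_lr = 2e-3) {
  train_config(start_lr = start_lr, batch_size = batch_size,
               max_epochs = max_epochs, patience = 10L, seed = seed)
}

# build a WindowDataset from a synthetic world with target
# f(center codon, reference) applied to the gene-mean-normalized reference
planted_target_dataset <- function(cfg, genes, sim, f_center, W = 5L) {
  cd <- codon_density(sim$track, genes)
  ref_log <- normalize_and_log(cd)
  ref_lin <- normalize_gene_mean(cd)
  dw <- cfg$dwell
  tgt_vals <- lapply(names(ref_lin$values), function(id) {
    f_center(genes$codons[[id]], ref_lin$values[[id]])
  })
  names(tgt_vals) <- names(ref_lin$values)
  tgt <- make_codon_density(tgt_vals, "gene_mean_normalized")
  build_windows(genes, ref_log, tgt, W = W)
}
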