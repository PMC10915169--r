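# In silico mutagenesis: sequence impact scores (SIS), clustering of SIS
# profiles, and per-cluster codon enrichment.
#
# Sign convention: SIS = RD - RD', the original prediction minus the mean
# prediction over randomly mutated windows. Mutating away a causal stall
# motif lowers the prediction, so causal positions carry the *largest* SIS
# under this convention (profiles are sometimes plotted with the opposite
# sign, as mutant-minus-original).

predictor_fn <- function(model, mask_ref = FALSE) {
  if (is.function(model)) return(model)
  abort_if(!inherits(model, "ribocast_model"),
           "model must be a ribocast_model or a function(seq_mat, ref_mat)")
  abort_if(is.null(model$params), "untrained model")
  function(seq_mat, ref_mat) {
    predict_batched(model$params, model$bn, model$config, seq_mat, ref_mat,
                    mask_ref || model$mask_ref)
  }
}

#' Sequence impact score profile of one site
#'
#' Slides a `mut_window`-codon mutation window across the `2W+1`-codon input
#' window. At each placement the window is replaced by `n_samples` random
#' sequences (codons drawn uniformly from the 61 sense codons), the model
#' prediction is averaged over the samples (`RD'`), and the window's score
#' is `RD - RD'`. The per-codon SIS is the mean over the placements covering
#' that codon (edge codons are covered by fewer placements; `n_windows`
#' records how many).
#'
#' @param model a `ribocast_model`, or any `function(seq_mat, ref_mat)`
#'   returning one prediction per row (useful for synthetic ground-truth
#'   models).
#' @param seq_window integer vector of codon indices (length `2W+1`).
#' @param ref_window numeric vector of log reference densities, same length.
#' @param mut_window mutation window width in codons.
#' @param n_samples random sequences per placement.
#' @param seed integer seed for the mutant draws.
#' @return a `SISProfile`: list with `position` (-W..W), `sis`, `n_windows`,
#'   `rd` (the unmutated prediction) and `window_sis` per placement.
#' @export
compute_sis <- function(model, seq_window, ref_window, mut_window = 10L,
                        n_samples = 100L, seed = 1L) {
  f <- predictor_fn(model)
  L <- length(seq_window)
  abort_if(length(ref_window) != L, "seq/ref length mismatch")
  abort_if(mut_window < 1L || mut_window > L,
           "mut_window must be in 1..window length")
  n_place <- L - mut_window + 1L
  rd <- as.numeric(f(matrix(seq_window, nrow = 1L),
                     matrix(ref_window, nrow = 1L)))
  sense_idx <- sense_codon_indices()
  muts <- with_seed(seed, {
    m <- matrix(rep(seq_window, each = n_place * n_samples),
                nrow = n_place * n_samples)
    for (s in seq_len(n_place)) {
      rows <- (s - 1L) * n_samples + seq_len(n_samples)
      m[rows, s:(s + mut_window - 1L)] <-
        sample(sense_idx, n_samples * mut_window, replace = TRUE)
    }
    m
  })
  refs <- matrix(rep(ref_window, each = nrow(muts)), nrow = nrow(muts))
  preds <- as.numeric(f(muts, refs))
  rdp <- vapply(seq_len(n_place), function(s) {
    mean(preds[(s - 1L) * n_samples + seq_len(n_samples)])
  }, numeric(1))
  window_sis <- rd - rdp
  sis <- numeric(L)
  n_windows <- integer(L)
  for (j in seq_len(L)) {
    cover <- seq.int(max(1L, j - mut_window + 1L), min(j, n_place))
    cover <- cover[cover >= 1L & cover <= n_place]
    n_windows[j] <- length(cover)
    sis[j] <- if (length(cover)) mean(window_sis[cover]) else NA_real_
  }
  W <- (L - 1L) %/% 2L
  structure(list(position = seq.int(-W, W), sis = sis,
                 n_windows = n_windows, rd = as.numeric(rd),
                 window_sis = window_sis, mut_window = mut_window,
                 n_samples = n_samples, seed = seed),
            class = "SISProfile")
}

#' SIS profiles for many sites
#'
#' @param model as in [compute_sis()].
#' @param ds a `WindowDataset` whose instances are the sites.
#' @param idx instance indices (default all).
#' @inheritParams compute_sis
#' @return matrix (sites x positions) of per-codon SIS, with the site
#'   provenance in rownames (`gene:center`).
#' @export
compute_sis_matrix <- function(model, ds, idx = seq_len(n_instances(ds)),
                               mut_window = 10L, n_samples = 100L,
                               seed = 1L) {
  out <- t(vapply(seq_along(idx), function(k) {
    i <- idx[k]
    compute_sis(model, ds$seq[i, ], ds$ref[i, ], mut_window, n_samples,
                seed = seed + k - 1L)$sis
  }, numeric(ncol(ds$seq))))
  rownames(out) <- paste0(ds$gene[idx], ":", ds$center_index[idx])
  out
}

#' Cluster SIS profiles with K-means
#'
#' When `k` is not given it is chosen by the elbow method, automated as the
#' maximum second difference of the inertia (total within-cluster sum of
#' squares) curve over `k_range`. Deterministic given `seed` (default 0).
#' Missing positions are imputed as 0 (flagged in the `imputed` attribute).
#' Labels are 0-based (0..k-1).
#'
#' @param profiles matrix (sites x positions) or list of `SISProfile`s.
#' @param k number of clusters, or `NULL` for elbow selection.
#' @param seed RNG seed for K-means.
#' @param k_range candidate k values for the elbow method.
#' @param nstart K-means restarts.
#' @return a `ClusterSet`: list with `k`, `labels` (0-based), `centers`,
#'   `inertia` (data frame k, inertia) and `seed`.
#' @export
cluster_sis <- function(profiles, k = NULL, seed = 0L, k_range = 2:15,
                        nstart = 10L) {
  X <- if (is.list(profiles) && !is.matrix(profiles)) {
    do.call(rbind, lapply(profiles, `[[`, "sis"))
  } else {
    as.matrix(profiles)
  }
  imputed <- any(is.na(X))
  X[is.na(X)] <- 0
  abort_if(!is.null(k) && nrow(X) < k, "fewer profiles than clusters")
  if (all(apply(X, 2L, function(col) length(unique(col)) == 1L))) {
    warning("all profiles identical; degenerate clustering with k = 1",
            call. = FALSE)
    return(structure(list(k = 1L, labels = rep(0L, nrow(X)),
                          centers = X[1, , drop = FALSE],
                          inertia = data.frame(k = 1L, inertia = 0),
                          seed = as.integer(seed)),
                     class = "ClusterSet"))
  }
  k_range <- k_range[k_range <= nrow(X)]
  inertia <- data.frame(k = integer(), inertia = double())
  if (is.null(k) || length(k_range)) {
    inertia <- data.frame(
      k = k_range,
      inertia = vapply(k_range, function(kk) {
        with_seed(seed, stats::kmeans(X, kk, nstart = nstart,
                                      iter.max = 100L)$tot.withinss)
      }, numeric(1)))
  }
  if (is.null(k)) {
    abort_if(length(k_range) < 3L, "k_range too small for elbow selection")
    d2 <- diff(diff(inertia$inertia))  # second difference; elbow = max
    k <- inertia$k[which.max(d2) + 1L]
  }
  km <- with_seed(seed, stats::kmeans(X, k, nstart = nstart, iter.max = 100L))
  structure(list(k = as.integer(k), labels = km$cluster - 1L,
                 centers = km$centers, inertia = inertia,
                 seed = as.integer(seed), imputed = imputed),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("<ClusterSet> k=%d, sizes: %s\n", x$k,
              paste(tabulate(x$labels + 1L, x$k), collapse = ", ")))
  invisible(x)
}

# vectorised Welch t-test over matrix columns; returns two-sided p
welch_p_cols <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- colSums(sweep(X, 2L, mx)^2) / (nx - 1)
  vy <- colSums(sweep(Y, 2L, my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 0)
  list(p = p, sign = sign(mx - my))
}

#' Per-cluster positional codon enrichment
#'
#' For each cluster and each (sense codon, window position) pair, compares
#' the codon's occurrence indicator across the cluster's sites against
#' `n_background` random codon sequences (uniform over sense codons by
#' default, or drawn from `usage` weights) with a two-sample t-test. Scores
#' are `sign(enrichment) * -log10(p)` with the p-value floored at 1e-300.
#'
#' @param clusters a `ClusterSet` from [cluster_sis()].
#' @param site_seqs integer matrix (sites x positions) of codon indices
#'   aligned with the clustered profiles.
#' @param n_background number of random background sequences.
#' @param seed integer seed.
#' @param usage optional named codon-usage weights over the sense codons.
#' @return named list (one `61 x positions` signed score matrix per
#'   cluster; all-NA matrix for clusters with fewer than 3 sites).
#' @export
cluster_codon_enrichment <- function(clusters, site_seqs,
                                     n_background = 500L, seed = 1L,
                                     usage = NULL) {
  abort_if(nrow(site_seqs) != length(clusters$labels),
           "site_seqs rows must match clustered profiles")
  L <- ncol(site_seqs)
  sc <- sense_codons()
  sidx <- sense_codon_indices()
  prob <- if (is.null(usage)) NULL else unname(usage[sc] / sum(usage[sc]))
  bg <- with_seed(seed, matrix(sample(sidx, n_background * L, replace = TRUE,
                                      prob = prob),
                               nrow = n_background))
  W <- (L - 1L) %/% 2L
  out <- lapply(seq_len(clusters$k) - 1L, function(cl) {
    rows <- which(clusters$labels == cl)
    mat <- matrix(NA_real_, length(sc), L,
                  dimnames = list(sc, seq.int(-W, W)))
    if (length(rows) < 3L) return(mat)
    S <- site_seqs[rows, , drop = FALSE]
    for (ci in seq_along(sc)) {
      X <- (S == sidx[ci]) + 0
      Y <- (bg == sidx[ci]) + 0
      wt <- welch_p_cols(X, Y)
      mat[ci, ] <- wt$sign * -log10(pmax(wt$p, 1e-300))
    }
    mat
  })
  names(out) <- paste0("cluster", seq_len(clusters$k) - 1L)
  out
}

#' Export SIS profiles / cluster labels / enrichment matrices as TSV
#'
#' @param x SIS matrix, `ClusterSet`, or enrichment matrix list.
#' @param path output path (a prefix for enrichment lists:
#'   `<path>.clusterN.tsv`).
#' @return `path`, invisibly.
#' @export
export_sis_tsv <- function(x, path) {
  if (inherits(x, "ClusterSet")) {
    data.table::fwrite(data.table::data.table(site_id = seq_along(x$labels),
                                              cluster = x$labels),
                       path, sep = "\t")
  } else if (is.list(x) && !is.matrix(x)) {
    for (nm in names(x)) {
      dt <- data.table::as.data.table(x[[nm]], keep.rownames = "codon")
      data.table::fwrite(dt, paste0(path, ".", nm, ".tsv"), sep = "\t")
    }
  } else {
    dt <- data.table::as.data.table(as.matrix(x), keep.rownames = "site_id")
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}
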