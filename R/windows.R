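# Model-ready window datasets: one instance per retained codon whose full
# +/-W context lies inside the CDS. seq is an n x (2W+1) integer matrix of
# codon indices (0..63), ref the matching log reference densities, target the
# center-codon density in the target condition.

#' Build (sequence window, reference window, target) training instances
#'
#' For each gene, valid center codons `i` (0-based) satisfy
#' `i >= max(trim, W)` and `i <= len - 1 - max(trim, W)`: the first/last
#' `trim` codons are excluded and no window crosses a gene boundary. Genes
#' too short to host any center contribute no instances.
#'
#' @param genes a `GeneSet`.
#' @param ref_cd reference `CodonDensity`, `transform = "log"`.
#' @param target_cd target `CodonDensity` (any transform; recorded).
#' @param W half-window in codons (default 20, i.e. 41-codon windows).
#' @param trim end trim in codons (default 10).
#' @return a `WindowDataset`: list with integer matrix `seq`, numeric matrix
#'   `ref`, numeric `target`, provenance `gene`/`center_index`, and metadata
#'   `W`, `ref_transform`, `target_transform`, `pseudocount`.
#' @export
build_windows <- function(genes, ref_cd, target_cd, W = 20L, trim = 10L) {
  abort_if(W < 1, "W must be >= 1")
  abort_if(ref_cd$transform != "log",
           "reference densities must be log-transformed (got ",
           ref_cd$transform, ")")
  ids <- Reduce(intersect, list(gene_ids(genes), names(ref_cd$values),
                                names(target_cd$values)))
  abort_if(!length(ids), "no genes shared by genes, ref_cd and target_cd")
  W <- as.integer(W)
  L <- 2L * W + 1L
  margin <- max(as.integer(trim), W)
  parts <- lapply(ids, function(id) {
    len <- length(genes$codons[[id]])
    abort_if(length(ref_cd$values[[id]]) != len ||
               length(target_cd$values[[id]]) != len,
             "density length mismatch for gene '", id, "'")
    lo <- margin
    hi <- len - 1L - margin
    if (hi < lo) return(NULL)
    centers <- seq.int(lo, hi)
    offs <- seq.int(-W, W)
    pos <- outer(centers, offs, `+`)  # n x L, 0-based codon positions
    idx <- codon_index(genes$codons[[id]])
    list(seq = matrix(idx[pos + 1L], nrow = length(centers)),
         ref = matrix(ref_cd$values[[id]][pos + 1L], nrow = length(centers)),
         target = target_cd$values[[id]][centers + 1L],
         gene = rep(id, length(centers)),
         center = centers)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  abort_if(!length(parts), "no gene long enough to contribute instances")
  structure(list(
    seq = do.call(rbind, lapply(parts, `[[`, "seq")),
    ref = do.call(rbind, lapply(parts, `[[`, "ref")),
    target = unlist(lapply(parts, `[[`, "target"), use.names = FALSE),
    gene = unlist(lapply(parts, `[[`, "gene"), use.names = FALSE),
    center_index = unlist(lapply(parts, `[[`, "center"), use.names = FALSE),
    W = W, trim = as.integer(trim),
    ref_transform = ref_cd$transform,
    target_transform = target_cd$transform,
    pseudocount = ref_cd$pseudocount
  ), class = "WindowDataset")
}

#' @export
print.WindowDataset <- function(x, ...) {
  cat(sprintf("<WindowDataset> %d instances, W=%d, target=%s\n",
              nrow(x$seq), x$W, x$target_transform))
  invisible(x)
}

#' Number of instances in a WindowDataset
#' @param ds a `WindowDataset`.
#' @return integer.
#' @export
n_instances <- function(ds) nrow(ds$seq)

#' Subset a WindowDataset by instance index
#' @param ds a `WindowDataset`.
#' @param idx integer indices.
#' @return a `WindowDataset`.
#' @export
subset_windows <- function(ds, idx) {
  out <- ds
  out$seq <- ds$seq[idx, , drop = FALSE]
  out$ref <- ds$ref[idx, , drop = FALSE]
  out$target <- ds$target[idx]
  out$gene <- ds$gene[idx]
  out$center_index <- ds$center_index[idx]
  out
}

#' Split instances into train/validation/test sets or k folds
#'
#' `fraction` mode uses 70/15/15 proportions (sizes within one instance of
#' the stated fractions); `kfold` mode yields `k` near-equal disjoint folds.
#' Assignment is deterministic given `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param ds a `WindowDataset` (or anything with [n_instances()]).
#' @param mode `"fraction"` or `"kfold"`.
#' @param seed integer seed.
#' @param fractions train/validation/test proportions (fraction mode).
#' @param k number of folds (kfold mode).
#' @return a `DatasetSplit`: list with `mode`, `seed` and `assignment`
#'   (character `"train"/"validation"/"test"`, or integer fold 1..k).
#' @export
split_dataset <- function(ds, mode = c("fraction", "kfold"), seed,
                          fractions = c(train = 0.70, validation = 0.15,
                                        test = 0.15),
                          k = 10L) {
  mode <- match.arg(mode)
  n <- n_instances(ds)
  abort_if(n < 1, "dataset is empty")
  assignment <- with_seed(seed, {
    if (mode == "fraction") {
      abort_if(abs(sum(fractions) - 1) > 1e-8, "fractions must sum to 1")
      n_tr <- round(fractions[["train"]] * n)
      n_va <- round(fractions[["validation"]] * n)
      n_te <- n - n_tr - n_va
      abort_if(n_te < 0, "fractions leave no room for a test set")
      lab <- rep(c("train", "validation", "test"), c(n_tr, n_va, n_te))
      lab[sample.int(n)] <- lab
      lab
    } else {
      abort_if(k > n, "k (", k, ") exceeds instance count (", n, ")")
      fold <- rep(seq_len(k), length.out = n)
      fold[sample.int(n)] <- fold
      fold
    }
  })
  structure(list(mode = mode, seed = as.integer(seed), k = if (mode == "kfold") as.integer(k) else NULL,
                 assignment = assignment),
            class = "DatasetSplit")
}
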