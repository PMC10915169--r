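# Codon-resolution densities and pause scores. The per-codon value is the sum
# of footprint counts over the codon's three nucleotides. Per-gene statistics
# exclude the first and last `trim` codons (default 10) to avoid the atypical
# counts at the beginnings and ends of genes.

new_codon_density <- function(values, transform, pseudocount = NA_real_,
                              condition = NA_character_) {
  structure(list(values = values, transform = transform,
                 pseudocount = pseudocount, condition = condition),
            class = "CodonDensity")
}

#' @export
print.CodonDensity <- function(x, ...) {
  cat(sprintf("<CodonDensity> %d genes, transform=%s\n",
              length(x$values), x$transform))
  invisible(x)
}

# indices (1-based) of retained codons of a gene of length `len`
retained_idx <- function(len, trim = 10L) {
  if (len <= 2L * trim) return(integer(0))
  seq.int(trim + 1L, len - trim)
}

#' Collapse a nucleotide track to per-codon densities
#'
#' Each codon's value is the sum of the footprint counts at its three
#' nucleotides.
#'
#' @param track a `ProfileTrack` whose vectors are length-consistent with
#'   `genes` (3 x codons).
#' @param genes a `GeneSet`; only its genes are collapsed.
#' @return a `CodonDensity` with `transform = "raw"`.
#' @export
codon_density <- function(track, genes) {
  ids <- gene_ids(genes)
  values <- lapply(ids, function(id) {
    v <- track$counts[[id]]
    abort_if(is.null(v), "gene '", id, "' not covered by track")
    len <- length(genes$codons[[id]])
    abort_if(length(v) != 3L * len,
             "length mismatch for gene '", id, "': track ", length(v),
             " nt vs ", 3L * len, " nt expected")
    unname(colSums(matrix(v, nrow = 3L)))
  })
  names(values) <- ids
  new_codon_density(values, "raw", condition = track$condition)
}

gene_mean_retained <- function(values, trim = 10L) {
  vapply(values, function(v) {
    idx <- retained_idx(length(v), trim)
    if (!length(idx)) NA_real_ else mean(v[idx])
  }, numeric(1))
}

#' Gene-mean normalization of codon densities
#'
#' Divides each gene's codon values by the gene's mean over retained codons
#' (first/last `trim` excluded from the mean), making genes of different
#' expression comparable. Genes whose retained mean is zero (or that are too
#' short to retain any codon) are dropped with a warning.
#'
#' @param cd a raw `CodonDensity`.
#' @param trim codons trimmed from each gene end for the mean (default 10).
#' @return a `CodonDensity` with `transform = "gene_mean_normalized"`.
#' @export
normalize_gene_mean <- function(cd, trim = 10L) {
  abort_if(cd$transform != "raw", "expected raw densities, got ", cd$transform)
  m <- gene_mean_retained(cd$values, trim)
  drop <- is.na(m) | m == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " gene(s) with zero/undefined retained mean",
            call. = FALSE)
  }
  vals <- Map(`/`, cd$values[!drop], m[!drop])
  new_codon_density(vals, "gene_mean_normalized", condition = cd$condition)
}

#' Normalize and log-transform codon densities
#'
#' Computes `log2(value / gene_mean + pseudocount)` per codon, where the gene
#' mean is taken over retained codons. This is the reference-branch input
#' scale of the model.
#'
#' @param cd a raw `CodonDensity`.
#' @param pseudocount added before the log (default 0.5).
#' @param trim codons trimmed from each gene end for the mean (default 10).
#' @return a `CodonDensity` with `transform = "log"`.
#' @export
normalize_and_log <- function(cd, pseudocount = 0.5, trim = 10L) {
  norm <- normalize_gene_mean(cd, trim)
  vals <- lapply(norm$values, function(v) log2(v + pseudocount))
  out <- new_codon_density(vals, "log", pseudocount = pseudocount,
                           condition = cd$condition)
  out
}

#' Codon pause scores
#'
#' The pause score of a codon instance is its density divided by the mean
#' density over the retained codons of its ORF (>1 means slower-than-average
#' decoding). Per codon type, the score is the mean over all instances;
#' codon-type scores are z-scored across the observed sense codon types
#' (stops excluded), and amino-acid scores aggregate synonymous codons before
#' z-scoring across the 20 amino acids.
#'
#' @param cd a raw `CodonDensity`.
#' @param genes the matching `GeneSet`.
#' @param trim codons trimmed from each gene end (default 10); trimmed codons
#'   contribute neither instances nor to the ORF mean.
#' @return a `PauseScoreTable`: list with `instances` (gene, codon_index,
#'   codon, score), `codon` (61 sense codon types: n, mean_score, z; NA when
#'   unobserved) and `aa` (20 amino acids) data frames.
#' @export
pause_scores <- function(cd, genes, trim = 10L) {
  abort_if(cd$transform != "raw", "expected raw densities, got ", cd$transform)
  ids <- intersect(gene_ids(genes), names(cd$values))
  abort_if(!length(ids), "no overlap between genes and densities")
  inst <- lapply(ids, function(id) {
    v <- cd$values[[id]]
    len <- length(genes$codons[[id]])
    abort_if(length(v) != len, "codon count mismatch for gene '", id, "'")
    idx <- retained_idx(len, trim)
    if (!length(idx)) return(NULL)
    m <- mean(v[idx])
    if (m == 0) return(NULL)
    data.frame(gene = id, codon_index = idx - 1L,
               codon = genes$codons[[id]][idx],
               score = v[idx] / m, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(inst, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " gene(s) dropped (zero retained mean or too short)",
            call. = FALSE)
  }
  instances <- do.call(rbind, inst)
  abort_if(is.null(instances), "no scorable codon instances")

  zscore <- function(x) {
    obs <- !is.na(x)
    z <- rep(NA_real_, length(x))
    if (sum(obs) >= 1L) {
      s <- stats::sd(x[obs])
      z[obs] <- if (is.na(s) || s == 0) 0 else (x[obs] - mean(x[obs])) / s
    }
    z
  }

  sc <- sense_codons()
  keep <- instances$codon %in% sc
  mean_by <- tapply(instances$score[keep], factor(instances$codon[keep], levels = sc), mean)
  n_by <- tapply(instances$score[keep], factor(instances$codon[keep], levels = sc), length)
  codon_tab <- data.frame(codon = sc, aa = codon_to_aa(sc),
                          n = as.integer(ifelse(is.na(n_by), 0L, n_by)),
                          mean_score = as.numeric(mean_by),
                          stringsAsFactors = FALSE)
  codon_tab$z <- zscore(codon_tab$mean_score)

  aas <- sort(unique(codon_to_aa(sc)))
  aa_of_inst <- codon_to_aa(instances$codon[keep])
  aa_mean <- tapply(instances$score[keep], factor(aa_of_inst, levels = aas), mean)
  aa_n <- tapply(instances$score[keep], factor(aa_of_inst, levels = aas), length)
  aa_tab <- data.frame(aa = aas,
                       n = as.integer(ifelse(is.na(aa_n), 0L, aa_n)),
                       mean_score = as.numeric(aa_mean),
                       stringsAsFactors = FALSE)
  aa_tab$z <- zscore(aa_tab$mean_score)

  structure(list(instances = instances, codon = codon_tab, aa = aa_tab,
                 trim = trim),
            class = "PauseScoreTable")
}

#' @export
print.PauseScoreTable <- function(x, ...) {
  cat(sprintf("<PauseScoreTable> %d instances, %d/%d codon types observed\n",
              nrow(x$instances), sum(x$codon$n > 0), nrow(x$codon)))
  invisible(x)
}

#' Export per-codon values as TSV
#'
#' Fixed column order (`gene_id`, `codon_index`, `value`), 6-decimal
#' fixed-point formatting.
#'
#' @param cd a `CodonDensity`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_codon_density <- function(cd, path) {
  dt <- data.table::rbindlist(lapply(names(cd$values), function(id) {
    v <- cd$values[[id]]
    data.table::data.table(gene_id = id,
                           codon_index = seq_along(v) - 1L,
                           value = sprintf("%.6f", v))
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Export a PauseScoreTable as TSV
#' @param pst a `PauseScoreTable`.
#' @param path output path for the per-instance table.
#' @return `path`, invisibly.
#' @export
export_pause_scores <- function(pst, path) {
  dt <- data.table::data.table(gene_id = pst$instances$gene,
                               codon_index = pst$instances$codon_index,
                               value = sprintf("%.6f", pst$instances$score))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
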