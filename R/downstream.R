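# Interpretive analyses on measured or predicted densities: translation
# efficiency, positional codon enrichment, and differential pause-site
# detection with an exact conditional test.

#' Translation efficiency table
#'
#' TE = mean ribosome density (RD) / mRNA abundance (FPKM), computed on the
#' gene intersection of the two inputs. Genes with FPKM = 0 are excluded and
#' counted in the `n_zero_fpkm` attribute.
#'
#' @param rd_by_gene named numeric vector of mean ribosome densities.
#' @param fpkm_by_gene named numeric vector of FPKM values.
#' @return data frame (gene, RD, FPKM, TE).
#' @export
translation_efficiency <- function(rd_by_gene, fpkm_by_gene) {
  ids <- intersect(names(rd_by_gene), names(fpkm_by_gene))
  abort_if(!length(ids), "no genes shared between RD and FPKM inputs")
  rd <- rd_by_gene[ids]
  fpkm <- fpkm_by_gene[ids]
  zero <- fpkm == 0
  out <- data.frame(gene = ids[!zero], RD = unname(rd[!zero]),
                    FPKM = unname(fpkm[!zero]),
                    TE = unname(rd[!zero] / fpkm[!zero]),
                    stringsAsFactors = FALSE)
  attr(out, "n_zero_fpkm") <- sum(zero)
  out
}

#' Mean ribosome density per gene
#' @param track a `ProfileTrack`.
#' @return named numeric vector (mean reads per nt).
#' @export
mean_density_by_gene <- function(track) {
  vapply(track$counts, mean, numeric(1))
}

# Welch t-test p-value robust to zero-variance inputs: identical constant
# samples give t = 0 / p = 1, separated constants give p = 0.
welch_p <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * stats::pt(-abs(t), df)
}

#' Positional enrichment of a codon in a gene group
#'
#' Counts occurrences of `codon` in consecutive `window`-codon windows over
#' the first `first_n_codons` codons of each gene in `group`, and compares
#' each window's per-gene counts against size-matched random gene groups
#' drawn from `background` (two-sample t-test). Typical use: genes in the
#' highest/lowest TE deciles vs all genes.
#'
#' @param group a `GeneSet` (the group of interest, >= 3 genes).
#' @param background a `GeneSet` to sample comparison groups from.
#' @param codon codon string, e.g. `"CCA"`.
#' @param window window width in codons.
#' @param first_n_codons region analyzed from the start of each CDS.
#' @param n_resample number of random background groups; reported p-values
#'   average over resamples.
#' @param seed integer seed.
#' @return data frame (window, start, end, p) with one row per window;
#'   attribute `p_matrix` holds the per-resample p-values.
#' @export
positional_codon_enrichment <- function(group, background, codon,
                                        window = 10L, first_n_codons = 100L,
                                        n_resample = 20L, seed = 1L) {
  abort_if(n_genes(group) < 3, "group must contain at least 3 genes")
  starts <- seq.int(1L, first_n_codons, by = window)
  count_windows <- function(codons) {
    vapply(starts, function(s) {
      e <- min(s + window - 1L, first_n_codons, length(codons))
      if (s > length(codons)) 0L else sum(codons[s:e] == codon)
    }, integer(1))
  }
  grp <- vapply(group$codons, count_windows, integer(length(starts)))
  grp <- matrix(grp, nrow = length(starts))  # windows x genes
  bg_all <- background$codons
  n_grp <- n_genes(group)
  abort_if(length(bg_all) < n_grp, "background smaller than group")
  pmat <- with_seed(seed, {
    vapply(seq_len(n_resample), function(r) {
      pick <- sample(names(bg_all), n_grp)
      bg <- vapply(bg_all[pick], count_windows, integer(length(starts)))
      bg <- matrix(bg, nrow = length(starts))
      vapply(seq_along(starts), function(w) welch_p(grp[w, ], bg[w, ]),
             numeric(1))
    }, numeric(length(starts)))
  })
  pmat <- matrix(pmat, nrow = length(starts))
  out <- data.frame(window = seq_along(starts), start = starts,
                    end = pmin(starts + window - 1L, first_n_codons),
                    p = rowMeans(pmat))
  attr(out, "p_matrix") <- pmat
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: the two-sided p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within a relative tolerance
#' of 1e-7). The odds ratio is the sample odds ratio `(a*d)/(b*c)`, reported
#' as `Inf` when `b*c = 0` and `a*d > 0`.
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` read row-wise.
#' @return list with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(c(3, 1, 1, 3))  # p = 34/70
fisher_exact_2x2 <- function(table) {
  x <- if (is.matrix(table)) {
    abort_if(!all(dim(table) == 2L), "need a 2x2 table")
    c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    as.numeric(table)
  }
  abort_if(length(x) != 4L, "need a 2x2 table")
  abort_if(any(x < 0), "negative cell(s) in contingency table")
  abort_if(any(x != round(x)), "contingency table must be integer")
  abort_if(sum(x) == 0, "all-zero contingency table")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * cc)
  }
  m <- a + b; n <- cc + d; k <- a + cc
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= pobs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Detect condition-dependent pause sites
#'
#' For every retained codon of every shared gene, builds the 2x2 table
#' `[[case_at_pos, case_total - case_at_pos], [ctrl_at_pos, ctrl_total -
#' ctrl_at_pos]]` (totals at gene scope) from integer-rounded codon counts
#' and applies [fisher_exact_2x2()]. Sites with `p < alpha` and odds ratio
#' > 1 (enrichment in the case condition) are returned sorted by p-value.
#' Benjamini-Hochberg q-values over all tested positions are reported for
#' information only and never used for flagging.
#'
#' @param ctrl_cd,case_cd raw (count-scale) `CodonDensity` objects.
#' @param genes a `GeneSet`; genes absent from either condition are skipped
#'   with a warning.
#' @param alpha flagging threshold on the raw p-value.
#' @param trim codons excluded at each gene end.
#' @return data frame (gene, codon_index, a, b, c, d, odds_ratio, p, q)
#'   of flagged sites, sorted by p; attribute `n_tested` gives the number of
#'   positions tested.
#' @export
detect_pause_sites <- function(ctrl_cd, case_cd, genes, alpha = 0.001,
                               trim = 10L) {
  abort_if(ctrl_cd$transform != "raw" || case_cd$transform != "raw",
           "pause-site detection needs raw count-scale densities")
  ids <- gene_ids(genes)
  missing <- ids[!(ids %in% names(ctrl_cd$values) &
                     ids %in% names(case_cd$values))]
  if (length(missing)) {
    warning("skipping ", length(missing),
            " gene(s) absent from one condition", call. = FALSE)
  }
  ids <- setdiff(ids, missing)
  rows <- lapply(ids, function(id) {
    ctrl <- round_half_up(ctrl_cd$values[[id]])
    case <- round_half_up(case_cd$values[[id]])
    len <- length(genes$codons[[id]])
    abort_if(length(ctrl) != len || length(case) != len,
             "density length mismatch for gene '", id, "'")
    idx <- retained_idx(len, trim)
    if (!length(idx)) return(NULL)
    ctot <- sum(ctrl[idx]); katot <- sum(case[idx])
    if (ctot == 0 && katot == 0) return(NULL)
    res <- vapply(idx, function(i) {
      ft <- fisher_exact_2x2(c(case[i], katot - case[i],
                               ctrl[i], ctot - ctrl[i]))
      c(case[i], katot - case[i], ctrl[i], ctot - ctrl[i],
        ft$odds_ratio, ft$p_value)
    }, numeric(6))
    data.frame(gene = id, codon_index = idx - 1L,
               a = res[1, ], b = res[2, ], c = res[3, ], d = res[4, ],
               odds_ratio = res[5, ], p = res[6, ],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(gene = character(), codon_index = integer(),
                      a = numeric(), b = numeric(), c = numeric(),
                      d = numeric(), odds_ratio = numeric(), p = numeric())
  }
  tab$q <- if (nrow(tab)) stats::p.adjust(tab$p, "BH") else numeric(0)
  hits <- tab[tab$p < alpha & tab$odds_ratio > 1 &
                !is.nan(tab$odds_ratio), , drop = FALSE]
  hits <- hits[order(hits$p), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_tested") <- nrow(tab)
  hits
}

#' Write a pause-site table as TSV
#' @param sites data frame from [detect_pause_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pause_sites <- function(sites, path) {
  data.table::fwrite(
    data.table::as.data.table(sites[, c("gene", "codon_index", "a", "b",
                                        "c", "d", "odds_ratio", "p", "q")]),
    path, sep = "\t")
  invisible(path)
}
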