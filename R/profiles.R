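# ProfileTrack: per-gene dense vectors of footprint counts indexed by 0-based
# nt position within the CDS. Counts are assumed already assigned to a single
# ribosome-site position per footprint (A/P-site calibration is upstream).

new_profile_track <- function(counts, condition, replicate = NULL) {
  stopifnot(is.list(counts))
  abort_if(any(vapply(counts, function(v) any(v < 0), logical(1))),
           "negative counts are not allowed")
  structure(list(condition = as.character(condition),
                 replicate = if (is.null(replicate)) NULL else as.character(replicate),
                 counts = counts),
            class = "ProfileTrack")
}

#' @export
print.ProfileTrack <- function(x, ...) {
  cat(sprintf("<ProfileTrack> condition=%s%s, %d genes, %.0f reads\n",
              x$condition,
              if (is.null(x$replicate)) "" else paste0("/", x$replicate),
              length(x$counts), sum(unlist(x$counts, use.names = FALSE))))
  invisible(x)
}

#' Read a per-nucleotide footprint count table
#'
#' The profile dialect is tab-separated with the mandatory header
#' `gene_id<TAB>position<TAB>count`; `position` is 0-based within the CDS.
#' Unlisted positions are zero. When a `GeneSet` is supplied, vectors are
#' sized to `3 * length_codons` and positions are validated against it;
#' otherwise each vector extends to the largest observed position.
#'
#' @param path path to the TSV file.
#' @param condition condition label stored on the track.
#' @param replicate optional replicate label.
#' @param genes optional `GeneSet` used for validation and dense sizing.
#' @return a `ProfileTrack`.
#' @export
read_profile_table <- function(path, condition, replicate = NULL, genes = NULL) {
  abort_if(!file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  abort_if(!identical(names(dt), c("gene_id", "position", "count")),
           "expected header 'gene_id\\tposition\\tcount' in ", path)
  dt$gene_id <- as.character(dt$gene_id)
  abort_if(nrow(dt) > 0 && any(dt$count < 0), "negative count in ", path)
  counts <- list()
  if (nrow(dt) > 0) {
    by_gene <- split(dt[, c("position", "count")], dt$gene_id)
    counts <- lapply(names(by_gene), function(id) {
      d <- by_gene[[id]]
      len <- if (!is.null(genes)) {
        abort_if(!id %in% gene_ids(genes),
                 "gene '", id, "' in profile but not in GeneSet")
        3L * length(genes$codons[[id]])
      } else {
        max(d$position) + 1L
      }
      bad <- d$position >= len | d$position < 0
      abort_if(any(bad), "position out of range for gene '", id, "': ",
               paste(d$position[bad], collapse = ", "))
      v <- numeric(len)
      v[d$position + 1L] <- v[d$position + 1L] + d$count
      v
    })
    names(counts) <- names(by_gene)
  }
  new_profile_track(counts, condition, replicate)
}

#' Write a ProfileTrack in the profile TSV dialect
#'
#' Writes nonzero positions only (the reader treats unlisted positions as 0);
#' supply the `GeneSet` when re-reading to recover all-zero genes.
#'
#' @param track a `ProfileTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(track, path) {
  rows <- lapply(names(track$counts), function(id) {
    v <- track$counts[[id]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.table::data.table(gene_id = id, position = nz - 1L, count = v[nz])
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0) {
    dt <- data.table::data.table(gene_id = character(), position = integer(),
                                 count = numeric())
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Average replicate tracks position-wise
#'
#' Replicated experiments are combined by taking the mean occupancy at each
#' nucleotide.
#'
#' @param tracks list of `ProfileTrack`s with identical condition and gene
#'   coverage.
#' @return a `ProfileTrack` (replicate label `"mean"` when >1 input).
#' @export
average_replicates <- function(tracks) {
  if (inherits(tracks, "ProfileTrack")) tracks <- list(tracks)
  abort_if(length(tracks) < 1, "need at least one track")
  conds <- unique(vapply(tracks, `[[`, character(1), "condition"))
  abort_if(length(conds) > 1, "mixed conditions: ",
           paste(conds, collapse = ", "))
  if (length(tracks) == 1L) return(tracks[[1L]])
  ids <- lapply(tracks, function(t) sort(names(t$counts)))
  for (i in seq_along(tracks)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      diff <- union(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
      stop("gene sets differ between replicates: ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  avg <- lapply(ids[[1]], function(id) {
    vs <- lapply(tracks, function(t) t$counts[[id]])
    abort_if(length(unique(lengths(vs))) != 1,
             "replicate length mismatch for gene ", id)
    Reduce(`+`, vs) / length(vs)
  })
  names(avg) <- ids[[1]]
  new_profile_track(avg, conds, replicate = "mean")
}

mean_reads_per_nt <- function(track, ids = names(track$counts)) {
  vapply(ids, function(id) {
    v <- track$counts[[id]]
    abort_if(is.null(v), "gene '", id, "' not covered by track")
    mean(v)
  }, numeric(1))
}

#' Filter genes by length and ribosome coverage
#'
#' Retains genes whose CDS is at least `min_len_nt` nucleotides (default 200,
#' which avoids the 5' ramp) and whose mean footprint coverage is at least
#' `min_reads_per_nt` (boundary inclusive). Organism presets follow common
#' practice: 0.5 reads/nt for prokaryotes, 5 for eukaryotes.
#'
#' @param genes a `GeneSet`.
#' @param track a `ProfileTrack` covering every gene.
#' @param min_len_nt minimum CDS length in nt.
#' @param min_reads_per_nt coverage threshold; ignored when `preset` given.
#' @param preset `"prok"` (0.5) or `"euk"` (5), optional.
#' @return the filtered `GeneSet`, with attributes `preset` and
#'   `min_reads_per_nt` recording the threshold used.
#' @export
filter_genes <- function(genes, track, min_len_nt = 200,
                         min_reads_per_nt = 0.5, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("prok", "euk"))
    min_reads_per_nt <- c(prok = 0.5, euk = 5)[[preset]]
  }
  ids <- gene_ids(genes)
  len_nt <- 3L * gene_lengths(genes)
  dens <- mean_reads_per_nt(track, ids)
  keep <- len_nt >= min_len_nt & dens >= min_reads_per_nt
  if (!any(keep)) warning("filter_genes: no genes retained", call. = FALSE)
  out <- subset_genes(genes, ids[keep])
  attr(out, "preset") <- preset %||% "custom"
  attr(out, "min_reads_per_nt") <- min_reads_per_nt
  out
}

#' Select the genes with highest mean ribosome density
#'
#' Ties are broken by lexicographic gene id for determinism.
#'
#' @param genes a `GeneSet`.
#' @param track a `ProfileTrack` covering every gene.
#' @param n number of genes to keep (`n <=` gene count).
#' @return a `GeneSet` with `n` genes.
#' @export
top_genes_by_density <- function(genes, track, n) {
  abort_if(n > n_genes(genes), "n (", n, ") exceeds gene count (",
           n_genes(genes), ")")
  ids <- gene_ids(genes)
  dens <- mean_reads_per_nt(track, ids)
  ord <- order(-dens, ids)
  subset_genes(genes, ids[ord[seq_len(n)]])
}
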