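# GeneSet: named list of codon vectors (one entry per CDS), the carrier for
# all coding-sequence input. Coordinates throughout the package are 0-based
# within-CDS positions (nt) and 0-based codon indices.

new_gene_set <- function(codons) {
  stopifnot(is.list(codons))
  abort_if(is.null(names(codons)) || anyDuplicated(names(codons)) > 0,
           "gene ids must be present and unique")
  structure(list(codons = codons), class = "GeneSet")
}

#' Gene ids, counts and codon lengths of a GeneSet
#' @param genes a `GeneSet`.
#' @return `gene_ids()`: character vector; `n_genes()`: integer;
#'   `gene_lengths()`: named integer vector of lengths in codons.
#' @export
gene_ids <- function(genes) names(genes$codons)

#' @rdname gene_ids
#' @export
n_genes <- function(genes) length(genes$codons)

#' @rdname gene_ids
#' @export
gene_lengths <- function(genes) lengths(genes$codons)

#' Extract the codons of one gene
#' @param genes a `GeneSet`.
#' @param id gene id.
#' @return character vector of 3-mers.
#' @export
gene_codons <- function(genes, id) {
  abort_if(!id %in% gene_ids(genes), "unknown gene id: ", id)
  genes$codons[[id]]
}

#' Subset a GeneSet
#' @param genes a `GeneSet`.
#' @param ids gene ids to keep.
#' @return a `GeneSet`.
#' @export
subset_genes <- function(genes, ids) {
  abort_if(!all(ids %in% gene_ids(genes)), "unknown gene id(s) in subset")
  new_gene_set(genes$codons[ids])
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("<GeneSet> %d genes, %d..%d codons\n", n_genes(x),
              if (n_genes(x)) min(gene_lengths(x)) else 0L,
              if (n_genes(x)) max(gene_lengths(x)) else 0L))
  invisible(x)
}

split_into_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

#' Read coding sequences from a FASTA file
#'
#' One record per gene, CDS only, sense strand. Sequences are upper-cased and
#' `U` is mapped to `T`. Record ids are the first whitespace-delimited token
#' of the FASTA header.
#'
#' @param path path to a FASTA file.
#' @return a [GeneSet][gene_ids] of codon vectors.
#' @section Errors:
#' A sequence whose length is not divisible by 3, a duplicated id, or any
#' character outside `ACGTU` raises an error naming the offending record.
#' @export
read_cds_fasta <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  abort_if(anyDuplicated(ids) > 0, "duplicate gene id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  bad_chr <- grepl("[^ACGT]", seqs)
  abort_if(any(bad_chr), "non-ACGTU character(s) in record(s): ",
           paste(ids[bad_chr], collapse = ", "))
  bad_len <- nchar(seqs) %% 3L != 0L
  abort_if(any(bad_len),
           "CDS length not divisible by 3 for record(s): ",
           paste(ids[bad_len], collapse = ", "))
  codons <- lapply(seqs, split_into_codons)
  names(codons) <- ids
  new_gene_set(codons)
}

#' Write a GeneSet as FASTA
#' @param genes a `GeneSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  lines <- unlist(lapply(gene_ids(genes), function(id) {
    c(paste0(">", id), paste0(genes$codons[[id]], collapse = ""))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
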