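# Codon vocabulary and genetic-code lookups. Codon indices are 0-based over
# the lexicographic DNA alphabet (AAA = 0 ... TTT = 63); model inputs use
# these indices, IO uses the 3-mer strings.

#' The 64 DNA codons in lexicographic order
#'
#' @return character vector of length 64 (`"AAA"`, `"AAC"`, ..., `"TTT"`).
#' @export
#' @examples
#' codon_alphabet()[1:5]
codon_alphabet <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Stop codons (standard genetic code)
#' @return character vector `c("TAA", "TAG", "TGA")`.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' The 61 sense codons
#'
#' Sense codons in lexicographic order; stop codons are excluded from
#' pause-score z-scoring and from random mutant sampling (a stop insertion
#' would model nonsense, not elongation context).
#'
#' @return character vector of length 61.
#' @export
sense_codons <- function() setdiff(codon_alphabet(), stop_codons())

#' Map codons to one-letter amino acids
#'
#' Uses the standard genetic code (stops map to `"*"`).
#'
#' @param codons character vector of 3-mers over ACGT.
#' @return character vector of one-letter amino-acid codes.
#' @export
codon_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  abort_if(anyNA(aa), "invalid codon(s): ",
           paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' Convert codon strings to 0-based model indices and back
#'
#' @param codons character vector of 3-mers.
#' @return `codon_index()`: integer vector in 0..63; `index_codon()`: 3-mers.
#' @export
codon_index <- function(codons) {
  idx <- match(codons, codon_alphabet()) - 1L
  abort_if(anyNA(idx), "invalid codon(s): ",
           paste(unique(codons[is.na(idx)]), collapse = ", "))
  idx
}

#' @rdname codon_index
#' @param index integer vector in 0..63.
#' @export
index_codon <- function(index) {
  abort_if(any(index < 0L | index > 63L | is.na(index)),
           "codon index out of range 0..63")
  codon_alphabet()[index + 1L]
}

# indices (0-based) of the 61 sense codons, used for mutant sampling
sense_codon_indices <- function() codon_index(sense_codons())
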