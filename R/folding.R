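# Folding-energy interface: a pluggable wrapper around an external RNA
# folding engine, with a bundled deterministic stub so the pipeline runs
# without external software. The stub is a toy score, not a thermodynamic
# model.

#' Folding energy of a nucleotide sequence
#'
#' With `engine = "stub"` (default) a deterministic toy energy is returned:
#' the sequence is scanned from both ends inward and each consecutive
#' Watson-Crick pair (A:U/T, G:C) contributes -2 kcal/mol until the first
#' mismatch — i.e. `-2 x` length of the terminal stem. With
#' `engine = "rnafold"` the external `RNAfold` binary is called (error with
#' instructions when absent).
#'
#' @param nt_sequence nucleotide string (T and U both accepted).
#' @param engine `"stub"` or `"rnafold"`.
#' @return energy in kcal/mol (attribute `engine` records the engine used).
#' @export
folding_energy <- function(nt_sequence, engine = c("stub", "rnafold")) {
  engine <- match.arg(engine)
  s <- chartr("U", "T", toupper(nt_sequence))
  if (engine == "rnafold") {
    bin <- Sys.which("RNAfold")
    abort_if(bin == "",
             "RNAfold not found on PATH; install ViennaRNA or use ",
             "engine = 'stub'")
    out <- system2(bin, args = "--noPS", input = chartr("T", "U", s),
                   stdout = TRUE)
    m <- regmatches(out[2], regexpr("\\(\\s*-?[0-9.]+\\)$", out[2]))
    e <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    return(structure(e, engine = "rnafold"))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  n <- length(ch)
  stem <- 0L
  for (i in seq_len(n %/% 2L)) {
    if (!is.na(comp[ch[i]]) && comp[[ch[i]]] == ch[n + 1L - i]) {
      stem <- stem + 1L
    } else {
      break
    }
  }
  structure(-2 * stem, engine = "stub")
}
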