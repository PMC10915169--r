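Package: ribocast
Title: Context-Dependent Modeling and Correction of Ribosome Profiling Densities
Version: 0.1.0
Authors@R:
    person("ribocast", "developers", email = "ribocast@example.org", role = c("aut", "cre"))
Description: Codon-resolution preprocessing of ribosome profiling footprint
    tracks, a two-branch convolution + multi-head attention regression model
    that predicts context-dependent ribosome densities from a coding sequence
    window and a reference density window, and downstream interpretive tools:
    differential pause-site detection with exact tests, in silico mutagenesis
    sequence impact scores, clustering of impact-score profiles, positional
    codon enrichment, and translation efficiency. Includes a deterministic,
    seeded ribo-seq simulator with known codon dwell times, context effects
    and technical-bias operators so the whole pipeline is testable without
    external data, plus a command-line interface for reproducible runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
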