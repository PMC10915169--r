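# Deterministic, seeded generator of synthetic genomes and paired ribosome
# profiling tracks with known dwell-time structure, context effects,
# technical bias, and collision (disome-like) derivation. The stated world:
# genes start with ATG and end with a stop; internal codons follow usage
# weights; the ribosome's per-codon rate is dwell(codon) times any matching
# context effects; reads are allocated multinomially with Poisson gene
# totals (or exactly proportionally with noise off) and placed on the middle
# nucleotide of each codon.

#' Configuration of the synthetic ribo-seq world
#'
#' @param n_genes number of genes.
#' @param length_range gene length range in codons (min >= 70, so genes
#'   survive end trims plus a default window).
#' @param usage named codon-usage weights over the 61 sense codons (default
#'   uniform).
#' @param dwell named positive per-codon dwell-time multipliers over the 61
#'   sense codons. Default `NULL`: log-normal dwell times (sdlog 0.3, a
#'   realistic severalfold spread) drawn deterministically from `seed`.
#' @param context_effects list of motif effects; each element is
#'   `list(offsets=, codons=, effect=)`: when the codons at the given
#'   offsets relative to a position all match, that position's rate is
#'   multiplied by `effect`.
#' @param noise `"none"` (exact expected reads) or `"poisson"`.
#' @param depth expected reads per gene.
#' @param bias_spec optional named per-codon multiplicative distortion used
#'   by [apply_technical_bias()].
#' @param collision_rule list with threshold `theta` (on the per-codon rate)
#'   and upstream offset `d` (codons) for [simulate_collisions()].
#' @param seed mandatory integer seed; all outputs are bitwise reproducible
#'   given the config.
#' @return a `SynthConfig`.
#' @export
synth_config <- function(n_genes = 200L, length_range = c(100L, 300L),
                         usage = NULL, dwell = NULL,
                         context_effects = list(),
                         noise = c("poisson", "none"), depth = 2000,
                         bias_spec = NULL,
                         collision_rule = list(theta = 2, d = 10L),
                         seed) {
  abort_if(missing(seed), "seed is mandatory")
  noise <- match.arg(noise)
  abort_if(length_range[1] < 70L, "length range below 70 codons")
  sc <- sense_codons()
  if (is.null(usage)) usage <- stats::setNames(rep(1, 61), sc)
  abort_if(!all(sc %in% names(usage)), "usage must cover all sense codons")
  if (is.null(dwell)) {
    dwell_seed <- (as.numeric(seed) * 13 + 7) %% 2147483647
    dwell <- stats::setNames(
      with_seed(dwell_seed, exp(stats::rnorm(61, 0, 0.3))), sc)
  }
  abort_if(!all(sc %in% names(dwell)), "dwell must cover all sense codons")
  abort_if(any(dwell <= 0), "dwell multipliers must be > 0")
  for (ce in context_effects) {
    abort_if(is.null(ce$offsets) || is.null(ce$codons) || is.null(ce$effect),
             "context effect needs offsets, codons, effect")
    abort_if(ce$effect <= 0, "context effect must be > 0")
  }
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range),
                 usage = usage[sc], dwell = dwell[sc],
                 context_effects = context_effects, noise = noise,
                 depth = depth, bias_spec = bias_spec,
                 collision_rule = collision_rule, seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate a synthetic GeneSet
#'
#' Genes begin with ATG, end with a stop codon, and draw internal codons
#' from the configured usage weights. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a `GeneSet`.
#' @export
generate_genes <- function(cfg) {
  sc <- sense_codons()
  if (cfg$n_genes == 0L) return(new_gene_set(stats::setNames(list(), character(0))))
  with_seed(cfg$seed, {
    rng <- seq.int(cfg$length_range[1], cfg$length_range[2])
    lens <- rng[sample.int(length(rng), cfg$n_genes, replace = TRUE)]
    codons <- lapply(lens, function(len) {
      c("ATG",
        sample(sc, len - 2L, replace = TRUE, prob = cfg$usage),
        sample(stop_codons(), 1L))
    })
    names(codons) <- sprintf("g%04d", seq_len(cfg$n_genes))
    new_gene_set(codons)
  })
}

# per-codon expected rates for one gene: dwell(codon) x context effects
gene_rates <- function(codons, cfg) {
  r <- unname(cfg$dwell[codons])
  r[is.na(r)] <- 1  # ATG start is sense; stops get neutral dwell
  len <- length(codons)
  for (ce in cfg$context_effects) {
    offs <- as.integer(ce$offsets)
    for (i in seq_len(len)) {
      pos <- i + offs
      if (any(pos < 1L | pos > len)) next
      if (all(codons[pos] == ce$codons)) r[i] <- r[i] * ce$effect
    }
  }
  r
}

#' Simulate a footprint track with known ground-truth rates
#'
#' Per-codon rate = dwell(codon) x matching context effects; a gene's reads
#' are allocated across codons proportionally to the rates, with the gene
#' total exactly `depth` (`noise = "none"`) or Poisson(`depth`) followed by
#' a multinomial draw (`noise = "poisson"`). All reads sit on the middle
#' nucleotide of their codon. The draw is controlled by
#' `cfg$seed + seed_offset`, so paired conditions/replicates use different
#' offsets while remaining fully reproducible.
#'
#' @param genes a `GeneSet` (typically from [generate_genes()]).
#' @param cfg a [synth_config()].
#' @param condition condition label for the track.
#' @param seed_offset integer added to `cfg$seed` for this draw.
#' @return list with `track` (`ProfileTrack`), `rates` (named list of
#'   per-codon true rates) and `truth` (data frame gene, codon_index,
#'   true_rate).
#' @export
simulate_density <- function(genes, cfg, condition = "synthetic",
                             seed_offset = 1L) {
  ids <- gene_ids(genes)
  rates <- lapply(ids, function(id) gene_rates(genes$codons[[id]], cfg))
  names(rates) <- ids
  counts <- with_seed(cfg$seed + seed_offset, {
    lapply(ids, function(id) {
      r <- rates[[id]]
      codon_reads <- if (cfg$noise == "none") {
        cfg$depth * r / sum(r)
      } else {
        n <- stats::rpois(1L, cfg$depth)
        as.numeric(stats::rmultinom(1L, n, r))
      }
      nt <- numeric(3L * length(r))
      nt[seq_along(r) * 3L - 1L] <- codon_reads  # middle nt of each codon
      nt
    })
  })
  names(counts) <- ids
  truth <- data.frame(
    gene = rep(ids, lengths(rates)),
    codon_index = unlist(lapply(rates, function(r) seq_along(r) - 1L),
                         use.names = FALSE),
    true_rate = unlist(rates, use.names = FALSE))
  list(track = new_profile_track(counts, condition), rates = rates,
       truth = truth)
}

#' Apply a sequence-specific technical bias to a track
#'
#' Multiplies each codon's reads by `bias_spec[codon]` and renormalizes so
#' the gene total is preserved: protocol bias redistributes reads within a
#' gene, it does not create them.
#'
#' @param track a `ProfileTrack` (reads on middle nucleotides, as written by
#'   [simulate_density()]).
#' @param genes the matching `GeneSet`.
#' @param cfg a [synth_config()] with `bias_spec` set.
#' @return a biased `ProfileTrack` (condition suffixed `"+bias"`).
#' @export
apply_technical_bias <- function(track, genes, cfg) {
  abort_if(is.null(cfg$bias_spec), "cfg$bias_spec is not defined")
  counts <- lapply(gene_ids(genes), function(id) {
    v <- track$counts[[id]]
    abort_if(is.null(v), "gene '", id, "' not covered by track")
    codons <- genes$codons[[id]]
    cr <- colSums(matrix(v, nrow = 3L))
    mult <- cfg$bias_spec[codons]
    mult[is.na(mult)] <- 1
    tot <- sum(cr)
    br <- cr * unname(mult)
    if (tot > 0 && sum(br) > 0) br <- br * (tot / sum(br))
    nt <- numeric(length(v))
    nt[seq_along(br) * 3L - 1L] <- br
    nt
  })
  names(counts) <- gene_ids(genes)
  new_profile_track(counts, paste0(track$condition, "+bias"),
                    track$replicate)
}

#' Derive a disome-like collision track from a monosome track
#'
#' Collision signal at codon i = monosome(i) x 1[rate(i) > theta] x
#' monosome(i - d): a trailing ribosome stacks `d` codons upstream of a
#' stalled one. Per gene, the disome track is rescaled to the gene's
#' monosome total (when any signal exists). Deterministic given its inputs.
#'
#' @param track monosome `ProfileTrack` (middle-nt placement).
#' @param genes the matching `GeneSet`.
#' @param cfg a [synth_config()] with `collision_rule` (`theta`, `d`).
#' @param rates named list of true per-codon rates from
#'   [simulate_density()].
#' @return a disome `ProfileTrack` (condition suffixed `"+disome"`).
#' @export
simulate_collisions <- function(track, genes, cfg, rates) {
  theta <- cfg$collision_rule$theta
  d <- as.integer(cfg$collision_rule$d)
  counts <- lapply(gene_ids(genes), function(id) {
    v <- track$counts[[id]]
    cr <- colSums(matrix(v, nrow = 3L))
    len <- length(cr)
    abort_if(d >= len, "collision offset d (", d,
             ") >= gene length for '", id, "'")
    r <- rates[[id]]
    di <- numeric(len)
    i <- seq.int(d + 1L, len)
    di[i] <- cr[i] * (r[i] > theta) * cr[i - d]
    tot <- sum(cr)
    if (sum(di) > 0) di <- di * (tot / sum(di))
    nt <- numeric(length(v))
    nt[seq_len(len) * 3L - 1L] <- di
    nt
  })
  names(counts) <- gene_ids(genes)
  new_profile_track(counts, paste0(track$condition, "+disome"),
                    track$replicate)
}

#' Write the generator's ground truth as TSV
#' @param truth data frame (gene, codon_index, true_rate).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  data.table::fwrite(data.table::as.data.table(truth), path, sep = "\t")
  invisible(path)
}
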