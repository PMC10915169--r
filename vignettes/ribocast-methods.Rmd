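---
title: "ribocast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribocast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ribosome profiling measures per-nucleotide footprint counts along coding
sequences; the density at a codon reflects how slowly it is decoded. Two
practical obstacles stand between the raw counts and biological
interpretation. First, harvesting and lysis protocols introduce
sequence-specific artifacts (e.g. spurious pausing at Ser/Gly codons under
some bacterial protocols), so two libraries of the same biology can show
different pausing landscapes. Second, the interesting signal is often the
*change* in local decoding speed between two conditions (protocols, ages,
monosome vs disome), which no single-library statistic captures.

ribocast addresses both with a paired-condition regression model: given the
codon sequence around a position and the (log) ribosome density of the same
window in a *reference* condition, predict the density of the center codon
in a *target* condition. Once trained on a pair of datasets, the model maps
new reference-condition data onto the target condition — removing protocol
bias when the pair is (biased, unbiased), or predicting collision-prone
sites when the pair is (monosome, disome). Model interrogation by in silico
mutagenesis then attributes the predicted changes to specific codons.

# Preprocessing conventions

All coordinates are 0-based within the CDS; counts are assumed already
assigned to a single ribosome-site position per footprint (A/P-site offset
calibration is upstream of this package). The pipeline is:

* replicates are averaged per nucleotide (`average_replicates()`);
* genes shorter than 200 nt are removed, as are genes below a mean coverage
  threshold — 0.5 reads/nt (prokaryote preset) or 5 reads/nt (eukaryote
  preset), boundary inclusive (`filter_genes()`);
* per-codon density is the sum of the codon's three nucleotide counts
  (`codon_density()`);
* the first and last 10 codons of every gene are excluded from all
  statistics (initiation/termination ramps);
* the *pause score* of a codon instance is its density divided by the mean
  density over the retained codons of its ORF; per codon type the score is
  the mean over instances, z-scored across the observed sense codon types
  (stop codons excluded — they are terminal events, not elongation
  context). A codon type with no instances is reported `NA` and excluded
  from z-scoring; if all type means coincide (zero SD) the z-scores are
  defined as 0 rather than NaN.

"Normalized ribosome density" is not a single convention in the field; we
normalize by the gene's mean over retained codons, which makes genes of
different expression comparable, and log-transform the model's reference
input as `log2(normalized + 0.5)`. The pseudocount 0.5 keeps zero-count
codons finite while distorting typical values (near 1) by less than a
factor of 2; it is configurable.

# Window datasets

A training instance is built for every retained codon whose full ±W context
lies inside the CDS: valid centers are `i >= max(10, W)` and
`i <= len - 1 - max(10, W)`. The default W = 20 gives 41-codon windows — the
center codon must be represented because it is the prediction target, so the
window length is 2W+1, not 2W. The instance carries the codon-index window
(0..63 per codon), the log reference-density window, and the target: the
center codon's gene-mean-normalized density in the target condition on the
*linear* scale. Keeping the target linear resolves a structural tension in
the architecture: the output head ends in a ReLU, whose codomain [0, ∞)
matches linear normalized densities but not log densities. The reference
input stays log-transformed.

Splits are 70/15/15 train/validation/test (sizes within one instance) or
k-fold, deterministic given a seed.

# The two-branch model

Branch 1 (sequence): codons are embedded (8 dimensions), giving a
(positions × embedding) image processed by five convolution blocks — 2D
convolution with a 5×5 kernel, 32 filters, SAME padding, stride 1; batch
normalization; then a pointwise fully connected stage with ReLU. After the
blocks, average pooling over the embedding axis leaves a
(positions × 32) map. Branch 2 (reference density): identical except the
convolutions are 1D over positions.

Each branch then runs one transformer-style block: multi-head scaled
dot-product attention (10 heads, key/query dimension 8, dropout 0.1 on the
attention probabilities, training mode only), heads concatenated, followed
by a feed-forward stage (dense, layer normalization, ReLU) and a global
average over positions, producing one 32-vector per branch. The merge is
element-wise multiplication through a linear head with a final ReLU:
`pred = ReLU(w · (x_seq ∘ x_ref) + b)`. The multiplicative merge reflects
the generative intuition that a codon's density is a *rate multiplier*
acting on the local baseline occupancy.

With `mask_ref = TRUE` the reference branch output is replaced by a learned
constant 32-vector, turning the network into a pure sequence model while
preserving head dimensionality; "masking" has no unique definition and the
learned-constant choice keeps the merge well-scaled.

Two orderings were genuinely open: whether the attention block precedes or
follows filter pooling, and how the final 32-vector is formed. We pool the
embedding axis first (so attention runs over positions, which is what
"capturing interdependency among codons" requires) and take the global
position average after the feed-forward stage (the only reading under which
both branches end in a 32-vector).

A practical note on position information: the network has no explicit
positional encoding, so the only way the model can distinguish the center
codon from its neighbours is the boundary signature that SAME padding
imprints near window edges and that deepens with each convolution block.
With kernel size 5, each block extends the receptive field by ±2; desk-scale
configurations must keep enough blocks that `2·blocks ≥ W`, otherwise
center-specific targets are structurally unlearnable. This is visible
empirically: at W = 5, two blocks plateau well below the recovery criterion
while three blocks pass it comfortably.

# Training

Adam minimizes mean squared error under a cosine learning-rate decay,
`lr(s) = lr0 · (1 + cos(πs))/2` with `lr0 = 5e-4`, where `s` is the
normalized progress (step / total planned steps) — this yields the stated
start value and a monotone decay to zero. Early stopping ends training when
the validation loss has not decreased for 10 consecutive epochs; the model
returned is the best-validation-epoch one. Batch size (128) and maximum
epochs (200) are unstated upstream and configurable. All gradients are
hand-written reverse-mode (no deep-learning backend exists in this stack)
and are verified against central finite differences to 1e-4 in the test
suite; convolution and attention forwards are verified against brute-force
nested-loop oracles to 1e-6. Checkpoints are a JSON config plus a text
array archive at %.17g, which round-trips IEEE doubles bit-exactly.

# Downstream analyses

**Differential pause sites.** For each retained codon, a 2×2 table
`[[case_at, case_rest], [ctrl_at, ctrl_rest]]` is built at *gene* scope
(position vs rest-of-gene; whether the original used gene- or library-level
totals is not stated — users comparing results should note this choice).
Densities are rounded half-up to integers because the exact test needs
integer tables and replicate averaging can produce fractions. The two-sided
Fisher p-value sums hypergeometric probabilities ≤ the observed one (within
1e-7 relative, the standard guard against ties lost to floating point); the
odds ratio is the sample OR `ad/bc` with `Inf` when `bc = 0 < ad`. Sites
with `p < 0.001` and `OR > 1` are flagged — a raw threshold, reproducing the
upstream convention; Benjamini–Hochberg q-values are reported for
information only.

**Sequence impact scores.** For a site, a `mut_window`-codon window slides
across the input; at each placement the window is replaced by random
sequences (uniform over the 61 sense codons — stop insertion would model
nonsense, not elongation) and the model's mean prediction RD′ over
`n_samples` draws is recorded. The window score is `SIS = RD − RD′` and the
per-codon SIS is the mean over covering placements (edge codons are covered
by fewer placements; the count is reported). Sign convention: under
RD − RD′, mutating away a causal stall motif *lowers* the prediction, so
causal positions are SIS *maxima*; profiles are sometimes plotted with the
opposite (mutant-minus-original) sign, under which the same positions are
minima. The package uses RD − RD′ throughout and the tests assert
localization of the extremum. With `mut_window = 1` the per-codon SIS of an
additive model recovers each position's effect exactly; wider windows
recover a moving-average-smoothed version (both are property-tested).

**Clustering and enrichment.** SIS profiles are clustered with K-means
(seed 0 by default, deterministic); the cluster count comes from the elbow
method, automated as the maximum second difference of the inertia curve
over k = 2..15, overridable. Per cluster, codon-by-position enrichment
compares occurrence indicators against random background sequences (uniform
over sense codons by default; genome codon usage optionally) with a Welch
t-test, reported as `sign × (−log10 p)` with p floored at 1e-300 before the
log. Folding energies come from a pluggable interface: the external RNAfold
binary when present, otherwise a bundled deterministic stub (−2 kcal/mol per
consecutive complementary pair scanning inward from the sequence ends) that
exists so pipelines run without external software — it has no thermodynamic
accuracy and is documented as such.

# The synthetic world

The generator emulates the statistical structure of paired ribo-seq
libraries without any download. Genes (default 200, 100–300 codons, at
least 70 so a gene survives trims plus a window) start with ATG, end with a
stop, and draw internal codons from usage weights (uniform by default).
The latent per-codon rate is `dwell(codon) × Π context effects`; dwell
times default to a log-normal spread (sdlog 0.3, drawn deterministically
from the seed), a realistic severalfold range between fast and slow codons.
Context effects are motif-keyed multipliers (e.g. "×4 when the previous
codon is GGT and the center is CCG"), the generator's stand-in for
interaction-driven stalls. Reads per gene are Poisson around `depth`
(default 2000, the coverage of a well-expressed gene in a filtered set)
allocated multinomially across codons, all placed on the codon's middle
nucleotide — placement within the codon is invisible to codon-level sums
but must be fixed for byte-reproducible files. Technical bias multiplies
per-codon reads by `bias_spec[codon]` and renormalizes to the gene total:
protocol bias redistributes reads, it does not create expression. A
disome-like track is derived as
`mono(i) × 1[rate(i) > θ] × mono(i − d)`, rescaled per gene.

What a green test does establish: the preprocessing conventions are
internally consistent; the model can recover planted
sequence-by-reference relationships and codon dwell rankings from Poisson
data at realistic coverage; bias correction removes a planted compositional
bias while preserving a planted interaction stall; SIS localizes planted
causal motifs; the pause-site test is calibrated under a true null. What it
does not establish: performance on real libraries with footprint-length
artifacts, 5′ ramps, UTR effects, frameshifting or mapping noise — none of
which the generator emulates.

# Desk-scale configurations

Training-based tests run the spec-stated data scale (~500 genes, ~20k
windows, Poisson noise) but a scaled-down architecture: W = 5, 3 convolution
blocks, 8 filters, 2 heads of key dimension 4, embedding 4, batch 512,
initial learning rate 2e-3, ≤ 22 epochs. The reductions keep the whole test
suite within a 1-CPU 25-minute budget; the block count respects the
receptive-field constraint above, and the package defaults remain the full
published architecture. In the bias-correction scenario the generator's
codon usage is enriched for the two motif codons so the planted interaction
has ~130 instances — enough to estimate a group mean at desk scale.

# Known limitations

* The model needs a trained pair; it cannot correct a protocol it has never
  seen mapped to an unbiased partner.
* Initiation/termination are excluded by construction (10-codon trims), so
  ramp biology is out of reach.
* The reference input must use the exact transform the model was trained
  with; `predict()` refuses mismatched transform metadata rather than
  silently mis-scaling.
* Batch-norm statistics make train-mode forward passes batch-dependent;
  all reported predictions use evaluation mode, which is deterministic.
* The folding-energy stub is a placeholder, not an energy model.
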