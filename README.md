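# ribocast

Context-dependent modeling and correction of ribosome profiling densities
at codon resolution.

Ribosome profiling (ribo-seq) counts ribosome-protected footprints along
coding sequences; high density at a codon means slow decoding. Two chronic
problems stand between those counts and biology: **protocol artifacts**
(harvest/lysis chemistry introduces sequence-specific spurious pauses, e.g.
at Ser/Gly codons in filtered, chloramphenicol-treated bacterial samples)
and the fact that the interesting quantity is usually a **change in local
decoding speed between two conditions** (biased vs unbiased protocol,
monosome vs disome, young vs aged). ribocast is for ribo-seq analysts who
have a *paired* design and want to (a) map densities from one condition
onto the other, (b) call condition-dependent pause sites with an exact
test, and (c) attribute model-predicted pausing to specific codons by in
silico mutagenesis.

## The model

For each retained codon *i* of a gene, an instance pairs the codon window
`s[i−W..i+W]` (default W = 20, i.e. 41 codons) with the log-transformed,
gene-mean-normalized reference-condition density of the same window, and
the target is the center codon's normalized density in the target
condition:

    x_seq = SeqBranch(embed(s))        # 2D conv blocks -> attention -> FF
    x_ref = RefBranch(log2(d_ref+0.5)) # 1D conv blocks -> attention -> FF
    d̂_target(i) = ReLU( w · (x_seq ∘ x_ref) + b )

Each branch uses 5 convolution blocks (kernel 5(×5), 32 filters, batch
norm, pointwise ReLU), one multi-head attention block (10 heads, key dim 8,
dropout 0.1, `a_ij = softmax(q_i k_j^T / √K)`), a feed-forward + layer-norm
stage, and a global average over positions. Training: Adam, MSE loss,
cosine learning-rate decay `lr(s) = 0.0005·(1+cos(πs))/2`, 70/15/15
train/validation/test split, early stopping after 10 stale epochs. The
forward/backward passes are implemented in this package (R + small Rcpp
kernels) and are verified against brute-force oracles and finite
differences in the test suite.

Downstream: codon **pause scores** (density / ORF mean, z-scored across the
61 sense codon types), **differential pause sites** via two-sided Fisher's
exact tests on `[[case_at, case_rest],[ctrl_at, ctrl_rest]]` tables flagged
at p < 0.001 and OR > 1, **sequence impact scores** (SIS = RD − RD′ under
sliding-window random mutagenesis), K-means **clustering** of SIS profiles
with elbow-based k, per-cluster positional **codon enrichment**, and
**translation efficiency** (RD/FPKM). A seeded synthetic-data module
generates genomes and paired tracks with known dwell times, context-effect
stalls, technical bias and disome-like collisions, so the entire pipeline
is testable offline.

## Worked example

Simulate a biased/unbiased pair, train the corrector, and compare pause
scores (runs in ~2 minutes on one CPU):

```r
library(ribocast)
cfg <- synth_config(n_genes = 150, length_range = c(80, 120), depth = 2000,
                    noise = "poisson", seed = 42,
                    bias_spec = c(GGT = 3, GGC = 3, AGC = 3))
genes  <- generate_genes(cfg)
truth  <- simulate_density(genes, cfg, condition = "unbiased")
biased <- apply_technical_bias(truth$track, genes, cfg)

cd_biased <- codon_density(biased, genes)
ps <- pause_scores(cd_biased, genes)
subset(ps$codon, codon %in% c("GGT", "GGC", "AGC", "AAA"))
#>    codon aa   n mean_score          z
#> 1    AAA  K 205  0.8911468 -0.2360211
#> 10   AGC  S 234  1.8537139  1.8915486
#> 42   GGC  G 200  1.7023074  1.5568935
#> 44   GGT  G 200  3.7638354  6.1135052
```

The biased track shows strong artifactual pausing at the distorted codons
(z up to 6.1). Train the two-branch model to map biased densities onto the
unbiased condition:

```r
ds <- build_windows(genes,
                    ref_cd    = normalize_and_log(cd_biased),
                    target_cd = normalize_gene_mean(codon_density(truth$track, genes)),
                    W = 5)
split <- split_dataset(ds, "fraction", seed = 1)
model <- train_model(ds, split,
                     model_cfg = model_config(W = 5, embed_dim = 4, conv_blocks = 3,
                                              filters = 8, attention_heads = 2, key_dim = 4),
                     train_cfg = train_config(start_lr = 2e-3, batch_size = 512,
                                              max_epochs = 15, seed = 1))
test <- which(split$assignment == "test")
pred <- predict(model, subset_windows(ds, test))
unlist(evaluate_predictions(as.vector(pred), ds$target[test]))
#>    pearson   spearman        mse 
#> 0.93246925 0.94360247 0.01617672
```

Held-out predictions track the unbiased densities (r = 0.93). The corrected
mean pause score of the bias-targeted codon GGT drops from 3.64 (biased
input) to 1.56, close to its true unbiased value 1.37 — the artifact is
removed while real dwell-time differences are kept:

```r
center <- index_codon(ds$seq[test, 6])
sel <- center == "GGT"
c(input     = mean(2^ds$ref[test, 6][sel] - 0.5),
  corrected = mean(pred[sel]),
  truth     = mean(ds$target[test][sel]))
#> GGT mean score  input: 3.64  corrected: 1.56  truth: 1.37
```

Interpretation tools follow the same interfaces: `detect_pause_sites()`
returns the flagged Fisher tables, `compute_sis()` / `cluster_sis()` /
`cluster_codon_enrichment()` interrogate a trained model around sites of
interest, and `save_model()` / `load_model()` round-trip checkpoints
bit-exactly.

## Command line

```sh
ribocast=$(Rscript -e 'cat(system.file("exec/ribocast", package = "ribocast"))')
Rscript "$ribocast" simulate --seed 7 --out out/sim
Rscript "$ribocast" train --cds out/sim/cds.fasta \
    --ref-profile out/sim/profile_ref.tsv \
    --target-profile out/sim/profile_target.tsv --window 5 --seed 1 --out out/run
Rscript "$ribocast" pause-sites --cds out/sim/cds.fasta \
    --ref-profile out/sim/profile_ref.tsv \
    --target-profile out/sim/profile_target.tsv --alpha 0.001 --out out/ps
```

Subcommands: `simulate`, `preprocess`, `train`, `predict`, `pause-sites`,
`sis`, `cluster`. Every run writes a `manifest.json` (resolved config,
package version, input checksums) sufficient to replay it.

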