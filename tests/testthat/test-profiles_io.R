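# profiles_io: FASTA/profile reading, replicate averaging, filtering,
# codon densities, pause scores, windows, splits.

test_that("read_cds_fasta parses, validates and normalizes records", {
  gs <- make_gene_set(list(g1 = "ATGGCTTAA", g2 = "atguuucgatga"))
  expect_equal(gene_ids(gs), c("g1", "g2"))
  expect_equal(gene_codons(gs, "g1"), c("ATG", "GCT", "TAA"))
  expect_equal(gene_codons(gs, "g2"), c("ATG", "TTT", "CGA", "TGA"))
  expect_equal(unname(gene_lengths(gs)), c(3L, 4L))

  expect_error(make_gene_set(list(bad = "ATGGCTTAAG")), "bad")
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ATGTAA", ">g1", "ATGTGA"), tmp)
  expect_error(read_cds_fasta(tmp), "duplicate")
  writeLines(c(">gx", "ATGNNNTAA"), tmp)
  expect_error(read_cds_fasta(tmp), "gx")
  unlink(tmp)
})

test_that("FASTA writer round-trips a GeneSet", {
  gs <- make_gene_set(list(a = random_cds(30, 1), b = random_cds(41, 2)))
  tmp <- tempfile(fileext = ".fasta")
  write_cds_fasta(gs, tmp)
  gs2 <- read_cds_fasta(tmp)
  expect_identical(gs2$codons, gs$codons)
  unlink(tmp)
})

test_that("read_profile_table densifies, validates and round-trips", {
  gs <- make_gene_set(list(g1 = "ATGGCTTAA"))
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tposition\tcount", "g1\t0\t2", "g1\t5\t1"), tmp)
  tr <- read_profile_table(tmp, "cond", genes = gs)
  expect_equal(tr$counts$g1, c(2, 0, 0, 0, 0, 1, 0, 0, 0))

  writeLines("gene_id\tposition\tcount", tmp)
  expect_length(read_profile_table(tmp, "cond")$counts, 0)

  writeLines(c("gene_id\tposition\tcount", "g1\t9\t1"), tmp)
  expect_error(read_profile_table(tmp, "cond", genes = gs), "g1.*9")
  writeLines(c("gene_id\tposition\tcount", "g1\t1\t-2"), tmp)
  expect_error(read_profile_table(tmp, "cond", genes = gs), "negative")
  writeLines(c("gene\tpos\tn", "g1\t1\t2"), tmp)
  expect_error(read_profile_table(tmp, "cond"), "header")

  # writer/reader round trip through the sparse dialect
  tr2 <- make_track(list(g1 = c(0, 3, 0, 0, 0, 0, 2.5, 0, 0)))
  write_profile_table(tr2, tmp)
  expect_equal(read_profile_table(tmp, "c1", genes = gs)$counts$g1,
               tr2$counts$g1)
  unlink(tmp)
})

test_that("average_replicates averages element-wise and validates inputs", {
  t1 <- make_track(list(g = c(2, 0, 4)), "c", "r1")
  t2 <- make_track(list(g = c(0, 0, 2)), "c", "r2")
  t3 <- make_track(list(g = c(3, 0, 0), h = c(1, 1, 1)), "c", "r3")
  expect_equal(average_replicates(list(t1, t2))$counts$g, c(1, 0, 3))
  expect_identical(average_replicates(list(t1)), t1)
  expect_equal(average_replicates(list(
    make_track(list(g = c(3, 0)), "c"), make_track(list(g = c(0, 0)), "c"),
    make_track(list(g = c(0, 3)), "c")))$counts$g, c(1, 1))
  expect_error(average_replicates(list(t1, make_track(list(g = 1:3), "d"))),
               "mixed conditions")
  expect_error(average_replicates(list(t1, t3)), "h")
  # order invariance
  expect_equal(average_replicates(list(t2, t1))$counts,
               average_replicates(list(t1, t2))$counts)
})

test_that("filter_genes applies length and inclusive coverage thresholds", {
  seqs <- list(
    short = paste(rep("AAA", 66), collapse = ""),   # 198 nt < 200
    lowc = paste(rep("AAC", 100), collapse = ""),   # 300 nt
    ok = paste(rep("AAG", 100), collapse = ""))
  gs <- make_gene_set(seqs)
  tr <- make_track(list(short = rep(10, 198),
                        lowc = c(rep(0, 150), rep(149 / 150, 150)),
                        ok = c(rep(0, 150), rep(1, 150))))  # mean exactly 0.5
  kept <- filter_genes(gs, tr, preset = "prok")
  expect_equal(gene_ids(kept), "ok")  # boundary inclusive at 0.5
  expect_equal(attr(kept, "min_reads_per_nt"), 0.5)
  kept_euk <- suppressWarnings(filter_genes(gs, tr, preset = "euk"))
  expect_equal(n_genes(kept_euk), 0L)
  expect_warning(filter_genes(gs, tr, min_reads_per_nt = 100), "no genes")
})

test_that("top_genes_by_density ranks by mean density with lexicographic ties", {
  gs <- make_gene_set(list(a = "ATGTAA", b = "ATGTGA", c = "ATGTAG"))
  tr <- make_track(list(a = rep(5, 6), b = rep(1, 6), c = rep(3, 6)))
  expect_equal(gene_ids(top_genes_by_density(gs, tr, 2)), c("a", "c"))
  expect_equal(gene_ids(top_genes_by_density(gs, tr, 3)), c("a", "c", "b"))
  tr2 <- make_track(list(a = rep(3, 6), b = rep(3, 6), c = rep(0, 6)))
  expect_equal(gene_ids(top_genes_by_density(gs, tr2, 1)), "a")
  expect_error(top_genes_by_density(gs, tr, 4), "exceeds")
})

test_that("codon_density sums the three nucleotides of each codon", {
  gs <- make_gene_set(list(g = "ATGTAA", h = "ATGTGA"))
  tr <- make_track(list(g = c(1, 2, 3, 4, 5, 6), h = rep(0, 6)))
  cd <- codon_density(tr, gs)
  expect_equal(cd$values$g, c(6, 15))
  expect_equal(cd$values$h, c(0, 0))
  expect_equal(codon_density(make_track(list(g = c(0, 0, 7))),
                             make_gene_set(list(g = "ATG")))$values$g, 7)
  expect_error(codon_density(make_track(list(g = c(1, 2))), gs), "mismatch")
})

test_that("normalize_and_log matches the stated formula", {
  len <- 30L
  gs <- make_gene_set(list(g = random_cds(len, 3)))
  v <- rep(4, len)
  cd <- make_codon_density(list(g = v))
  out <- normalize_and_log(cd)
  expect_equal(out$values$g, rep(log2(1.5), len), tolerance = 1e-12)

  v2 <- rep(1, len); v2[15] <- 2  # value twice the (retained) gene mean
  m <- mean(v2[11:20])
  cd2 <- make_codon_density(list(g = v2))
  out2 <- normalize_and_log(cd2)
  expect_equal(out2$values$g[15], log2(2 / m + 0.5), tolerance = 1e-12)

  cd3 <- make_codon_density(list(g = rep(0, len), h = rep(2, len)))
  expect_warning(out3 <- normalize_and_log(cd3), "dropping")
  expect_named(out3$values, "h")
})

test_that("pause scores normalize per gene and z-score across codon types", {
  set.seed(5)
  gs <- make_gene_set(list(g1 = random_cds(60, 10), g2 = random_cds(45, 11)))
  vals <- lapply(gene_lengths(gs), function(n) runif(n, 0.5, 4))
  cd <- make_codon_density(vals)
  pst <- pause_scores(cd, gs)
  # per-gene mean of instance scores = 1 within 1e-9
  for (id in gene_ids(gs)) {
    expect_equal(mean(pst$instances$score[pst$instances$gene == id]), 1,
                 tolerance = 1e-9)
  }
  obs <- !is.na(pst$codon$z)
  expect_equal(mean(pst$codon$z[obs]), 0, tolerance = 1e-9)
  expect_equal(sd(pst$codon$z[obs]), 1, tolerance = 1e-9)
  expect_true(all(is.na(pst$codon$mean_score[pst$codon$n == 0])))
  expect_equal(nrow(pst$codon), 61L)
  expect_equal(nrow(pst$aa), 20L)

  # uniform density -> all instance scores exactly 1
  cdu <- make_codon_density(lapply(gene_lengths(gs), function(n) rep(3, n)))
  pstu <- pause_scores(cdu, gs)
  expect_true(all(pstu$instances$score == 1))
  # degenerate SD -> all z-scores 0
  expect_true(all(pstu$codon$z[!is.na(pstu$codon$z)] == 0))

  # explicit instance arithmetic: retained values 4,0,0,0 -> scores 4,0,0,0
  gs1 <- make_gene_set(list(s = random_cds(24, 12)))
  v <- rep(0, 24); v[11] <- 4
  ps1 <- pause_scores(make_codon_density(list(s = v)), gs1)
  expect_equal(sort(ps1$instances$score, decreasing = TRUE)[1], 4)
  expect_equal(sum(ps1$instances$score), 4)
})

test_that("build_windows enumerates exactly the valid centers", {
  # brute-force oracle over centers
  centers_oracle <- function(len, W, trim = 10) {
    Filter(function(i) i >= trim && i <= len - 1 - trim &&
             i - W >= 0 && i + W <= len - 1, seq.int(0, len - 1))
  }
  for (case in list(c(61, 20), c(25, 1), c(80, 5))) {
    len <- case[1]; W <- case[2]
    gs <- make_gene_set(stats::setNames(list(random_cds(len, len)), "g"))
    v <- seq_len(len) + 0.0
    ref <- normalize_and_log(make_codon_density(list(g = v)))
    tgt <- normalize_gene_mean(make_codon_density(list(g = v)))
    ds <- build_windows(gs, ref, tgt, W = W)
    oc <- centers_oracle(len, W)
    expect_equal(sort(ds$center_index), sort(unlist(oc)))
    expect_equal(ncol(ds$seq), 2 * W + 1)
  }
  # 61 codons, W=20 -> 21 instances at centers 20..40
  gs <- make_gene_set(stats::setNames(list(random_cds(61, 7)), "g"))
  v <- runif(61, 1, 2)
  ds <- build_windows(gs, normalize_and_log(make_codon_density(list(g = v))),
                      normalize_gene_mean(make_codon_density(list(g = v))),
                      W = 20)
  expect_equal(n_instances(ds), 21L)
  expect_equal(range(ds$center_index), c(20L, 40L))
  # too-short gene contributes nothing (25 codons cannot host a W=20 center)
  expect_error(build_windows(
    make_gene_set(stats::setNames(list(random_cds(25, 8)), "g")),
    normalize_and_log(make_codon_density(list(g = rep(1, 25)))),
    normalize_gene_mean(make_codon_density(list(g = rep(1, 25)))), W = 20),
    "no gene long enough")
  expect_error(build_windows(gs, normalize_gene_mean(
    make_codon_density(list(g = v))), normalize_gene_mean(
      make_codon_density(list(g = v))), W = 5), "log")
})

test_that("window/seq round-trip reproduces the gene codons", {
  len <- 40L
  gs <- make_gene_set(list(g = random_cds(len, 21)))
  v <- runif(len, 1, 3)
  ref <- normalize_and_log(make_codon_density(list(g = v)))
  tgt <- normalize_gene_mean(make_codon_density(list(g = v)))
  ds <- build_windows(gs, ref, tgt, W = 4)
  for (i in seq_len(n_instances(ds))) {
    decoded <- index_codon(ds$seq[i, ])
    pos <- ds$center_index[i] + seq(-4, 4)
    expect_equal(decoded, gene_codons(gs, "g")[pos + 1])
    expect_equal(ds$target[i], tgt$values$g[ds$center_index[i] + 1])
  }
})

test_that("split_dataset partitions deterministically", {
  len <- 150L
  gs <- make_gene_set(list(g = random_cds(len, 31)))
  v <- runif(len, 1, 3)
  ds <- build_windows(gs, normalize_and_log(make_codon_density(list(g = v))),
                      normalize_gene_mean(make_codon_density(list(g = v))),
                      W = 3)
  n <- n_instances(ds)
  # exact 70/15/15 at n = 100
  ds100 <- subset_windows(ds, seq_len(100))
  sp <- split_dataset(ds100, "fraction", seed = 4)
  expect_equal(as.integer(table(sp$assignment)[c("train", "validation", "test")]),
               c(70L, 15L, 15L))
  # determinism
  sp2 <- split_dataset(ds100, "fraction", seed = 4)
  expect_identical(sp$assignment, sp2$assignment)
  # kfold properties over several seeds (disjoint + exhaustive + near-equal)
  for (seed in 1:5) {
    kf <- split_dataset(ds, "kfold", seed = seed, k = 7)
    expect_equal(length(kf$assignment), n)
    expect_true(all(diff(range(tabulate(kf$assignment, 7))) <= 1))
  }
  kf10 <- split_dataset(subset_windows(ds, 1:10), "kfold", seed = 1, k = 10)
  expect_equal(sort(kf10$assignment), 1:10)
  expect_error(split_dataset(subset_windows(ds, 1:5), "kfold", seed = 1,
                             k = 10), "exceeds")
})

test_that("conservation: codon density sums equal nt count sums", {
  cfg <- synth_config(n_genes = 10, length_range = c(70, 100), seed = 77,
                      noise = "poisson", depth = 500)
  genes <- generate_genes(cfg)
  sim <- simulate_density(genes, cfg)
  cd <- codon_density(sim$track, genes)
  for (id in gene_ids(genes)) {
    expect_equal(sum(cd$values[[id]]), sum(sim$track$counts[[id]]))
  }
})
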