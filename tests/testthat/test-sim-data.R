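# Synthetic-data generators: determinism, planted structure, edge cases.

test_that("annotation simulation is deterministic and well-formed", {
  cfg <- hotspot_sim_config(seed = 7)
  a1 <- gen_annotation(cfg)
  a2 <- gen_annotation(cfg)
  expect_identical(a1, a2)

  g <- a1$genes
  expect_false(is.unsorted(g$start))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))  # non-overlapping
  expect_true(all(g$end <= 1e7))
  expect_false(anyDuplicated(g$gene_id) > 0)

  # every cluster spans exactly three consecutive genes
  for (i in seq_len(nrow(a1$clusters))) {
    members <- a1$clusters$member_gene_ids[[i]]
    expect_length(members, 3L)
    idx <- match(members, g$gene_id)
    expect_equal(diff(idx), c(1L, 1L))
    expect_equal(a1$clusters$start[i], g$start[idx[1]])
    expect_equal(a1$clusters$end[i], g$end[idx[3]])
  }
})

test_that("zero cluster rates produce zero cluster calls", {
  cfg <- annotation_sim_config(c(chr1 = 1e6), n_genes = 100,
                               background_cluster_rate = 0, seed = 1)
  expect_equal(nrow(gen_annotation(cfg)$clusters), 0L)
})

test_that("a hotspot outside its chromosome is rejected", {
  expect_error(
    annotation_sim_config(c(chr1 = 1e6), n_genes = 10,
                          hotspot = list(chrom = "chr1", start = 9e5,
                                         end = 2e6, rate = 0.1)),
    "outside its chromosome")
  expect_error(
    annotation_sim_config(c(chr1 = 1e6), n_genes = 10,
                          hotspot = list(chrom = "chrX", start = 0,
                                         end = 1e5, rate = 0.1)),
    "not in")
})

test_that("cluster counts concentrate at rate x genes", {
  # background rate 0.02 over 2000 genes: expect 40 +/- 3 binomial SDs;
  # only seeds among the last two genes are skipped, a negligible edge
  cfg <- annotation_sim_config(c(chr1 = 2e7), n_genes = 2000,
                               background_cluster_rate = 0.02, seed = 123)
  n <- nrow(gen_annotation(cfg)$clusters)
  expect_lt(abs(n - 2000 * 0.02), 3 * sqrt(2000 * 0.02 * 0.98) + 2)
})

test_that("expression simulation has the planted structure", {
  cfg <- planted_expression_config(seed = 3)
  m <- gen_expression(cfg)
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_equal(dim(m), c(200L, 12L))
  expect_identical(m, gen_expression(cfg))  # deterministic

  # end-to-end: the planted cluster passes the co-expression filter
  norm <- normalize_counts(m)
  planted <- attr(m, "planted_genes")
  bait <- select_bait(norm, planted)
  res <- bait_correlation(norm, bait, planted)
  expect_gte(sum(res$r > 0.85, na.rm = TRUE), 3)
})

test_that("reordering samples and restoring the order is an identity", {
  m <- gen_expression(planted_expression_config(seed = 5))
  perm <- sample(ncol(m))
  m2 <- m[, perm][, order(perm)]
  expect_equal(m2, m[, ], ignore_attr = TRUE)
})

test_that("counts approach per-tissue means in the low-noise limit", {
  cfg <- expression_sim_config(
    n_genes = 8, tissues = c(a = 2, b = 2),
    planted_genes = sprintf("p%d", 1:8),
    planted_profile = c(a = 5000, b = 50000),
    dispersion = 1e-6, size_factor_range = c(1, 1), seed = 6)
  m <- gen_expression(cfg)
  # per-gene scale is lognormal; tissue-b/tissue-a ratio must be ~10
  ratios <- rowMeans(m[, 3:4]) / rowMeans(m[, 1:2])
  expect_true(all(abs(ratios - 10) / 10 < 0.05))
})

test_that("replicate counts below one are rejected", {
  expect_error(
    expression_sim_config(10, tissues = c(root = 0), planted_genes = "p1",
                          planted_profile = c(root = 10)),
    "replicate")
})

test_that("spectrum simulation controls the error component", {
  cfg <- spectrum_sim_config(genome_size = 2e5, coverage = 30, seed = 1)
  sp <- gen_kmer_spectrum(cfg)
  expect_identical(sp, gen_kmer_spectrum(cfg))  # deterministic
  # no configured errors: occurrence-1 mass is only the Poisson tail
  n1 <- sum(sp$count[sp$occurrence == 1])
  expect_lt(n1, 1e-6 * sum(sp$count))

  cfg_err <- spectrum_sim_config(genome_size = 2e5, coverage = 30,
                                 error_kmer_fraction = 0.1, seed = 1)
  sp_err <- gen_kmer_spectrum(cfg_err)
  tot <- kmer_totals(sp_err)
  err_instances <- sum(sp_err$count[sp_err$occurrence <= 2] *
                       sp_err$occurrence[sp_err$occurrence <= 2])
  expect_equal(err_instances / tot$Kn, 0.1, tolerance = 0.02)

  expect_error(spectrum_sim_config(1e6, coverage = 2), "coverage")
})

test_that("codon-pair simulation respects its contract", {
  p0 <- simulate_codon_pair(0, 2, 0.5, 50, seed = 1)
  expect_equal(p0$seq_a, p0$seq_b)

  p <- simulate_codon_pair(0.3, 2, 0.5, 100, seed = 2)
  expect_equal(nchar(p$seq_a), 300L)
  expect_identical(p, simulate_codon_pair(0.3, 2, 0.5, 100, seed = 2))
  # codon_pair() validated: no stops, pure ACGT, equal length

  # at large t the descendant forgets the ancestor and samples pi
  big <- simulate_codon_pair(40, 2, 1, 12200, seed = 3)
  idx <- seq(1, nchar(big$seq_b), 3)
  freqs <- table(factor(substring(big$seq_b, idx, idx + 2),
                        levels = sense_codons())) / 12200
  # each codon frequency within 4 SDs of 1/61
  se <- sqrt((1 / 61) * (60 / 61) / 12200)
  expect_true(all(abs(freqs - 1 / 61) < 4 * se))
})
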