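# Sliding-window cluster-density scan and hotspot ranking.

test_that("a single full-chromosome window scores clusters per gene", {
  len <- c(chr1 = 1e8)
  genes <- data.frame(chrom = "chr1",
                      start = seq(0, 99e6, length.out = 100),
                      end = seq(0, 99e6, length.out = 100) + 1000,
                      gene_id = sprintf("g%03d", 1:100))
  clusters <- data.frame(chrom = "chr1", start = c(1e6, 5e7),
                         end = c(1.2e6, 5.02e7),
                         cluster_id = c("c1", "c2"))
  sc <- window_scan(genes, clusters, window = 1e8, slide = 1e8,
                    chrom_lengths = len)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$n_genes, 100)
  expect_equal(sc$n_clusters, 2)
  expect_equal(sc$score, 0.02)
})

test_that("zero clusters give zero scores everywhere", {
  toy <- random_toy_genome(11)
  sc <- window_scan(toy$genes, toy$clusters[0, ], window = 1e6,
                    slide = 1e5, chrom_lengths = c(chr1 = toy$len))
  expect_true(all(sc$n_clusters == 0))
  expect_true(all(sc$score[sc$defined] == 0))
})

test_that("window counts match the exhaustive membership oracle", {
  for (seed in 1:25) {
    toy <- random_toy_genome(seed)
    sc <- window_scan(toy$genes, toy$clusters, window = 1e6, slide = 1e5,
                      chrom_lengths = c(chr1 = toy$len))
    expect_equal(sc$n_genes,
                 oracle_window_counts(toy$genes, "chr1",
                                      sc$window_start, sc$window_end))
    expect_equal(sc$n_clusters,
                 oracle_window_counts(toy$clusters, "chr1",
                                      sc$window_start, sc$window_end))
  }
})

test_that("midpoint assignment partitions features over a disjoint tiling", {
  toy <- random_toy_genome(42)
  sc <- window_scan(toy$genes, toy$clusters, window = 7e5, slide = 7e5,
                    chrom_lengths = c(chr1 = toy$len))
  expect_equal(sum(sc$n_genes), nrow(toy$genes))
  expect_equal(sum(sc$n_clusters), nrow(toy$clusters))
})

test_that("scan is invariant to feature order and coordinate scaling", {
  toy <- random_toy_genome(7)
  sc <- window_scan(toy$genes, toy$clusters, window = 1e6, slide = 2e5,
                    chrom_lengths = c(chr1 = toy$len))
  perm <- sample(nrow(toy$genes))
  sc2 <- window_scan(toy$genes[perm, ], toy$clusters, window = 1e6,
                     slide = 2e5, chrom_lengths = c(chr1 = toy$len))
  expect_equal(sc2, sc)
  # scaling all coordinates by a constant leaves counts and scores intact
  k <- 4
  genes_k <- transform(toy$genes, start = start * k, end = end * k)
  clusters_k <- transform(toy$clusters, start = start * k, end = end * k)
  sc3 <- window_scan(genes_k, clusters_k, window = 1e6 * k, slide = 2e5 * k,
                     chrom_lengths = c(chr1 = toy$len * k))
  expect_equal(sc3$n_genes, sc$n_genes)
  expect_equal(sc3$n_clusters, sc$n_clusters)
  expect_equal(sc3$score, sc$score)
})

test_that("features beyond the chromosome end are rejected by name", {
  genes <- data.frame(chrom = "chr1", start = 5e5, end = 2e6,
                      gene_id = "runaway")
  expect_error(
    window_scan(genes, genes[0, c(1:3)] |> transform(cluster_id = character(0)),
                window = 1e6, slide = 1e6, chrom_lengths = c(chr1 = 1e6)),
    "runaway")
})

test_that("hotspot ranking sorts by score with deterministic tie-breaks", {
  sc <- data.frame(chrom = "chr1", window_start = c(0, 10, 20),
                   window_end = c(100, 110, 120),
                   n_clusters = c(1, 5, 2), n_genes = c(100, 100, 100),
                   score = c(0.01, 0.05, 0.02), defined = TRUE)
  rk <- rank_hotspots(sc)
  expect_equal(rk$window_start, c(10, 20, 0))
  # equal scores: higher n_clusters first
  sc2 <- data.frame(chrom = "chr1", window_start = c(0, 10),
                    window_end = c(100, 110),
                    n_clusters = c(2, 4), n_genes = c(100, 200),
                    score = c(0.02, 0.02), defined = TRUE)
  expect_equal(rank_hotspots(sc2)$window_start, c(10, 0))
  # undefined windows are dropped; all undefined is an error
  sc3 <- sc; sc3$score <- NA_real_
  expect_error(rank_hotspots(sc3), "undefined")
})

test_that("a planted hotspot is recovered as the top-ranked window", {
  ann <- gen_annotation(hotspot_sim_config(seed = 7))
  sc <- window_scan(ann$genes, ann$clusters, window = 1e6, slide = 5e5,
                    chrom_lengths = c(chr1 = 1e7))
  top <- rank_hotspots(sc, top_n = 1)
  # the planted hotspot occupies [2 Mb, 3 Mb)
  expect_gte(top$window_end, 2e6)
  expect_lte(top$window_start, 3e6)
})

test_that("the co-expression filter flags clusters by strict r threshold", {
  mk_res <- function(r) structure(
    list(bait_id = names(r)[1], r = r, n_samples = 12,
         undefined = character(0)),
    class = "coexpression_result")
  clusters <- data.frame(cluster_id = c("c1", "c2"))
  clusters$member_gene_ids <- list(c("b1", "g1", "g2", "g3"),
                                   c("b2", "h1", "h2"))
  coexpr <- list(
    c1 = mk_res(c(b1 = 1.0, g1 = 0.9, g2 = 0.86, g3 = 0.2)),
    c2 = mk_res(c(b2 = 1.0, h1 = 0.85, h2 = 0.85)))
  res <- coexpressed_cluster_count(clusters, coexpr)
  expect_equal(res$clusters$flagged, c(TRUE, FALSE))  # 0.85 is not > 0.85
  expect_equal(res$n_flagged, 1L)
})
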