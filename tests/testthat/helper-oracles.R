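# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the window-membership oracle loops over every
# feature x window pair, the size-factor oracle is a direct transcription
# of the median-of-ratios formula, the matrix-exponential oracle uses
# Matrix::expm (scaling-and-squaring) instead of the package's
# eigendecomposition, and the colinearity oracle enumerates all
# permutations.

# Exhaustive O(features x windows) midpoint-membership counts.
oracle_window_counts <- function(features, chrom, starts, ends) {
  mid <- (features$start + features$end)[features$chrom == chrom] / 2
  vapply(seq_along(starts), function(i)
    sum(mid >= starts[i] & mid < ends[i]), integer(1))
}

# Median-of-ratios size factors, written out long-hand.
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(x) prod(x)^(1 / length(x)))
  keep <- apply(counts, 1, function(x) all(x > 0))
  sapply(seq_len(ncol(counts)), function(j)
    median(counts[keep, j] / geo[keep]))
}

# GY94 pairwise log-likelihood via Matrix::expm.
oracle_gy94_loglik <- function(pair, t, kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  P <- as.matrix(Matrix::expm(Q * t))
  codons <- sense_codons()
  idx <- seq(1, nchar(pair$seq_a), 3)
  ca <- substring(pair$seq_a, idx, idx + 2)
  cb <- substring(pair$seq_b, idx, idx + 2)
  ia <- match(ca, codons); ib <- match(cb, codons)
  sum(log(pi[ia] * P[cbind(ia, ib)]))
}

# All permutations of a small vector (n! rows).
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# Exact two-sided permutation p for Kendall tau by full enumeration.
oracle_exact_perm_p <- function(dist, ranks) {
  tau_obs <- cor(dist, ranks, method = "kendall")
  perms <- all_permutations(ranks)
  taus <- apply(perms, 1, function(r) cor(dist, r, method = "kendall"))
  mean(abs(taus) >= abs(tau_obs) - 1e-12)
}

# Random toy genome for scan-vs-oracle trials.
random_toy_genome <- function(seed) {
  set.seed(seed)
  len <- sample(2e6:5e6, 1)
  n_genes <- sample(50:200, 1)
  n_clusters <- sample(0:20, 1)
  gs <- sort(sample.int(len - 1000L, n_genes))
  genes <- data.frame(chrom = "chr1", start = gs, end = gs + 500,
                      gene_id = sprintf("g%03d", seq_len(n_genes)))
  cs <- if (n_clusters > 0) sort(sample.int(len - 20000L, n_clusters)) else
    integer(0)
  clusters <- data.frame(chrom = rep("chr1", n_clusters), start = cs,
                         end = cs + 10000,
                         cluster_id = sprintf("c%03d", seq_len(n_clusters)))
  list(genes = genes, clusters = clusters, len = len)
}

# A small planted-hotspot scan configuration shared by recovery tests.
hotspot_sim_config <- function(seed) {
  annotation_sim_config(
    chromosome_lengths = c(chr1 = 1e7),
    n_genes = 1000,
    background_cluster_rate = 0.002,
    hotspot = list(chrom = "chr1", start = 2e6, end = 3e6, rate = 0.05),
    seed = seed)
}

# A planted 8-gene co-expression simulation: root-tip-high profile over
# six tissues, two replicates each.
planted_expression_config <- function(seed, dispersion = 0.05) {
  expression_sim_config(
    n_genes = 200,
    tissues = c(root = 2, root_tip = 2, leaf = 2, panicle = 2,
                shoot = 2, spikelet = 2),
    planted_genes = sprintf("cl_g%02d", 1:8),
    planted_profile = c(root = 150, root_tip = 2000, leaf = 10,
                        panicle = 10, shoot = 15, spikelet = 10),
    dispersion = dispersion,
    seed = seed)
}
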