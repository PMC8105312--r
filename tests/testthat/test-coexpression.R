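# Median-of-ratios normalisation, bait correlations, Z-scores.

test_that("size factors are 1 for identical samples and split a 2x scaling", {
  m <- matrix(c(10, 30, 50, 10, 30, 50), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 30, 50), s2 = c(20, 60, 100))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
})

test_that("size factors match independent implementations of the formula", {
  set.seed(1)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 5) + 1L, ncol = 6,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  expect_equal(unname(size_factors(m)), oracle_size_factors(m),
               tolerance = 1e-10)
  # odd gene count: the median is a single ratio, so the linear-scale
  # median here coincides exactly with DESeq2 log-scale median
  m_odd <- m[1:199, ]
  expect_equal(unname(size_factors(m_odd)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m_odd)),
               tolerance = 1e-10)
})

test_that("size factors are equivariant under scaling one sample", {
  # Scaling sample j by c multiplies its factor by c relative to the
  # others: the geometric-mean reference shifts every factor by c^(-1/m),
  # so the invariance is in the factor ratios.
  set.seed(2)
  m <- matrix(rnbinom(100 * 4, mu = 50, size = 5) + 1L, ncol = 4,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
  sf <- size_factors(m)
  m2 <- m; m2[, 2] <- m[, 2] * 3
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2 / sf), c(1, 3, 1, 1) * 3^(-1 / 4),
               tolerance = 1e-12)
})

test_that("all-zero-bearing matrices need a pseudocount", {
  m <- matrix(c(0, 5, 3, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m), "pseudocount")
  expect_length(size_factors(m, pseudocount = 1), 2)
})

test_that("normalisation divides by factors and round-trips", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_equal(normalize_counts(m, c(1, 1, 1)), m, ignore_attr = TRUE)
  f <- c(a = 2, b = 1, c = 4)
  n <- normalize_counts(m, f)
  expect_equal(sweep(n, 2, f, "*"), m, ignore_attr = TRUE)
  expect_error(normalize_counts(m, c(1, 2)), "one size factor per sample")
})

test_that("bait correlations follow the Pearson formula", {
  norm <- rbind(bait = c(1, 2, 3, 4),
                same = c(2, 4, 6, 8),
                anti = 10 - c(1, 2, 3, 4),
                hand = c(1, 3, 2, 4),
                flat = c(5, 5, 5, 5))
  colnames(norm) <- paste0("s", 1:4)
  res <- bait_correlation(norm, "bait")
  expect_equal(res$r[["bait"]], 1)
  expect_equal(res$r[["same"]], 1)
  expect_equal(res$r[["anti"]], -1)
  expect_equal(res$r[["hand"]], 0.8)
  expect_true(is.na(res$r[["flat"]]))
  expect_equal(res$undefined, "flat")
  expect_error(bait_correlation(norm, "flat"), "zero variance")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(3)
  norm <- matrix(rlnorm(5 * 8), 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  r1 <- bait_correlation(norm, "g1")$r
  norm2 <- norm; norm2["g3", ] <- 2.5 * norm["g3", ] + 7
  r2 <- bait_correlation(norm2, "g1")$r
  expect_equal(r2, r1)
})

test_that("bait selection takes the highest mean with lexicographic ties", {
  norm <- rbind(b = c(5, 5), a = c(9, 9), c = c(2, 2))
  colnames(norm) <- c("s1", "s2")
  expect_equal(select_bait(norm), "a")
  expect_equal(select_bait(norm, "c"), "c")
  norm_tie <- rbind(zz = c(4, 4), aa = c(4, 4))
  colnames(norm_tie) <- c("s1", "s2")
  expect_equal(select_bait(norm_tie), "aa")
})

test_that("Z-scores standardise rows and flag constant genes", {
  norm <- rbind(g1 = c(0, 10), g2 = c(3, 3))
  colnames(norm) <- c("s1", "s2")
  z <- zscore_matrix(norm)
  expect_equal(unname(z["g1", ]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z["g2", ]), c(0, 0))
  expect_equal(attr(z, "constant_genes"), "g2")

  set.seed(4)
  big <- matrix(rlnorm(10 * 6), 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  zb <- zscore_matrix(big)
  expect_equal(unname(rowMeans(zb)), rep(0, 10))
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 10))
})
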