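# GY94 rate matrix, likelihood, ML fitting and the dN/dS = 1 LRT.

test_that("the rate matrix is a proper reversible generator", {
  set.seed(5)
  pi <- rlnorm(61); pi <- pi / sum(pi)
  Q <- gy94_rate_matrix(kappa = 3, omega = 0.4, pi = pi)
  expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
  # scaled to one expected substitution per codon per unit time
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance: pi_i q_ij = pi_j q_ji
  flux <- pi * Q
  expect_equal(flux, t(flux), tolerance = 1e-12)
  # pi is stationary for P(t)
  P <- bgcevol:::.gy94_prob(Q, 0.8, pi)
  expect_equal(as.numeric(pi %*% P), pi, tolerance = 1e-10)
  expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
})

test_that("the likelihood matches a scaling-and-squaring expm oracle", {
  p <- simulate_codon_pair(0.5, 2, 0.3, 200, seed = 6)
  pi_sets <- list(rep(1 / 61, 61), f3x4_frequencies(p))
  set.seed(7)
  for (i in 1:6) {
    t <- runif(1, 0.01, 2); kappa <- runif(1, 0.5, 8)
    omega <- runif(1, 0.05, 3)
    for (pi in pi_sets) {
      expect_equal(gy94_loglik(p, t, kappa, omega, pi),
                   oracle_gy94_loglik(p, t, kappa, omega, pi),
                   tolerance = 1e-9)
    }
  }
})

test_that("an identical pair fits to the branch-length floor", {
  p <- codon_pair(strrep("ATGAAACCCGGG", 20), strrep("ATGAAACCCGGG", 20))
  f <- gy94_fit(p, freqs = "equal")
  expect_lt(f$t_hat, 1e-5)
  # at t ~ 0 the likelihood is just the codon frequencies of one sequence
  expect_equal(f$logL, 80 * log(1 / 61), tolerance = 1e-3)
})

test_that("fitting is symmetric in the two sequences", {
  p <- simulate_codon_pair(0.4, 2, 0.5, 150, seed = 8)
  swapped <- codon_pair(p$seq_b, p$seq_a)
  f1 <- gy94_fit(p, freqs = "equal")
  f2 <- gy94_fit(swapped, freqs = "equal")
  expect_equal(f2$logL, f1$logL, tolerance = 1e-6)
  expect_equal(f2$omega_hat, f1$omega_hat, tolerance = 1e-4)
})

test_that("omega is recovered from simulated pairs", {
  om <- vapply(1:8, function(s) {
    p <- simulate_codon_pair(0.3, 2, 0.2, 500, seed = 300 + s)
    gy94_fit(p, freqs = "equal")$omega_hat
  }, numeric(1))
  expect_gte(median(om), 0.15)
  expect_lte(median(om), 0.25)
})

test_that("the LRT compares free and fixed fits on the chi-squared(1) scale", {
  mk_fit <- function(logL, omega = NULL) structure(
    list(t_hat = 0.3, kappa_hat = 2,
         omega_hat = if (is.null(omega)) 0.5 else omega,
         omega_fixed = !is.null(omega), logL = logL, converged = TRUE,
         codon_freqs = rep(1 / 61, 61), n_codons = 100L),
    class = "gy94_fit")
  # equal likelihoods: no evidence against omega = 1
  r0 <- lrt(mk_fit(-1000), mk_fit(-1000, omega = 1))
  expect_equal(r0$stat, 0)
  expect_equal(r0$p, 1)
  # the 5% critical value of chi-squared(1)
  r <- lrt(mk_fit(-1000 + 3.841459 / 2), mk_fit(-1000, omega = 1))
  expect_equal(r$stat, 3.841459)
  expect_equal(r$p, 0.05, tolerance = 1e-6)
  # adding a constant to both log-likelihoods changes nothing
  r2 <- lrt(mk_fit(-500 + 3.841459 / 2), mk_fit(-500, omega = 1))
  expect_equal(r2$stat, r$stat)
  # free model must dominate the nested fixed model
  expect_error(lrt(mk_fit(-1001), mk_fit(-1000, omega = 1)),
               "optimiser failure")
  # argument roles are checked
  expect_error(lrt(mk_fit(-1000, omega = 1), mk_fit(-1000, omega = 1)),
               "omega estimated")
  expect_error(lrt(mk_fit(-1000), mk_fit(-1000, omega = 0.5)),
               "fixed at 1")
})

test_that("the LRT pipeline detects strong purifying selection", {
  p <- simulate_codon_pair(0.4, 2, 0.1, 400, seed = 9)
  free <- gy94_fit(p, freqs = "equal")
  fixed <- gy94_fit(p, fix_omega = 1, freqs = "equal")
  r <- lrt(free, fixed)
  expect_true(r$significant)
  expect_lt(free$omega_hat, 0.3)
})
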