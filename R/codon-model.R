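# Goldman-Yang (GY94) codon substitution model: rate matrix, transition
# probabilities, pairwise maximum-likelihood fitting, and the dN/dS = 1
# likelihood-ratio test.

# 61 sense codons of the standard genetic code, with their amino acids.
.codon_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  tab <- list(
    codons = sense,
    aa = unname(gc[sense]),
    nts = do.call(rbind, strsplit(sense, "")),
    index = setNames(seq_along(sense), sense)
  )
  .codon_env$tab <- tab
  tab
}

#' The 61 sense codons of the standard genetic code
#' @return Character vector of codons, alphabetical, stop codons excluded.
#' @export
sense_codons <- function() .codon_table()$codons

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Classify all single-nucleotide codon moves once: for each ordered sense
# pair differing at one position, whether the change is a transition and
# whether it is synonymous.
.codon_moves <- function() {
  if (!is.null(.codon_env$moves)) return(.codon_env$moves)
  tab <- .codon_table()
  n <- length(tab$codons)
  from <- integer(0); to <- integer(0); ts <- logical(0); syn <- logical(0)
  nts <- tab$nts
  for (i in seq_len(n)) {
    diffs <- sweep(nts, 2, nts[i, ], FUN = "!=")
    nd <- rowSums(diffs)
    js <- which(nd == 1L)
    for (j in js) {
      pos <- which(diffs[j, ])
      from <- c(from, i); to <- c(to, j)
      ts <- c(ts, .is_transition(nts[i, pos], nts[j, pos]))
      syn <- c(syn, tab$aa[i] == tab$aa[j])
    }
  }
  .codon_env$moves <- list(from = from, to = to, transition = ts,
                           synonymous = syn)
  .codon_env$moves
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61x61 Goldman-Yang rate matrix over sense codons. The rate
#' from codon i to codon j is zero unless the codons differ at exactly one
#' nucleotide, and otherwise proportional to the target codon frequency
#' `pi[j]`, times `kappa` for a transition, times `omega` for a
#' nonsynonymous change. The matrix is scaled so that
#' `-sum(pi * diag(Q)) = 1`, making branch length `t` the expected number
#' of substitutions per codon.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (> 0).
#' @param pi codon frequencies over [sense_codons()] (length 61, sums to 1).
#' @return 61x61 rate matrix with dimnames the sense codons.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  .check_number(kappa, "kappa", min = 0, strict_min = TRUE)
  .check_number(omega, "omega", min = 0, strict_min = TRUE)
  tab <- .codon_table()
  if (length(pi) != 61L || any(pi < 0))
    stop("'pi' must be 61 nonnegative frequencies", call. = FALSE)
  pi <- pi / sum(pi)
  mv <- .codon_moves()
  n <- 61L
  Q <- matrix(0, n, n, dimnames = list(tab$codons, tab$codons))
  rate <- pi[mv$to]
  rate[mv$transition] <- rate[mv$transition] * kappa
  rate[!mv$synonymous] <- rate[!mv$synonymous] * omega
  Q[cbind(mv$from, mv$to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero total rate)", call. = FALSE)
  Q / scale
}

# Transition probabilities P(t) = expm(Q t) via symmetric eigendecomposition
# of the reversible Q (pi_i q_ij = pi_j q_ji). Zero-frequency codons are
# handled by restricting to the support of pi.
.gy94_prob <- function(Q, t, pi) {
  pos <- pi > 0
  n <- length(pi)
  P <- diag(n)
  s <- sqrt(pi[pos])
  B <- Q[pos, pos, drop = FALSE] * outer(s, 1 / s)
  B <- (B + t(B)) / 2  # symmetrise away rounding noise
  e <- eigen(B, symmetric = TRUE)
  Ppos <- (e$vectors * rep(exp(e$values * t), each = sum(pos))) %*% t(e$vectors)
  Ppos <- Ppos * outer(1 / s, s)
  Ppos[Ppos < 0] <- 0
  P[pos, pos] <- Ppos
  dimnames(P) <- dimnames(Q)
  P
}

#' F3x4 codon frequencies from an aligned pair
#'
#' Estimates codon frequencies as the product of position-specific
#' nucleotide frequencies (codon positions 1-3) computed from both
#' sequences pooled, renormalised over the 61 sense codons.
#'
#' @param pair a [codon_pair()].
#' @return Numeric vector of 61 frequencies over [sense_codons()].
#' @export
f3x4_frequencies <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  tab <- .codon_table()
  nt <- c(strsplit(pair$seq_a, "")[[1]], strsplit(pair$seq_b, "")[[1]])
  pos <- rep(rep(1:3, length.out = nchar(pair$seq_a)), 2)
  freq <- vapply(1:3, function(p) {
    f <- table(factor(nt[pos == p], levels = c("A", "C", "G", "T")))
    as.numeric(f) / sum(f)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  pi <- freq[tab$nts[, 1], 1] * freq[tab$nts[, 2], 2] * freq[tab$nts[, 3], 3]
  pi <- unname(pi)
  if (sum(pi) <= 0) stop("degenerate F3x4 frequencies", call. = FALSE)
  pi / sum(pi)
}

# Cross-tabulate aligned codons of a pair into a 61x61 count matrix.
.pair_codon_counts <- function(pair) {
  tab <- .codon_table()
  ca <- substring(pair$seq_a, seq(1, nchar(pair$seq_a), 3),
                  seq(3, nchar(pair$seq_a), 3))
  cb <- substring(pair$seq_b, seq(1, nchar(pair$seq_b), 3),
                  seq(3, nchar(pair$seq_b), 3))
  ia <- tab$index[ca]; ib <- tab$index[cb]
  counts <- matrix(0, 61, 61)
  for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1
  counts
}

#' GY94 pairwise log-likelihood at fixed parameters
#'
#' For an unrooted two-sequence tree the likelihood of an aligned codon
#' site (a, b) is `pi[a] * P[a, b](t)`; by reversibility the rooting does
#' not matter. Summed log-likelihood over sites.
#'
#' @param pair a [codon_pair()].
#' @param t branch length, expected substitutions per codon.
#' @param kappa,omega GY94 rate parameters.
#' @param pi codon frequencies (61); default equal.
#' @return Log-likelihood (scalar).
#' @export
gy94_loglik <- function(pair, t, kappa, omega, pi = rep(1 / 61, 61)) {
  stopifnot(inherits(pair, "codon_pair"))
  .check_number(t, "t", min = 0)
  counts <- .pair_codon_counts(pair)
  .gy94_loglik_counts(counts, t, kappa, omega, pi / sum(pi))
}

.gy94_loglik_counts <- function(counts, t, kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  P <- .gy94_prob(Q, t, pi)
  L <- pi * P  # joint site probability matrix
  nz <- counts > 0
  if (any(L[nz] <= 0)) return(-Inf)
  sum(counts[nz] * log(L[nz]))
}

# Parameter bounds (natural scale).
.gy94_bounds <- list(t = c(1e-6, 50), kappa = c(1e-2, 1e2), omega = c(1e-4, 20))

#' Fit the GY94 model to an aligned codon pair by maximum likelihood
#'
#' Maximises the pairwise GY94 log-likelihood over branch length `t`,
#' transition/transversion ratio `kappa`, and dN/dS `omega` (or over
#' `t, kappa` only when `fix_omega` is given, e.g. `fix_omega = 1` for the
#' null model of the dN/dS likelihood-ratio test). The search is
#' log-parameterised, bounded (t in [1e-6, 50], kappa in [0.01, 100],
#' omega in [1e-4, 20]) and run from multiple starting points; the best
#' log-likelihood wins, ties going to the smaller `t`.
#'
#' @param pair a [codon_pair()].
#' @param fix_omega `NULL` (estimate omega) or a fixed positive value.
#' @param freqs `"F3x4"` (default; position-specific nucleotide frequencies
#'   from the pair) or `"equal"`.
#' @param n_starts number of optimiser starting points (>= 3 recommended).
#' @return An object of class `gy94_fit`: list with `t_hat`, `kappa_hat`,
#'   `omega_hat`, `omega_fixed` (logical), `logL`, `converged`,
#'   `codon_freqs`, `n_codons`.
#' @seealso [lrt()] for the free-vs-fixed omega test.
#' @export
gy94_fit <- function(pair, fix_omega = NULL, freqs = c("F3x4", "equal"),
                     n_starts = 3L) {
  stopifnot(inherits(pair, "codon_pair"))
  freqs <- match.arg(freqs)
  if (!is.null(fix_omega))
    .check_number(fix_omega, "fix_omega", min = 0, strict_min = TRUE)
  pi <- if (freqs == "F3x4") f3x4_frequencies(pair) else rep(1 / 61, 61)
  counts <- .pair_codon_counts(pair)
  n_codons <- sum(counts)

  # Crude starting branch length from the raw codon mismatch fraction.
  p_diff <- 1 - sum(diag(counts)) / n_codons
  t0 <- max(0.05, min(3, -log(max(1 - p_diff, 1e-3))))

  b <- .gy94_bounds
  free_omega <- is.null(fix_omega)
  obj <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2])
    omega <- if (free_omega) exp(par[3]) else fix_omega
    -.gy94_loglik_counts(counts, t, kappa, omega, pi)
  }
  omega_starts <- c(0.3, 1, 3)
  starts <- lapply(seq_len(max(3L, n_starts)), function(i) {
    s <- c(log(t0 * c(1, 0.3, 3)[(i - 1L) %% 3L + 1L]), log(2))
    if (free_omega) s <- c(s, log(omega_starts[(i - 1L) %% 3L + 1L]))
    s
  })
  lower <- log(c(b$t[1], b$kappa[1], if (free_omega) b$omega[1]))
  upper <- log(c(b$t[2], b$kappa[2], if (free_omega) b$omega[2]))

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) ||
        fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best))
    stop("GY94 optimisation failed from every starting point", call. = FALSE)
  structure(list(
    t_hat = exp(best$par[1]),
    kappa_hat = exp(best$par[2]),
    omega_hat = if (free_omega) exp(best$par[3]) else fix_omega,
    omega_fixed = !free_omega,
    logL = -best$value,
    converged = any_conv,
    codon_freqs = pi,
    n_codons = n_codons
  ), class = "gy94_fit")
}

#' @export
print.gy94_fit <- function(x, ...) {
  cat(sprintf(
    "GY94 pairwise fit (%d codons): t = %.4g, kappa = %.4g, omega = %.4g%s\n",
    x$n_codons, x$t_hat, x$kappa_hat, x$omega_hat,
    if (x$omega_fixed) " (fixed)" else ""))
  cat(sprintf("  logL = %.4f, converged = %s\n", x$logL, x$converged))
  invisible(x)
}

#' Likelihood-ratio test of dN/dS = 1
#'
#' Compares a free-omega GY94 fit against a fit with omega fixed at 1.
#' Twice the log-likelihood difference is referred to a chi-squared
#' distribution with one degree of freedom; omega = 1 is interior to the
#' parameter space, so the plain chi-squared(1) calibration applies.
#'
#' @param free a [gy94_fit()] with omega estimated.
#' @param fixed a [gy94_fit()] with `fix_omega = 1`.
#' @param alpha significance level for the `significant` flag.
#' @return An object of class `lrt_result`: list with `stat`
#'   (2 * (logL_free - logL_fixed), clamped at 0), `df = 1`, `p`
#'   (upper-tail chi-squared), `significant`.
#' @export
#' @examples
#' # A statistic of 3.841459 sits exactly at the 5% critical value:
#' pchisq(3.841459, df = 1, lower.tail = FALSE)
lrt <- function(free, fixed, alpha = 0.05) {
  stopifnot(inherits(free, "gy94_fit"), inherits(fixed, "gy94_fit"))
  if (free$omega_fixed)
    stop("'free' fit must have omega estimated, not fixed", call. = FALSE)
  if (!fixed$omega_fixed || abs(fixed$omega_hat - 1) > 1e-12)
    stop("'fixed' fit must have omega fixed at 1", call. = FALSE)
  if (!isTRUE(free$converged) || !isTRUE(fixed$converged))
    stop("both fits must have converged", call. = FALSE)
  stat <- 2 * (free$logL - fixed$logL)
  if (stat < -1e-6)
    stop("free-model log-likelihood below fixed-model log-likelihood: ",
         "optimiser failure (the free model nests the fixed model)",
         call. = FALSE)
  stat <- max(stat, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(stat = stat, df = 1L, p = p,
                 significant = p < alpha, alpha = alpha),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT of dN/dS = 1: 2*dlogL = %.4f, df = 1, p = %.4g%s\n",
              x$stat, x$p,
              if (x$significant) sprintf(" (significant at %g)", x$alpha) else ""))
  invisible(x)
}

#' Divergence time from mean synonymous divergence
#'
#' Converts a mean pairwise synonymous substitution rate (Ks, substitutions
#' per synonymous site) between two lineages into a divergence time using a
#' molecular clock: `T = Ks / (2 * rate)`. The factor 2 accounts for
#' substitutions accumulating along both lineages since their split.
#'
#' @param mean_ks mean Ks of orthologous gene pairs (>= 0).
#' @param rate substitution rate per site per year. The default 6.5e-9 is a
#'   widely used grass synonymous clock rate.
#' @return List with `mean_ks`, `rate`, `time_years`, `time_mya`.
#' @export
#' @examples
#' divergence_time(0.3705)$time_mya  # 28.5
divergence_time <- function(mean_ks, rate = 6.5e-9) {
  .check_number(mean_ks, "mean_ks", min = 0)
  .check_number(rate, "rate", min = 0, strict_min = TRUE)
  t <- mean_ks / (2 * rate)
  list(mean_ks = mean_ks, rate = rate, time_years = t, time_mya = t / 1e6)
}
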