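# Simulation of aligned codon pairs under the GY94 model, the ground-truth
# oracle for the maximum-likelihood fitting and the dN/dS likelihood-ratio
# test.

#' Simulate an aligned codon pair under the GY94 model
#'
#' Draws an ancestral sequence of `n_codons` sense codons from the codon
#' frequency distribution `pi`, then evolves each codon independently for
#' branch length `t` under the GY94 rate matrix with the given `kappa` and
#' `omega`, sampling the descendant codon from the exact matrix-exponential
#' transition probabilities. Stop codons are excluded from the state space,
#' so the resulting pair is a valid [codon_pair()] by construction.
#'
#' @param t branch length in expected substitutions per codon (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (> 0).
#' @param n_codons number of codon sites (>= 1).
#' @param freqs codon frequencies: `"equal"` (default) or a numeric vector
#'   of 61 frequencies over [sense_codons()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [codon_pair()] with attribute `truth` echoing the simulation
#'   parameters.
#' @export
#' @examples
#' p <- simulate_codon_pair(t = 0.3, kappa = 2, omega = 0.2,
#'                          n_codons = 100, seed = 1)
#' ng86(p)
simulate_codon_pair <- function(t, kappa, omega, n_codons,
                                freqs = "equal", seed = NULL) {
  .check_number(t, "t", min = 0)
  .check_number(kappa, "kappa", min = 0, strict_min = TRUE)
  .check_number(omega, "omega", min = 0, strict_min = TRUE)
  .check_number(n_codons, "n_codons", min = 1)
  if (identical(freqs, "equal")) {
    pi <- rep(1 / 61, 61)
  } else {
    if (!is.numeric(freqs) || length(freqs) != 61L || any(freqs < 0))
      stop("'freqs' must be \"equal\" or 61 nonnegative frequencies",
           call. = FALSE)
    pi <- freqs / sum(freqs)
  }
  codons <- sense_codons()
  .with_seed(seed, {
    anc_idx <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    if (t == 0) {
      des_idx <- anc_idx
    } else {
      Q <- gy94_rate_matrix(kappa, omega, pi)
      P <- .gy94_prob(Q, t, pi)
      des_idx <- integer(n_codons)
      for (a in unique(anc_idx)) {
        sel <- anc_idx == a
        des_idx[sel] <- sample.int(61L, sum(sel), replace = TRUE,
                                   prob = P[a, ])
      }
    }
    pair <- codon_pair(paste(codons[anc_idx], collapse = ""),
                       paste(codons[des_idx], collapse = ""))
    attr(pair, "truth") <- list(t = t, kappa = kappa, omega = omega,
                                freqs = pi)
    pair
  })
}
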