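# Synthetic k-mer occurrence spectra: Poisson depth per distinct genomic
# k-mer plus an error component at occurrence 1-2. The spectrum is
# simulated directly as a histogram (no read-level simulation): the
# genome-size formula consumes only the histogram.

#' Configuration for the k-mer spectrum simulator
#'
#' @param genome_size haploid genome size in bp (> 0). Treated as the
#'   number of distinct genomic k-mer positions.
#' @param coverage mean k-mer depth of the sequencing run (> 2, so the
#'   coverage peak is separable from the error peak).
#' @param error_kmer_fraction fraction of all k-mer instances that are
#'   sequencing-error words, placed at occurrence 1-2 (in \[0, 1)).
#' @param repeat_fraction fraction of the genome whose k-mers are
#'   two-copy repeats, i.e. observed at doubled depth (in \[0, 1)).
#' @param k k-mer length (metadata).
#' @param seed integer seed.
#' @return Validated list of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(genome_size, coverage,
                                error_kmer_fraction = 0,
                                repeat_fraction = 0, k = 55L, seed = 1L) {
  .check_number(genome_size, "genome_size", min = 0, strict_min = TRUE)
  .check_number(coverage, "coverage", min = 2, strict_min = TRUE)
  .check_number(error_kmer_fraction, "error_kmer_fraction", min = 0)
  .check_number(repeat_fraction, "repeat_fraction", min = 0)
  if (error_kmer_fraction >= 1 || repeat_fraction >= 1)
    stop("fractions must be in [0, 1)", call. = FALSE)
  .check_number(seed, "seed")
  structure(list(genome_size = genome_size, coverage = coverage,
                 error_kmer_fraction = error_kmer_fraction,
                 repeat_fraction = repeat_fraction, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "spectrum_sim_config")
}

#' Simulate a k-mer occurrence spectrum
#'
#' Draws a Poisson depth for each distinct genomic k-mer -- at the mean
#' coverage for single-copy k-mers, at twice the mean for the repeat
#' fraction (two genomic copies pooled into one distinct word) -- and
#' tabulates the occurrence histogram. Error words are then added at
#' occurrence 1 (90% of error instances) and occurrence 2 (10%), scaled so
#' they make up the configured fraction of all instances. K-mers that
#' receive depth 0 are unobserved and drop out, as in a real spectrum.
#'
#' @param config a [spectrum_sim_config()].
#' @return A [kmer_spectrum()].
#' @export
gen_kmer_spectrum <- function(config) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  .with_seed(config$seed, {
    n_repeat_bp <- round(config$genome_size * config$repeat_fraction)
    n_single <- round(config$genome_size - n_repeat_bp)
    n_repeat_words <- floor(n_repeat_bp / 2)
    depths <- c(rpois(n_single, config$coverage),
                rpois(n_repeat_words, 2 * config$coverage))
    depths <- depths[depths > 0]
    hist <- tabulate(depths)
    f <- config$error_kmer_fraction
    if (f > 0) {
      total <- sum(seq_along(hist) * hist)
      err_instances <- f * total / (1 - f)
      # 90% of error instances as singletons, 10% as doubletons
      n1 <- round(0.9 * err_instances)
      n2 <- round(0.05 * err_instances)
      hist[1] <- hist[1] + n1
      if (length(hist) < 2) hist <- c(hist, 0)
      hist[2] <- hist[2] + n2
    }
    occ <- which(hist > 0)
    kmer_spectrum(occ, hist[occ], k = config$k)
  })
}
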