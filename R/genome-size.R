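# Genome-size estimation from a k-mer occurrence spectrum or from
# flow-cytometric 2C DNA amounts.

#' k-mer occurrence spectrum
#'
#' A k-mer spectrum is the histogram of a read set's distinct k-mer words by
#' the number of times each word occurs: `histogram[occ]` is the number of
#' distinct words seen exactly `occ` times. For a largely homozygous genome
#' sequenced to depth c, the spectrum shows a low-occurrence error peak
#' (sequencing errors create words seen once or twice) and a main peak near
#' the k-mer coverage depth.
#'
#' @param occurrence integer vector of occurrence values (>= 1).
#' @param count number of distinct k-mer words at each occurrence (>= 0).
#' @param k k-mer word length in nucleotides (metadata only).
#' @return An object of class `kmer_spectrum`: a data frame with columns
#'   `occurrence` and `count`, sorted by occurrence, with attribute `k`.
#' @seealso [kmer_totals()], [detect_peak()], [estimate_genome_size_kmer()]
#' @export
#' @examples
#' sp <- kmer_spectrum(c(1, 28, 29, 30), c(1e6, 4e5, 6e5, 4e5), k = 55)
#' detect_peak(sp)
kmer_spectrum <- function(occurrence, count, k = NA_integer_) {
  if (length(occurrence) != length(count) || length(occurrence) == 0L)
    stop("'occurrence' and 'count' must be non-empty vectors of equal length",
         call. = FALSE)
  occurrence <- as.numeric(occurrence)
  count <- as.numeric(count)
  if (any(is.na(occurrence)) || any(is.na(count)))
    stop("spectrum contains missing values", call. = FALSE)
  if (any(occurrence < 1) || any(occurrence != round(occurrence)))
    stop("occurrences must be integers >= 1", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (anyDuplicated(occurrence))
    stop("duplicated occurrence values in spectrum", call. = FALSE)
  ord <- order(occurrence)
  out <- data.frame(occurrence = occurrence[ord], count = count[ord])
  attr(out, "k") <- k
  class(out) <- c("kmer_spectrum", "data.frame")
  out
}

#' Total and unique k-mer instance counts
#'
#' `Kn` is the total number of k-mer words in the read set (instances, i.e.
#' occurrence times distinct-word count, summed over the histogram); `Ku` is
#' the number of single-copy ("unique") words, the instances at occurrence 1.
#' Words seen once are overwhelmingly sequencing errors, so `Kn - Ku` is the
#' effective k-mer count that carries genome signal.
#'
#' @param spectrum a [kmer_spectrum()].
#' @return Named list with elements `Kn` and `Ku`.
#' @export
kmer_totals <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  Kn <- sum(spectrum$occurrence * spectrum$count)
  Ku <- sum(spectrum$count[spectrum$occurrence == 1])
  list(Kn = Kn, Ku = Ku)
}

#' Detect the coverage peak of a k-mer spectrum
#'
#' The peak depth `Dp` is located at or above `min_occurrence`, so the
#' error peak at occurrence 1-2 is not picked up. With
#' `min_occurrence = "auto"` the search floor is the first strict local
#' minimum of the (densified) histogram above occurrence 1 -- the valley
#' between the error peak and the coverage peak; plateau minima resolve to
#' their lowest occurrence, and a histogram that rises from occurrence 1
#' (no error peak) is searched from occurrence 1.
#'
#' The returned depth is the rounded intensity-weighted centroid of the
#' contiguous bins within half-maximum of the raw argmax. A raw argmax
#' alone is unstable by one occurrence unit when the underlying depth
#' distribution has near-tied modes (a Poisson depth at integer mean has
#' exactly tied modes at `c - 1` and `c`), which would propagate a
#' `1/Dp`-sized error into the genome-size estimate; the centroid restores
#' the peak's centre.
#'
#' @param spectrum a [kmer_spectrum()].
#' @param min_occurrence `"auto"` (default) or an integer floor for the
#'   peak search.
#' @return The peak depth `Dp` (integer occurrence).
#' @export
detect_peak <- function(spectrum, min_occurrence = "auto") {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  max_occ <- max(spectrum$occurrence)
  dense <- numeric(max_occ)
  dense[spectrum$occurrence] <- spectrum$count
  if (identical(min_occurrence, "auto")) {
    floor_occ <- NA
    if (max_occ >= 2 && dense[1] <= dense[2]) {
      # no error peak: the histogram rises from occurrence 1, so the
      # valley degenerates to the origin and the whole range is searched
      floor_occ <- 1L
    } else if (max_occ >= 3) {
      for (i in 2:(max_occ - 1L)) {
        if (dense[i - 1L] > dense[i] && dense[i] <= dense[i + 1L] &&
            any(dense[(i + 1L):max_occ] > dense[i])) {
          floor_occ <- i
          break
        }
      }
    }
    if (is.na(floor_occ))
      stop("no coverage peak detected (histogram has no valley after ",
           "occurrence 1); supply an explicit 'min_occurrence'",
           call. = FALSE)
  } else {
    .check_number(min_occurrence, "min_occurrence", min = 1)
    floor_occ <- min_occurrence
    if (!any(spectrum$occurrence >= floor_occ))
      stop("spectrum has no occurrence >= min_occurrence", call. = FALSE)
  }
  eligible <- floor_occ:max_occ
  peak <- eligible[which.max(dense[eligible])]
  # half-maximum centroid around the argmax, staying above the floor
  half <- dense[peak] / 2
  lo <- peak
  while (lo - 1L >= floor_occ && dense[lo - 1L] >= half) lo <- lo - 1L
  hi <- peak
  while (hi + 1L <= max_occ && dense[hi + 1L] >= half) hi <- hi + 1L
  win <- lo:hi
  as.integer(round(sum(win * dense[win]) / sum(dense[win])))
}

#' Estimate genome size from a k-mer spectrum
#'
#' The haploid genome size is `Gs = (Kn - Ku) / Dp`: the number of effective
#' (non-unique) k-mer words divided by the k-mer depth at the coverage peak.
#' Unique words, dominated by sequencing errors, are removed from the
#' numerator; the peak depth converts word instances to genomic positions.
#'
#' @param spectrum a [kmer_spectrum()].
#' @param peak_override optionally fix `Dp` instead of detecting it.
#' @param min_occurrence passed to [detect_peak()] when `Dp` is detected.
#' @return An object of class `genome_size_estimate`: a list with
#'   `genome_size` (bp), `genome_size_gb` (3 significant figures),
#'   `method = "kmer"`, `peak_depth`, and `inputs_echo` (the Kn/Ku/Dp used).
#' @export
#' @examples
#' # A deep whole-genome shotgun spectrum summarised by its totals:
#' sp <- kmer_spectrum(c(1, 29), c(12260521110, (124199810495 - 12260521110) / 29))
#' est <- estimate_genome_size_kmer(sp, peak_override = 29)
#' est$genome_size_gb  # 3.86
estimate_genome_size_kmer <- function(spectrum, peak_override = NULL,
                                      min_occurrence = "auto") {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (is.null(peak_override)) {
    Dp <- detect_peak(spectrum, min_occurrence)
  } else {
    .check_number(peak_override, "peak_override", min = 1)
    Dp <- peak_override
  }
  tot <- kmer_totals(spectrum)
  if (tot$Kn <= tot$Ku)
    stop("Kn <= Ku: no multi-copy k-mer signal to estimate genome size from",
         call. = FALSE)
  gs <- (tot$Kn - tot$Ku) / Dp
  structure(list(
    genome_size = gs,
    genome_size_gb = signif(gs / 1e9, 3),
    method = "kmer",
    peak_depth = Dp,
    inputs_echo = list(Kn = tot$Kn, Ku = tot$Ku, Dp = Dp)
  ), class = "genome_size_estimate")
}

#' Genome size from flow cytometry
#'
#' The sample's 2C DNA amount (pg) is the ratio of its G1 peak mean to the
#' internal standard's G1 peak mean, times the standard's known 2C value.
#' The 1C genome size in base pairs uses the conversion
#' 1 pg DNA = 0.978e9 bp.
#'
#' @param sample_g1_mean,standard_g1_mean G1 fluorescence peak means
#'   (arbitrary units, same scale) for sample and internal standard.
#' @param standard_2c_pg 2C DNA amount of the standard in pg. The default
#'   5.43 pg is the maize CE-777 reference commonly used for cereals.
#' @param pg_to_bp conversion factor, bp per pg.
#' @return A `genome_size_estimate` with `method = "flow_cytometry"`,
#'   `genome_size` the 1C size in bp, and `pg_2c` the sample 2C value.
#' @export
#' @examples
#' est <- flow_cytometry_size(8.486, 5.43, standard_2c_pg = 5.43)
#' est$pg_2c            # 8.486
#' signif(est$genome_size / 1e9, 2)  # ~4.1 Gb
flow_cytometry_size <- function(sample_g1_mean, standard_g1_mean,
                                standard_2c_pg = 5.43, pg_to_bp = 0.978e9) {
  .check_number(sample_g1_mean, "sample_g1_mean", min = 0, strict_min = TRUE)
  .check_number(standard_g1_mean, "standard_g1_mean", min = 0, strict_min = TRUE)
  .check_number(standard_2c_pg, "standard_2c_pg", min = 0, strict_min = TRUE)
  .check_number(pg_to_bp, "pg_to_bp", min = 0, strict_min = TRUE)
  pg_2c <- sample_g1_mean / standard_g1_mean * standard_2c_pg
  gs <- pg_2c / 2 * pg_to_bp
  structure(list(
    genome_size = gs,
    genome_size_gb = signif(gs / 1e9, 3),
    method = "flow_cytometry",
    pg_2c = pg_2c,
    inputs_echo = list(sample_g1_mean = sample_g1_mean,
                       standard_g1_mean = standard_g1_mean,
                       standard_2c_pg = standard_2c_pg,
                       pg_to_bp = pg_to_bp)
  ), class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Genome size estimate (%s): %s Gb (%.0f bp)\n",
              x$method, format(x$genome_size_gb), x$genome_size))
  if (!is.null(x$peak_depth))
    cat(sprintf("  peak depth Dp = %g\n", x$peak_depth))
  if (!is.null(x$pg_2c))
    cat(sprintf("  2C = %.3f pg\n", x$pg_2c))
  invisible(x)
}
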