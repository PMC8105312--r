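# Median-of-ratios normalisation and bait-gene co-expression analysis of
# RNA-seq count matrices.

.check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and sample ids must be unique", call. = FALSE)
  if (any(counts < 0) || any(is.na(counts)))
    stop("'counts' must be nonnegative and complete", call. = FALSE)
  invisible(counts)
}

#' Median-of-ratios size factors
#'
#' The per-sample normalisation factors of the median-of-ratios estimator:
#' for sample j, the factor is the median over genes of
#' `counts[i, j] / geometric_mean(counts[i, ])`, the geometric mean taken
#' across samples. Genes with a zero count in any sample are excluded from
#' the median (their geometric mean is zero); a pseudocount can be added to
#' rescue sparse matrices.
#'
#' @param counts nonnegative genes x samples matrix with dimnames.
#' @param pseudocount value added to every count before the computation
#'   (default 0).
#' @return Named positive numeric vector of per-sample size factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
size_factors <- function(counts, pseudocount = 0) {
  .check_counts(counts)
  .check_number(pseudocount, "pseudocount", min = 0)
  x <- counts + pseudocount
  log_geo_means <- rowMeans(log(x))
  eligible <- is.finite(log_geo_means)
  if (!any(eligible))
    stop("no gene has nonzero counts in every sample; consider a ",
         "'pseudocount'", call. = FALSE)
  geo <- exp(log_geo_means[eligible])
  sf <- apply(x[eligible, , drop = FALSE], 2, function(col)
    median(col / geo))
  setNames(sf, colnames(counts))
}

#' Normalise counts by size factors
#'
#' Divides each sample column by its size factor.
#'
#' @param counts genes x samples matrix.
#' @param factors per-sample positive factors, one per column (named
#'   vectors are matched by name).
#' @return Normalised matrix of the same shape.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  .check_counts(counts)
  if (length(factors) != ncol(counts))
    stop("need one size factor per sample", call. = FALSE)
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), colnames(counts)))
      stop("size factor names do not match sample ids", call. = FALSE)
    factors <- factors[colnames(counts)]
  }
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  sweep(counts, 2, factors, "/")
}

#' Bait-gene Pearson correlations
#'
#' Computes the Pearson correlation of each gene's normalised expression
#' profile against a bait gene across samples. Genes with zero variance get
#' an undefined (NA) correlation and are flagged; a zero-variance bait is
#' an error.
#'
#' @param norm normalised genes x samples matrix.
#' @param bait_id bait gene id (row of `norm`).
#' @param gene_ids genes to correlate (default all rows).
#' @return Object of class `coexpression_result`: list with `bait_id`,
#'   `r` (named vector, `r[bait_id] == 1`), `n_samples`,
#'   `undefined` (ids of zero-variance genes).
#' @export
bait_correlation <- function(norm, bait_id, gene_ids = rownames(norm)) {
  stopifnot(is.matrix(norm), !is.null(rownames(norm)))
  if (ncol(norm) < 3L)
    stop("need at least 3 samples for correlation", call. = FALSE)
  missing_genes <- setdiff(c(bait_id, gene_ids), rownames(norm))
  if (length(missing_genes))
    stop("gene(s) not in matrix: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  bait <- norm[bait_id, ]
  if (sd(bait) == 0)
    stop(sprintf("bait gene '%s' has zero variance", bait_id), call. = FALSE)
  sub <- norm[gene_ids, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  r <- rep(NA_real_, length(gene_ids))
  names(r) <- gene_ids
  ok <- sds > 0
  if (any(ok))
    r[ok] <- as.numeric(cor(bait, t(sub[ok, , drop = FALSE])))
  structure(list(bait_id = bait_id, r = r, n_samples = ncol(norm),
                 undefined = gene_ids[!ok]),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("Co-expression vs bait '%s' (%d genes, %d samples)\n",
              x$bait_id, length(x$r), x$n_samples))
  invisible(x)
}

#' Choose a representative bait gene
#'
#' Default bait rule for cluster co-expression screening: the member gene
#' with the highest mean normalised expression, ties broken by the
#' lexicographically smallest gene id.
#'
#' @param norm normalised genes x samples matrix.
#' @param gene_ids candidate gene ids (non-empty).
#' @return A single gene id.
#' @export
select_bait <- function(norm, gene_ids = rownames(norm)) {
  stopifnot(is.matrix(norm), length(gene_ids) >= 1L)
  missing_genes <- setdiff(gene_ids, rownames(norm))
  if (length(missing_genes))
    stop("gene(s) not in matrix: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  means <- rowMeans(norm[gene_ids, , drop = FALSE])
  gene_ids[order(-means, gene_ids)][1]
}

#' Per-gene Z-score matrix
#'
#' Standardises each gene's normalised expression across samples:
#' `(x - mean) / sd` with the sample standard deviation (n - 1
#' denominator), the usual input for expression heatmaps. Zero-variance
#' genes become rows of zeros and are recorded in the `constant_genes`
#' attribute.
#'
#' @param norm normalised genes x samples matrix (>= 2 samples).
#' @param gene_ids rows to include (default all).
#' @return Z-score matrix with attribute `constant_genes`.
#' @export
zscore_matrix <- function(norm, gene_ids = rownames(norm)) {
  stopifnot(is.matrix(norm))
  if (ncol(norm) < 2L) stop("need at least 2 samples", call. = FALSE)
  sub <- norm[gene_ids, , drop = FALSE]
  mu <- rowMeans(sub)
  sds <- apply(sub, 1, sd)
  z <- (sub - mu) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  attr(z, "constant_genes") <- gene_ids[sds == 0]
  z
}
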