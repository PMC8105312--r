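# Synthetic tissue-structured RNA-seq count matrices with one planted
# co-expressed gene set, for validating normalisation and co-expression
# screening.

#' Configuration for the expression simulator
#'
#' @param n_genes total number of genes (planted set included).
#' @param tissues named integer vector: tissue label -> replicate count.
#' @param planted_genes character ids of the planted co-expressed set
#'   (non-empty; must number at most `n_genes`).
#' @param planted_profile per-tissue mean expression of the planted set
#'   (named like `tissues`, or unnamed in the same order).
#' @param dispersion negative-binomial dispersion alpha (> 0); count
#'   variance is `mu + alpha * mu^2`.
#' @param size_factor_range range of multiplicative library-size factors,
#'   drawn uniformly per sample.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters for
#'   background gene per-tissue means.
#' @param seed integer seed.
#' @return Validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes, tissues, planted_genes,
                                  planted_profile, dispersion = 0.05,
                                  size_factor_range = c(0.7, 1.4),
                                  baseline_log_mean = log(100),
                                  baseline_log_sd = 1, seed = 1L) {
  .check_number(n_genes, "n_genes", min = 1)
  if (is.null(names(tissues)) || any(tissues < 1))
    stop("'tissues' must be a named vector of replicate counts >= 1",
         call. = FALSE)
  if (length(planted_genes) == 0L)
    stop("planted gene set must be non-empty", call. = FALSE)
  if (length(planted_genes) > n_genes)
    stop("more planted genes than n_genes", call. = FALSE)
  if (is.null(names(planted_profile))) {
    if (length(planted_profile) != length(tissues))
      stop("'planted_profile' must have one mean per tissue", call. = FALSE)
    names(planted_profile) <- names(tissues)
  }
  if (!setequal(names(planted_profile), names(tissues)))
    stop("'planted_profile' names must match tissue labels", call. = FALSE)
  if (any(planted_profile < 0))
    stop("planted profile means must be >= 0", call. = FALSE)
  .check_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0) ||
      size_factor_range[1] > size_factor_range[2])
    stop("'size_factor_range' must be positive c(lo, hi)", call. = FALSE)
  .check_number(seed, "seed")
  structure(list(n_genes = as.integer(n_genes),
                 tissues = setNames(as.integer(tissues), names(tissues)),
                 planted_genes = planted_genes,
                 planted_profile = planted_profile[names(tissues)],
                 dispersion = dispersion,
                 size_factor_range = size_factor_range,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Generate a synthetic count matrix with a planted co-expressed set
#'
#' Draws negative-binomial counts (mean mu, variance `mu + alpha mu^2`)
#' for `n_genes` genes across all tissue replicates. Planted genes share
#' the configured per-tissue profile up to a gene-specific multiplicative
#' scale (which leaves Pearson correlations unchanged); background genes
#' get independent log-normal per-tissue means, so their correlation with
#' the planted profile is random. Each sample's means are multiplied by a
#' library-size factor drawn uniformly from `size_factor_range`.
#'
#' @param config an [expression_sim_config()].
#' @return Integer matrix genes x samples with dimnames; sample columns are
#'   labelled `tissue_rep<k>`. Attributes: `samples` (data frame with
#'   `sample_id`, `tissue`, `replicate`), `size_factors` (true drawn
#'   factors), `planted_genes`.
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  .with_seed(config$seed, {
    tissues <- config$tissues
    sample_tissue <- rep(names(tissues), tissues)
    sample_rep <- unlist(lapply(tissues, seq_len), use.names = FALSE)
    sample_ids <- sprintf("%s_rep%d", sample_tissue, sample_rep)
    n_samp <- length(sample_ids)
    n_bg <- config$n_genes - length(config$planted_genes)
    gene_ids <- c(config$planted_genes,
                  sprintf("bg_g%05d", seq_len(n_bg)))

    # per-gene per-tissue means
    mu_tissue <- matrix(0, config$n_genes, length(tissues),
                        dimnames = list(gene_ids, names(tissues)))
    scale_planted <- rlnorm(length(config$planted_genes), 0, 0.25)
    mu_tissue[seq_along(config$planted_genes), ] <-
      outer(scale_planted, config$planted_profile)
    if (n_bg > 0)
      mu_tissue[length(config$planted_genes) + seq_len(n_bg), ] <-
        matrix(rlnorm(n_bg * length(tissues), config$baseline_log_mean,
                      config$baseline_log_sd),
               n_bg, length(tissues))

    sf <- runif(n_samp, config$size_factor_range[1],
                config$size_factor_range[2])
    mu <- mu_tissue[, sample_tissue, drop = FALSE] *
      rep(sf, each = config$n_genes)
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
      nrow = config$n_genes,
      dimnames = list(gene_ids, sample_ids))
    attr(counts, "samples") <- data.frame(sample_id = sample_ids,
                                          tissue = sample_tissue,
                                          replicate = sample_rep)
    attr(counts, "size_factors") <- setNames(sf, sample_ids)
    attr(counts, "planted_genes") <- config$planted_genes
    counts
  })
}
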