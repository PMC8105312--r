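# Synthetic multi-chromosome gene annotations with planted cluster-density
# hotspots, for validating the sliding-window scan on known ground truth.

#' Configuration for the annotation simulator
#'
#' @param chromosome_lengths numeric vector of chromosome lengths in bp
#'   (named, or auto-named chr1, chr2, ...).
#' @param n_genes genes per chromosome (recycled to the number of
#'   chromosomes).
#' @param background_cluster_rate probability that a gene seeds a cluster
#'   call outside the hotspot (clusters per gene, in \[0, 1\]).
#' @param hotspot `NULL`, or a list with `chrom` (name or index), `start`,
#'   `end` (bp interval within the chromosome) and `rate` (elevated
#'   clusters-per-gene rate inside the interval).
#' @param gene_length fixed gene length in bp.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `annotation_sim_config`.
#' @export
annotation_sim_config <- function(chromosome_lengths, n_genes,
                                  background_cluster_rate = 0.002,
                                  hotspot = NULL, gene_length = 2000,
                                  seed = 1L) {
  if (length(chromosome_lengths) == 0L || any(chromosome_lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  n_genes <- rep_len(as.integer(n_genes), length(chromosome_lengths))
  if (any(n_genes < 1)) stop("need at least one gene per chromosome",
                             call. = FALSE)
  .check_number(background_cluster_rate, "background_cluster_rate",
                min = 0, max = 1)
  .check_number(gene_length, "gene_length", min = 1)
  if (any(n_genes * gene_length > chromosome_lengths))
    stop("genes do not fit on chromosome: reduce n_genes or gene_length",
         call. = FALSE)
  if (!is.null(hotspot)) {
    stopifnot(is.list(hotspot),
              all(c("chrom", "start", "end", "rate") %in% names(hotspot)))
    if (is.numeric(hotspot$chrom))
      hotspot$chrom <- names(chromosome_lengths)[hotspot$chrom]
    if (!hotspot$chrom %in% names(chromosome_lengths))
      stop("hotspot chromosome not in 'chromosome_lengths'", call. = FALSE)
    len <- chromosome_lengths[[hotspot$chrom]]
    if (hotspot$start < 0 || hotspot$end > len || hotspot$start >= hotspot$end)
      stop("hotspot interval outside its chromosome", call. = FALSE)
    .check_number(hotspot$rate, "hotspot rate", min = 0, max = 1)
  }
  .check_number(seed, "seed")
  structure(list(chromosome_lengths = chromosome_lengths, n_genes = n_genes,
                 background_cluster_rate = background_cluster_rate,
                 hotspot = hotspot, gene_length = gene_length,
                 seed = as.integer(seed)),
            class = "annotation_sim_config")
}

#' Generate a synthetic annotation with planted cluster calls
#'
#' Places non-overlapping, sorted genes of fixed length along each
#' chromosome (gene starts from uniformly partitioned intergenic gaps).
#' Each gene then seeds a cluster call with probability equal to the
#' clusters-per-gene rate at its position: the background rate everywhere,
#' or the elevated hotspot rate for genes whose midpoint lies inside the
#' hotspot interval. A cluster call spans its seed gene and the next two
#' genes (three consecutive members); seeds too close to the chromosome end
#' to have two downstream neighbours are skipped. The expected number of
#' cluster calls in a region is therefore rate x (genes in region).
#'
#' @param config an [annotation_sim_config()].
#' @return List with `genes` (data frame: `chrom`, `start`, `end`
#'   0-based half-open, `strand`, `gene_id`) and `clusters` (data frame:
#'   `chrom`, `start`, `end`, `cluster_id`, `cluster_type`,
#'   `member_gene_ids` list column).
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "annotation_sim_config"))
  .with_seed(config$seed, {
    gene_rows <- list()
    cluster_rows <- list()
    for (ci in seq_along(config$chromosome_lengths)) {
      chrom <- names(config$chromosome_lengths)[ci]
      len <- config$chromosome_lengths[[ci]]
      n <- config$n_genes[ci]
      gl <- config$gene_length
      # intergenic gaps: uniform partition of the free space into n+1 gaps
      free <- len - n * gl
      cuts <- sort(runif(n, 0, free))
      starts <- floor(cuts + (seq_len(n) - 1L) * gl)
      ends <- starts + gl
      ids <- sprintf("%s_g%04d", chrom, seq_len(n))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      genes <- data.frame(chrom = chrom, start = starts, end = ends,
                          strand = strand, gene_id = ids)
      gene_rows[[ci]] <- genes

      mid <- (starts + ends) / 2
      rate <- rep(config$background_cluster_rate, n)
      hs <- config$hotspot
      if (!is.null(hs) && hs$chrom == chrom)
        rate[mid >= hs$start & mid < hs$end] <- hs$rate
      seeds <- which(rbinom(n, 1, rate) == 1L)
      seeds <- seeds[seeds + 2L <= n]
      if (length(seeds)) {
        cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
          chrom = chrom,
          start = starts[seeds],
          end = ends[seeds + 2L],
          cluster_id = sprintf("bgc_%s_%04d", chrom, seq_along(seeds)),
          cluster_type = "synthetic",
          member_gene_ids = I(lapply(seeds, function(s) ids[s + 0:2]))
        )
      }
    }
    genes <- do.call(rbind, gene_rows)
    clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 cluster_id = character(), cluster_type = character(),
                 member_gene_ids = I(list()))
    rownames(genes) <- rownames(clusters) <- NULL
    list(genes = genes, clusters = clusters)
  })
}
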