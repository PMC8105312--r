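# Readers and writers for the plain-text formats the pipeline exchanges:
# GFF3 gene annotations, BED-style cluster calls with member genes, TSV
# count matrices, two-column spectrum TSVs, pairwise FASTA, chrom sizes
# and pathway-order tables. Internal coordinates are 0-based half-open;
# GFF3 I/O converts from/to 1-based inclusive, BED is native.

#' Write / read a gene annotation as GFF3
#'
#' @param genes data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`.
#' @param path file path.
#' @return `read_genes_gff3` returns a gene data frame in internal
#'   coordinates.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*"))
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "bgcevol"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = gr$ID)
}

#' Write / read cluster calls as extended BED
#'
#' BED6-style: chrom, start, end (0-based half-open), cluster_id,
#' cluster_type (column 5), strand "."; member gene ids occupy columns 7+
#' (one id per column).
#'
#' @param clusters data frame with `chrom`, `start`, `end`, `cluster_id`,
#'   `cluster_type`, `member_gene_ids` (list column).
#' @param path file path.
#' @export
write_clusters_bed <- function(clusters, path) {
  lines <- vapply(seq_len(nrow(clusters)), function(i) {
    paste(c(clusters$chrom[i],
            format(clusters$start[i], scientific = FALSE, trim = TRUE),
            format(clusters$end[i], scientific = FALSE, trim = TRUE),
            clusters$cluster_id[i], clusters$cluster_type[i], ".",
            clusters$member_gene_ids[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clusters_bed
#' @export
read_clusters_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  bad <- which(vapply(fields, length, integer(1)) < 6L)
  if (length(bad))
    stop("malformed cluster BED line ", bad[1], call. = FALSE)
  data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.numeric(vapply(fields, `[`, character(1), 2)),
    end = as.numeric(vapply(fields, `[`, character(1), 3)),
    cluster_id = vapply(fields, `[`, character(1), 4),
    cluster_type = vapply(fields, `[`, character(1), 5),
    member_gene_ids = I(lapply(fields, function(f)
      if (length(f) >= 7L) f[7:length(f)] else character(0)))
  )
}

#' Write / read a count matrix TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns with
#' `tissue_rep` style headers.
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a k-mer spectrum TSV
#'
#' Two tab-separated columns, occurrence and distinct k-mer count;
#' `#`-prefixed comment lines are allowed and a `# k=<n>` comment records
#' the word length.
#'
#' @param spectrum a [kmer_spectrum()].
#' @param path file path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  k <- attr(spectrum, "k")
  if (!is.na(k)) writeLines(sprintf("# k=%d", k), con)
  writeLines(sprintf("%d\t%s", spectrum$occurrence,
                     format(spectrum$count, scientific = FALSE, trim = TRUE)),
             con)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path)
  k <- NA_integer_
  km <- grep("^#\\s*k=", lines, value = TRUE)
  if (length(km)) k <- as.integer(sub("^#\\s*k=", "", km[1]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  kmer_spectrum(as.numeric(vapply(parts, `[`, character(1), 1)),
                as.numeric(vapply(parts, `[`, character(1), 2)),
                k = k)
}

#' Write / read an aligned codon pair as FASTA
#'
#' Two records, pre-aligned, equal length.
#'
#' @param pair a [codon_pair()].
#' @param path file path.
#' @param names record names.
#' @export
write_pair_fasta <- function(pair, path, names = c("seq_a", "seq_b")) {
  stopifnot(inherits(pair, "codon_pair"))
  x <- Biostrings::DNAStringSet(c(pair$seq_a, pair$seq_b))
  names(x) <- names
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_pair_fasta
#' @param clean apply [clean_alignment()] to the records (default TRUE, so
#'   gapped alignments are accepted).
#' @export
read_pair_fasta <- function(path, clean = TRUE) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) != 2L)
    stop("pair FASTA must contain exactly two records", call. = FALSE)
  a <- as.character(x[[1]]); b <- as.character(x[[2]])
  if (clean) clean_alignment(a, b) else codon_pair(a, b)
}

#' Read a chromosome-sizes TSV (name, length)
#' @param path file path.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read a pathway-order TSV (gene_id, step_rank)
#' @param path file path.
#' @return Named numeric vector of pathway step ranks.
#' @export
read_pathway_order <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), df[[1]])
}
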