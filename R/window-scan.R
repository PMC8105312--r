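# Sliding-window cluster-density scoring and hotspot ranking.
#
# Coordinates are 0-based half-open throughout the package's internal
# representation; the GFF3 reader/writer converts from/to 1-based
# inclusive and BED is native.

.check_features <- function(x, what, chrom_lengths, need_id) {
  req <- c("chrom", "start", "end", need_id)
  if (!is.data.frame(x) || !all(req %in% names(x)))
    stop(sprintf("'%s' must be a data frame with columns %s",
                 what, paste(req, collapse = ", ")), call. = FALSE)
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0) || any(x$end < x$start))
    stop(sprintf("invalid intervals in '%s' (need 0 <= start <= end)", what),
         call. = FALSE)
  bad_chrom <- setdiff(unique(x$chrom), names(chrom_lengths))
  if (length(bad_chrom))
    stop(sprintf("chromosome(s) %s in '%s' missing from chrom_lengths",
                 paste(bad_chrom, collapse = ", "), what), call. = FALSE)
  beyond <- x$end > chrom_lengths[x$chrom]
  if (any(beyond))
    stop(sprintf("feature '%s' extends beyond its chromosome",
                 x[[need_id]][which(beyond)[1]]), call. = FALSE)
  invisible(x)
}

#' Sliding-window cluster-density scan
#'
#' Scores biosynthetic-cluster density along each chromosome in large
#' sliding windows: the score of a window is the number of cluster calls
#' whose midpoint falls in the window divided by the number of genes whose
#' midpoint falls in the window (clusters per gene, i.e. cluster density
#' normalised by gene density). Windows start at 0 and advance by `slide`
#' while the start is inside the chromosome; the last windows are truncated
#' at the chromosome end. A feature belongs to a window iff its midpoint
#' lies in `[window_start, window_end)`.
#'
#' @param genes data frame of gene records: columns `chrom`, `start`, `end`
#'   (0-based half-open bp), `gene_id`.
#' @param clusters data frame of cluster calls: columns `chrom`, `start`,
#'   `end`, `cluster_id` (and optionally `cluster_type`,
#'   `member_gene_ids`).
#' @param window window size in bp (default 100 Mb).
#' @param slide slide size in bp (default 10 Mb); must satisfy
#'   `window >= slide > 0`.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @return Data frame of class `window_scores` with columns `chrom`,
#'   `window_start`, `window_end`, `n_clusters`, `n_genes`, `score`
#'   (NA when `n_genes == 0`), `defined`.
#' @export
window_scan <- function(genes, clusters, window = 1e8, slide = 1e7,
                        chrom_lengths) {
  .check_number(window, "window", min = 0, strict_min = TRUE)
  .check_number(slide, "slide", min = 0, strict_min = TRUE)
  if (window < slide) stop("'window' must be >= 'slide'", call. = FALSE)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("'chrom_lengths' must be a named vector of positive lengths",
         call. = FALSE)
  .check_features(genes, "genes", chrom_lengths, "gene_id")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in 'genes'", call. = FALSE)
  .check_features(clusters, "clusters", chrom_lengths, "cluster_id")

  one_chrom <- function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(0, len - 1e-9, by = slide)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    gm <- sort((genes$start + genes$end)[genes$chrom == chrom] / 2)
    cm <- sort((clusters$start + clusters$end)[clusters$chrom == chrom] / 2)
    # midpoints are multiples of 0.5, so shifting the boundary down by 0.25
    # turns "strictly below" into a findInterval query
    count_in <- function(m, lo, hi) {
      if (length(m) == 0L) return(integer(length(lo)))
      findInterval(hi - 0.25, m) - findInterval(lo - 0.25, m)
    }
    ng <- count_in(gm, starts, ends)
    nc <- count_in(cm, starts, ends)
    data.frame(chrom = chrom, window_start = starts, window_end = ends,
               n_clusters = nc, n_genes = ng,
               score = ifelse(ng > 0, nc / ng, NA_real_),
               defined = ng > 0)
  }
  out <- do.call(rbind, lapply(names(chrom_lengths), one_chrom))
  rownames(out) <- NULL
  class(out) <- c("window_scores", "data.frame")
  out
}

#' Rank cluster-density hotspot windows
#'
#' Orders the windows of a [window_scan()] by decreasing density score.
#' Windows with undefined scores (no genes) are excluded. Ties are broken
#' deterministically: higher cluster count first, then chromosome name,
#' then window start.
#'
#' @param scores a [window_scan()] result.
#' @param top_n number of top windows to return (default all).
#' @return The ranked windows with an added `rank` column.
#' @export
rank_hotspots <- function(scores, top_n = Inf) {
  stopifnot(is.data.frame(scores),
            all(c("chrom", "window_start", "score") %in% names(scores)))
  ok <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("all windows have undefined scores (no genes anywhere)",
         call. = FALSE)
  ord <- order(-ok$score, -ok$n_clusters, ok$chrom, ok$window_start)
  ok <- ok[ord, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  rownames(ok) <- NULL
  head(ok, n = if (is.finite(top_n)) top_n else nrow(ok))
}

#' Count clusters with co-expressed member genes
#'
#' Applies the co-expression filter used to triage predicted clusters: a
#' cluster is flagged when at least `min_genes` of its member genes
#' (the bait included, whose self-correlation is 1) have Pearson r against
#' the cluster bait strictly greater than `r_threshold`.
#'
#' @param clusters data frame with `cluster_id` and `member_gene_ids`
#'   (list column of character vectors, or comma-separated strings).
#' @param coexpr named list of [bait_correlation()] results, one per
#'   `cluster_id`.
#' @param r_threshold correlation threshold (strict; default 0.85).
#' @param min_genes minimum number of passing member genes (default 3).
#' @return List with `clusters` (data frame: `cluster_id`, `bait_id`,
#'   `n_pass`, `flagged`) and `n_flagged`.
#' @export
coexpressed_cluster_count <- function(clusters, coexpr, r_threshold = 0.85,
                                      min_genes = 3L) {
  stopifnot(is.data.frame(clusters),
            all(c("cluster_id", "member_gene_ids") %in% names(clusters)))
  missing_res <- setdiff(clusters$cluster_id, names(coexpr))
  if (length(missing_res))
    stop("no co-expression result for cluster(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cid <- clusters$cluster_id[i]
    members <- clusters$member_gene_ids[[i]]
    if (length(members) == 1L && grepl(",", members))
      members <- strsplit(members, ",")[[1]]
    res <- coexpr[[cid]]
    stopifnot(inherits(res, "coexpression_result"))
    r <- res$r[intersect(members, names(res$r))]
    n_pass <- sum(r > r_threshold, na.rm = TRUE)
    data.frame(cluster_id = cid, bait_id = res$bait_id,
               n_pass = n_pass, flagged = n_pass >= min_genes)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(clusters = tab, n_flagged = sum(tab$flagged))
}
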