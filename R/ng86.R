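# Aligned codon pairs and Nei-Gojobori (1986) counting of synonymous and
# nonsynonymous sites and differences, with Jukes-Cantor correction.

#' Aligned codon pair
#'
#' Container for two pre-aligned coding sequences. Sequences must be equal
#' length, a multiple of 3, contain only A/C/G/T, and contain no stop codon;
#' use [clean_alignment()] to get there from a raw alignment.
#'
#' @param seq_a,seq_b aligned nucleotide strings.
#' @return Object of class `codon_pair`: list with `seq_a`, `seq_b`,
#'   `n_codons`.
#' @export
codon_pair <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L)
    stop("sequences must be single character strings", call. = FALSE)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(seq_a) == 0L || nchar(seq_a) %% 3L != 0L)
    stop("alignment length must be a positive multiple of 3", call. = FALSE)
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stop("sequences contain non-ACGT characters; use clean_alignment()",
         call. = FALSE)
  gc <- Biostrings::GENETIC_CODE
  for (s in list(seq_a, seq_b)) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (any(gc[cod] == "*"))
      stop("sequence contains a stop codon; use clean_alignment()",
           call. = FALSE)
  }
  structure(list(seq_a = seq_a, seq_b = seq_b, n_codons = nchar(seq_a) %/% 3L),
            class = "codon_pair")
}

#' @export
print.codon_pair <- function(x, ...) {
  cat(sprintf("Aligned codon pair: %d codons (%d nt)\n",
              x$n_codons, 3L * x$n_codons))
  invisible(x)
}

#' Clean an aligned sequence pair into a valid codon pair
#'
#' Drops every codon column in which either sequence has a gap, an
#' ambiguity code (anything outside A/C/G/T; U is first converted to T),
#' or a stop codon, mirroring the usual "complete deletion" treatment of
#' pairwise codon alignments.
#'
#' @param seq_a,seq_b equal-length aligned nucleotide strings, length a
#'   multiple of 3.
#' @return A [codon_pair()]; the number of removed codon columns is
#'   attached as attribute `n_removed`.
#' @export
#' @examples
#' clean_alignment("ATG---AAA", "ATGCCCAAA")$n_codons  # 2
clean_alignment <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L)
    stop("sequences must be single character strings", call. = FALSE)
  seq_a <- chartr("U", "T", toupper(seq_a))
  seq_b <- chartr("U", "T", toupper(seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length must be a multiple of 3", call. = FALSE)
  idx <- seq(1, nchar(seq_a), 3)
  ca <- substring(seq_a, idx, idx + 2); cb <- substring(seq_b, idx, idx + 2)
  gc <- Biostrings::GENETIC_CODE
  ok_codon <- function(x) {
    clean <- !grepl("[^ACGT]", x)
    stopc <- clean & !is.na(gc[x]) & gc[x] == "*"
    clean & !stopc
  }
  keep <- ok_codon(ca) & ok_codon(cb)
  if (!any(keep))
    stop("no codon columns remain after cleaning", call. = FALSE)
  out <- codon_pair(paste(ca[keep], collapse = ""),
                    paste(cb[keep], collapse = ""))
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Per-codon synonymous site count: for each of the 9 single-nucleotide
# neighbours (3 per position), the fraction that are synonymous. Following
# the classic convention the denominator stays 3 per position and changes
# to stop codons count as nonsynonymous, so S + N = 3 per codon.
.syn_sites <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env$syn_sites)
  tab <- .codon_table()
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  s <- vapply(tab$codons, function(cod) {
    chars <- strsplit(cod, "")[[1]]
    syn <- 0
    for (pos in 1:3) for (nt in setdiff(nts, chars[pos])) {
      mut <- chars; mut[pos] <- nt
      mutc <- paste(mut, collapse = "")
      if (gc[[mutc]] != "*" && gc[[mutc]] == gc[[cod]]) syn <- syn + 1 / 3
    }
    syn
  }, numeric(1))
  .codon_env$syn_sites <- s
  s
}

# All minimal substitution pathways between two codons (2 or 3 differing
# positions -> 2 or 6 orderings). Pathways through a stop codon are
# excluded; if every pathway is blocked, all are used. Returns the average
# numbers of synonymous and nonsynonymous steps.
.codon_differences <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  eval_path <- function(ord) {
    cur <- a; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (gc[[c2]] == "*") return(NULL)
      if (gc[[c1]] == gc[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, eval_path)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    # every minimal pathway crosses a stop; fall back to counting through
    eval_all <- function(ord) {
      cur <- a; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (gc[[c1]] == gc[[c2]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- lapply(perms, eval_all)
  }
  colMeans(do.call(rbind, res))
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Counts expected synonymous (S) and nonsynonymous (N) sites per sequence
#' from the single-nucleotide mutational neighbours of each codon (averaged
#' over the two sequences), counts observed synonymous (Sd) and
#' nonsynonymous (Nd) differences with equal weighting over minimal
#' substitution pathways (pathways through stop codons excluded), and
#' applies the Jukes-Cantor correction `d = -(3/4) log(1 - (4/3) p)` to the
#' proportions `pS = Sd/S` and `pN = Nd/N`.
#'
#' @param pair a [codon_pair()].
#' @return Object of class `pairwise_rates`: list with `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega` (dN/dS; `NA` when dS = 0),
#'   `saturated` (TRUE when a proportion reached 3/4 and the corrected
#'   distance is `Inf`), `n_codons`.
#' @export
#' @examples
#' r <- ng86(codon_pair("TTT", "GTT"))
#' r$pN          # 3/7
#' round(r$dN, 3)  # 0.635
ng86 <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  idx <- seq(1, nchar(pair$seq_a), 3)
  ca <- substring(pair$seq_a, idx, idx + 2)
  cb <- substring(pair$seq_b, idx, idx + 2)
  ss <- .syn_sites()
  S <- (sum(ss[ca]) + sum(ss[cb])) / 2
  N <- 3 * pair$n_codons - S
  diffs <- mapply(.codon_differences, ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(Inf)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (dS == 0 || is.infinite(dS)) {
    if (is.infinite(dS) && is.finite(dN)) 0 else NA_real_
  } else dN / dS
  structure(list(
    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = dS, dN = dN, omega = omega,
    saturated = is.infinite(dS) || is.infinite(dN),
    n_codons = pair$n_codons
  ), class = "pairwise_rates")
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf(
    "NG86 rates (%d codons): S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n",
    x$n_codons, x$S_sites, x$N_sites, x$Sd, x$Nd))
  cat(sprintf("  dS = %.4g, dN = %.4g, dN/dS = %s%s\n", x$dS, x$dN,
              if (is.na(x$omega)) "undefined" else sprintf("%.4g", x$omega),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}
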