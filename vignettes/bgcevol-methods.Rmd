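---
title: "Methods: cluster hotspots, co-expression, genome size and codon evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster hotspots, co-expression, genome size and codon evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcevol)
```

# Scope and model

Plant biosynthetic gene clusters (BGCs) — physically co-located,
non-homologous genes that jointly encode a metabolic pathway, such as the
12-gene avenacin cluster of diploid oat — raise a recurring set of
quantitative questions: whether clusters concentrate in particular genomic
regions, whether a predicted cluster's member genes are co-expressed,
how large the host genome is, how fast the cluster genes evolve relative
to neutrality, and whether gene order tracks pathway order. `bgcevol`
implements one standard answer to each, plus simulators that generate
inputs with known ground truth so every stage can be validated without
external genome data.

# Genome size

## k-mer spectrum estimator

Given the occurrence histogram of a deep whole-genome read set, the
haploid genome size is

$$ G_s = \frac{K_n - K_u}{D_p}, $$

where $K_n$ is the total number of k-mer word instances
($\sum_{o} o \cdot \mathrm{hist}[o]$), $K_u$ the instances at occurrence 1
(overwhelmingly sequencing errors), and $D_p$ the depth of the coverage
peak. `kmer_totals()` and `estimate_genome_size_kmer()` implement exactly
this arithmetic; only occurrence-1 words are subtracted, so doubleton
errors remain in the numerator — this matches the printed worked example
the estimator is tested against (3.86 Gb from
$K_n = 1.242\times 10^{11}$, $K_u = 1.226\times 10^{10}$, $D_p = 29$).

**Peak detection.** `detect_peak()` separates the error peak from the
coverage peak at the first strict local minimum of the densified histogram
above occurrence 1 (plateau minima resolve to their lowest occurrence);
a histogram that rises from occurrence 1 has no error peak and is searched
from occurrence 1; a monotonically decreasing histogram has no detectable
coverage peak and is an error, with an explicit `min_occurrence` as the
escape hatch. The returned depth is the rounded intensity-weighted
centroid of the contiguous bins within half-maximum of the raw argmax
rather than the argmax itself. This matters more than it looks: a Poisson
depth distribution with integer mean $c$ has *exactly* tied modes at
$c-1$ and $c$, so a raw argmax flips between them on sampling noise and
propagates a $1/D_p$-sized relative error (4% at $25\times$) into the
estimate. The centroid restores the peak centre; on the simulated 2 Mb /
$25\times$ round trip the estimate is within 0.1% of truth.

## Flow cytometry

`flow_cytometry_size()` converts G1 fluorescence peak means to a 2C DNA
amount via the ratio to an internal standard (default: the maize
reference, 2C = 5.43 pg) and to base pairs with
1 pg = $0.978\times10^9$ bp, halving for the 1C value. The function is
arithmetic only; measurement replication and averaging are the caller's
concern.

# Cluster-density hotspots

`window_scan()` scores clusters-per-gene in sliding windows (defaults:
100 Mb window, 10 Mb slide — the scale appropriate to multi-Gb cereal
genomes; tests and simulations use proportionally smaller windows on Mb
toy genomes). Design choices:

* **Midpoint assignment.** A feature belongs to a window iff its midpoint
  lies in `[window_start, window_end)`. Midpoint assignment makes every
  disjoint tiling a partition (window = slide implies the per-window
  counts sum to the totals) and each feature count toward exactly
  `window/slide` overlapping windows; overlap-based assignment has
  neither property.
* **Coordinates.** Internally 0-based half-open; GFF3 I/O converts from
  1-based inclusive, BED is native. Window arithmetic is then exact.
* **Truncated terminal windows** are kept: terminal regions are exactly
  where subtelomeric cluster hotspots live, and the per-gene
  normalisation absorbs their smaller gene counts. Windows with zero
  genes have an undefined score and are excluded from ranking.
* **Denominator.** All supplied genes count; restricting to
  high-confidence genes is the caller's filtering decision.

`rank_hotspots()` sorts by score with deterministic tie-breaks (cluster
count, chromosome, start). The scan is validated against an exhaustive
feature-by-window membership oracle on random toy genomes, and by
planted-hotspot recovery: with 1000 genes on a 10 Mb chromosome, a
background rate of 0.002 clusters/gene and a 1 Mb hotspot at 0.05, the
planted window ranks first in ≥ 9/10 simulations.

# Co-expression screening

`size_factors()` reimplements the median-of-ratios estimator: sample
$j$'s factor is the median over genes of
$c_{ij} / (\prod_k c_{ik})^{1/m}$, genes with any zero count excluded.
The median is taken on the ratio scale (the literal formula); DESeq2
takes it on the log scale, which differs only when the median averages
two middle ratios — the two agree exactly at odd eligible-gene counts,
which is how the cross-check against DESeq2 is posed. One subtlety the
test suite documents: scaling one sample by $c$ rescales *all* factors by
$c^{-1/m}$ (the geometric-mean reference moves), with the scaled sample
additionally by $c$; only factor ratios are equivariant.

`bait_correlation()` computes Pearson r of every gene against a bait
across samples. Correlations are computed on normalised counts without a
log transform, replicates kept as separate samples (12 samples for 6
tissues × 2 replicates); a cluster passes the screen when at least 3
member genes (bait included) have r *strictly* greater than 0.85
(`coexpressed_cluster_count()`). The default bait
(`select_bait()`) is the member with the highest mean normalised
expression, ties to the lexicographically smallest id — a deterministic
stand-in for the analyst's "representative gene". `zscore_matrix()`
standardises per gene with the $n-1$ standard deviation, the common
heatmap convention; constant genes become zero rows and are flagged
rather than NaN.

# Codon evolution

## NG86 counting

`ng86()` counts expected synonymous sites per codon as the synonymous
fraction of the nine single-nucleotide neighbours (denominator fixed at 3
per position; changes to stop codons count as nonsynonymous, so
$S + N = 3 \times$ codons), averages sites over the two sequences, counts
differences with equal weight over minimal substitution pathways
(pathways through stops excluded; if all are blocked the count falls back
to all pathways), and applies the Jukes–Cantor correction
$d = -\tfrac34 \log(1 - \tfrac43 p)$. Proportions at or beyond $3/4$
saturate to `Inf` with a flag instead of erroring, so batch runs
complete. The single-difference hand example (TTT vs GTT:
$\bar S = 2/3$, $\bar N = 7/3$, $p_N = 3/7$, $d_N \approx 0.635$) is
frozen in the tests.

NG86 ignores the transition/transversion bias when counting sites, which
deflates $\hat\omega$ when $\kappa > 1$: a 50-replicate simulation oracle
at $t = 0.2$, $\kappa = 2$, true $\omega = 0.5$ centred the NG86
estimate at 0.41, and the recovery test uses the band $[0.30, 0.52]$
registered from that run. The likelihood route below does not share this
bias.

## GY94 maximum likelihood and the LRT

`gy94_rate_matrix()` builds the 61-sense-codon Goldman–Yang generator:
single-nucleotide changes at rate $\pi_j \kappa^{\mathrm{ts}}
\omega^{\mathrm{nonsyn}}$, scaled so branch length is expected
substitutions per codon. The chain is reversible, so transition
probabilities are computed by symmetric eigendecomposition of
$\Pi^{1/2} Q \Pi^{-1/2}$ — fast enough to sit inside an optimiser — and
checked in the tests against an independent scaling-and-squaring matrix
exponential (`Matrix::expm`) to $10^{-6}$ and better.

`gy94_fit()` maximises the pairwise likelihood
$\ell = \sum_{\text{sites}} \log \pi_a P_{ab}(t)$ (reversibility makes
the rooting irrelevant and the fit symmetric in the two sequences) over
$(t, \kappa, \omega)$, or $(t, \kappa)$ with $\omega$ fixed.
Numerical choices: site patterns are collapsed to a 61×61 count matrix;
the search is log-parameterised with bounds $t \in [10^{-6}, 50]$,
$\kappa \in [10^{-2}, 10^2]$, $\omega \in [10^{-4}, 20]$; L-BFGS-B from
three starting points ($\omega_0 \in \{0.3, 1, 3\}$, $t_0$ from the raw
codon mismatch fraction); best log-likelihood wins, ties to the smaller
$t$. Codon frequencies default to F3x4 estimated from the pooled pair,
with `"equal"` available for simulations.

`lrt()` forms $2(\ell_{\text{free}} - \ell_{\omega=1})$, clamps tiny
negative noise to zero, errors if the free model is genuinely dominated
(an optimiser-failure signal, since the models are nested), and refers
the statistic to $\chi^2_1$. $\omega = 1$ is interior to the parameter
space, so the plain $\chi^2_1$ calibration applies — no boundary
mixture. Calibration is verified by simulation: under $\omega = 1$
(300-codon pairs, 200 replicates) the measured rejection rate at
$p < 0.05$ falls within 3 binomial SDs of 0.05.

## Divergence dating

`divergence_time()` is the standard molecular-clock reading
$T = \bar{K_s} / (2r)$ with a default grass synonymous rate of
$6.5\times10^{-9}$ substitutions/site/year; the factor 2 accounts for
both lineages. $\bar{K_s} = 0.3705$ gives 28.5 My. Note the package's
$K_s$ comes from NG86 counting (or the GY94 fit), not from the
model-averaged estimators of the KaKs_Calculator family; absolute
$K_s$ values can differ from model-averaged ones by a few percent, which
propagates linearly into dates.

# Colinearity statistic

Statements that a cluster's gene order is "loosely colinear" with its
pathway order are made testable by `colinearity()`: Kendall's tau-b
between distance-from-telomere and pathway step rank, with a two-sided
permutation p-value $(1 + \#\{|\tau_{\text{perm}}| \ge |\tau|\})/(1 +
n_{\text{perm}})$. tau-b (tie-corrected) is preferred over Spearman
because pathway orderings are short (a dozen genes) and may contain tied
parallel steps. The permutation p is validated against full $5!$
enumeration on 5-gene inputs. This statistic is this package's own
construction, and reports should present it as such.

# Synthetic data: what it does and does not emulate

The generators define the package's study conditions:

* `gen_annotation()` — non-overlapping fixed-length genes placed by a
  uniform partition of intergenic space; each gene seeds a 3-gene cluster
  call with probability equal to the local clusters-per-gene rate
  (background 0.002; hotspot 0.05 over 1 Mb in the recovery
  configuration), so expected cluster counts per region are exactly
  rate × genes.
* `gen_expression()` — negative-binomial counts, variance
  $\mu + \alpha\mu^2$ (the parameterisation RNA-seq normalisation
  assumes), six tissues × two replicates, a planted 8-gene set sharing a
  root-tip-high profile up to a gene-specific scale (which preserves
  Pearson r), background genes with independent log-normal profiles,
  uniform library-size factors in [0.7, 1.4]. Dispersion and library
  sizes are chosen for testability — published RNA-seq characteristics
  for this design are not available — with $\alpha = 0.05$ as the
  default and $\alpha = 0.02$ in the recovery runs ("low dispersion").
* `gen_kmer_spectrum()` — the spectrum is simulated directly as a
  histogram (Poisson depth per distinct k-mer; a repeat fraction at
  doubled depth; error words injected at occurrence 1–2), because the
  estimator consumes only the histogram. No read-level error model.
* `simulate_codon_pair()` — ancestor from $\pi$, descendant by exact
  matrix-exponential sampling per site; stop codons excluded from the
  state space, so outputs satisfy the codon-pair invariants by
  construction.

All generators restore the caller's RNG state and are byte-deterministic
given their seed. Passing tests on these inputs show the *algorithms* are
correct under their stated models; they do not show that real annotations
have Bernoulli cluster placement, that real counts are NB with a single
dispersion, or that real coding sequences evolved under a homogeneous
GY94 process.

# Problem sizes and limitations

The validation suite runs at desk scale by design: toy genomes of a few
Mb for the scan oracle, 200-gene count matrices, 300–500-codon pairs,
50-replicate recovery and 200-replicate calibration experiments. The
published genome-scale quantities that require the actual assembly and
plantiSMASH runs (total cluster counts, the terminal-region census,
assembly quality metrics, per-species mean-Ks tables) are out of reach of
any reimplementation without those inputs; the package instead validates
each procedure against oracles and planted truth, and exposes the same
procedures for users who have real inputs in the supported formats.

Known limitations: no heterozygosity/repeat mixture modelling in the
genome-size module (GenomeScope-style fitting is out of scope); pairwise
(not site or branch) codon models only; no alignment construction —
codon pairs must arrive aligned, and `clean_alignment()` only drops
unusable columns; the co-expression module deliberately stops at size
factors and correlations (no dispersion estimation or differential
expression).
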