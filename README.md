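# bgcevol

Quantitative tools for studying the genomic organisation and evolution of
plant biosynthetic gene clusters (BGCs) — the physically co-located,
non-homologous genes that jointly encode metabolic pathways such as the
avenacin defence-compound cluster of oat. The package is aimed at plant
comparative genomicists who have a genome annotation, cluster predictions
(e.g. from plantiSMASH), RNA-seq counts and coding-sequence alignments,
and want the standard downstream statistics reproducibly and testably.

It implements five analyses plus the simulators to validate them:

| Analysis | Core quantity | Functions |
|---|---|---|
| Genome size | `Gs = (Kn − Ku)/Dp` from a k-mer spectrum; 2C pg → bp (1 pg = 0.978×10⁹ bp) | `estimate_genome_size_kmer()`, `detect_peak()`, `flow_cytometry_size()` |
| Cluster hotspots | clusters-per-gene in sliding windows (default 100 Mb window, 10 Mb slide) | `window_scan()`, `rank_hotspots()` |
| Co-expression | median-of-ratios size factors; bait-gene Pearson r; "≥ 3 genes with r > 0.85" cluster filter; Z-scores | `size_factors()`, `bait_correlation()`, `coexpressed_cluster_count()`, `zscore_matrix()` |
| Codon evolution | NG86 dN/dS with Jukes–Cantor correction; GY94 maximum-likelihood ω; LRT of ω = 1 on χ²(1); `T = Ks/(2r)` dating | `ng86()`, `gy94_fit()`, `lrt()`, `divergence_time()` |
| Colinearity | Kendall tau-b between gene order and pathway order, permutation p | `colinearity()` |

Synthetic-data generators (`gen_annotation()`, `gen_expression()`,
`gen_kmer_spectrum()`, `simulate_codon_pair()`) produce inputs with
planted ground truth, and `run_pipeline()` ties the stages together from
a declarative config with a reproducibility manifest. See the methods
vignette (`vignettes/bgcevol-methods.Rmd`) for the models, parameter
choices and limitations.

## Worked example

```r
library(bgcevol)

## Genome size from k-mer spectrum totals (a deep shotgun run summarised
## by its histogram): Kn = 1.242e11 total words, Ku = 1.226e10 unique
## words, coverage peak at depth 29
sp  <- kmer_spectrum(c(1, 29), c(12260521110, (124199810495 - 12260521110) / 29))
estimate_genome_size_kmer(sp, peak_override = 29)
#> Genome size estimate (kmer): 3.86 Gb (3859975496 bp)
#>   peak depth Dp = 29

## ... and from flow cytometry against the 5.43 pg maize standard
flow_cytometry_size(8.486, 5.43)
#> Genome size estimate (flow_cytometry): 4.15 Gb (4149654000 bp)
#>   2C = 8.486 pg

## Hotspot scan on a simulated annotation with a planted hotspot
ann <- gen_annotation(annotation_sim_config(
  chromosome_lengths = c(chr1 = 1e7), n_genes = 1000,
  background_cluster_rate = 0.002,
  hotspot = list(chrom = "chr1", start = 2e6, end = 3e6, rate = 0.05),
  seed = 7))
sc <- window_scan(ann$genes, ann$clusters, window = 1e6, slide = 5e5,
                  chrom_lengths = c(chr1 = 1e7))
head(rank_hotspots(sc), 3)[, c("window_start", "window_end", "n_clusters", "n_genes", "score")]
#>   window_start window_end n_clusters n_genes      score
#> 1      2000000    3000000          7      93 0.07526882
#> 2      1500000    2500000          6      96 0.06250000
#> 3      2500000    3500000          2      92 0.02173913

## Pairwise dN/dS with the likelihood-ratio test of omega = 1
pair  <- simulate_codon_pair(t = 0.3, kappa = 2, omega = 0.2,
                             n_codons = 500, seed = 1)
free  <- gy94_fit(pair, freqs = "equal")
fixed <- gy94_fit(pair, fix_omega = 1, freqs = "equal")
free$omega_hat
#> [1] 0.2105916
lrt(free, fixed)
#> LRT of dN/dS = 1: 2*dlogL = 73.9580, df = 1, p = 7.98e-18 (significant at 0.05)

## Mean synonymous divergence to time (grass clock, 6.5e-9 /site/year)
divergence_time(0.3705)$time_mya
#> [1] 28.5
```

The hotspot table reads: the top-ranked 1 Mb window spans exactly the
planted 2–3 Mb hotspot, with ~0.075 clusters per gene against a 0.002
background (the planted rate is 0.05; window counts fluctuate). The LRT p-value rejects neutral evolution for the simulated
pair, whose fitted ω ≈ 0.21 recovers the true 0.2.

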