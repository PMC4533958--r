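# smallRNAtlas

Profiling of small non-coding RNA populations from aligned small RNA-seq
reads, built for tissues in which miRNAs (~22 nt), piRNAs (24–31 nt, with a
strong 5′-uridine bias) and tRNA-derived small RNAs (tRFs ~20 nt, tRNA
halves ~33 nt) coexist — the archetype being normal testis versus
testicular germ cell tumor (TGCT), where the piRNA population is globally
lost while the miR-302/367 and miR-371-373 miRNA clusters are strongly
upregulated. The intended users are bioinformaticians analysing small
RNA-seq count data who need the complete downstream path in one tested,
scriptable package.

## What it does

* **Signatures** — read-length histograms (18–36 nt), per-length fractions
  of unique sequences with 5′U, 5′G and position-10 A, and positional
  base-frequency matrices with information content IC = 2 − H (bits), as
  used for sequence logos.
* **Small RNA contigs** — strand-specific merging of 24–36 nt read
  alignments into contigs (piRNA-precursor proxies), joining same-strand
  reads with gaps ≤ 100 bp and discarding contigs supported by fewer than
  100 alignment records; interval intersection and bidirectional overlap
  reports against a piRNA reference.
* **Classification** — precedence-based assignment of each alignment to
  miRNA / tRNA / piRNA cluster / repeat / exon / unannotated, per length
  window (18–24 / 25–31 / 32–36 nt), plus typing of tRNA-derived reads as
  tRFs or tRNA halves with their 5′/3′ end of origin.
* **Differential expression** — a from-scratch negative-binomial engine:
  median-of-ratios size factors
  `s_j = median_i k_ij / (prod_v k_iv)^(1/m)`; pooled method-of-moments
  dispersions with **maximum sharing** over a fitted mean–dispersion trend
  (parametric `a0 + a1/q`, or a local running-median trend for large contig
  sets); the exact conditioned NB test
  `p = Σ_{P(a,b) ≤ P(kA,kB)} P(a,b) / Σ P(a,b)` over all splits
  `a + b = kA + kB`; fold changes with `Inf`/`-Inf` conventions;
  Benjamini–Hochberg adjustment; and a variance-stabilizing transformation
  with the closed form
  `vst(q) = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q)))/(4 a0))`.
* **Reporting** — top-N expressed features, Euclidean complete-linkage
  sample clustering on VST data with newick export, volcano and heatmap
  tables (flags default to adjusted p < 1e-8 and |log2FC| > 5).
* **qPCR** — ΔΔCT relative quantification (`RQ = 2^-ΔΔCT`) with triplicate
  averaging, endogenous control, a calibrator sample (RQ = 1) and a
  CT > 35 negativity cutoff.
* **Synthetic data** — a generator emulating the study's read populations
  (length modes 22/30/33 nt, 70 % 5′U and elevated 10A in the normal piRNA
  population, 5′G at 32–34 nt, ~90 % tRNA origin of long reads, global
  piRNA loss at log2FC −5, 23 up-miRNAs at +11) with a ground-truth table
  for parameter-recovery testing, and `run_pipeline()`, which chains every
  stage into one reproducible, manifested run
  (`inst/scripts/run_pipeline.R` is a thin command-line wrapper).

## Worked example

A scaled-down experiment — 6 normal vs 5 tumor samples, 30,000 expected
reads per sample — simulated, profiled and tested end to end:

```r
library(smallRNAtlas)

spec   <- genome_spec(chrom_length = 3e5L, n_mirna_loci = 60L,
                      n_pirna_clusters = 30L, n_trna_genes = 120L,
                      n_repeat_elements = 40L, n_exons = 60L, seed = 1)
design <- default_design(n_normal = 6, n_tumor = 5)
params <- list(normal = normal_params(depth = 3e4),
               tumor  = tumor_params(depth = 3e4))
ex <- simulate_experiment(design, params, seed = 1, spec = spec)

signature_fractions(ex$samples$N01, lengths = c(24, 27, 30, 33))
#>   length n_unique frac_5prime_u frac_5prime_g frac_10a
#> 1     24      197          0.67         0.091     0.37
#> 2     27      779          0.72         0.110     0.32
#> 3     30     3149          0.72         0.097     0.34
#> 4     33      360          0.15         0.597     0.25
```

The normal-sample piRNA range (24–30 nt) sits at ~70 % 5′U with a mildly
elevated 10A, collapsing at 33 nt where 5′G-biased tRNA halves take over.

```r
contigs <- build_contigs(ex$samples, contig_params(min_support = 50))
contig_summary(contigs)
#>   n_contigs mean_length median_length
#> 1       246    432.7683           300

cmat <- count_reads(contigs, lapply(ex$samples,
                    function(g) g[width(g) >= 24 & width(g) <= 36]))
cond <- factor(ex$design$condition, levels = c("control", "case"))
de   <- nbinom_de(cmat, cond, fit_type = "local")
head(filter_significant(de, 1e-6)[, c("id", "baseMean", "log2FoldChange", "padj")], 3)
#>                id baseMean log2FoldChange     padj
#> 50  contig_000050    135.0          -5.03 7.68e-85
#> 89  contig_000089     81.7          -4.87 2.22e-80
#> 73  contig_000073     79.0          -4.91 2.29e-76
```

Seventy contigs are significant at adjusted p < 1e-6, all down in the tumor
group, mean log2FC −4.54 — the injected global piRNA loss of −5 recovered
through contig construction, counting, normalization and the exact test.
miRNA analysis (parametric fit) finds the injected up-set, including
transcripts absent from normals reported with an infinite fold change:

```r
dem <- nbinom_de(count_reads(ex$genome$tracks$mirna, ex$samples), cond,
                 fit_type = "parametric")
head(filter_significant(dem, 1e-6)[, c("id", "baseMean", "log2FoldChange", "padj")], 3)
#>            id baseMean log2FoldChange     padj
#> 18 mirna_0018      221            Inf 3.81e-70
#> 2  mirna_0002      203            Inf 1.24e-64
#> 5  mirna_0005      196           11.4 8.21e-61

v  <- vst(cmat, attr(de, "dispersion_model"), attr(de, "size_factors"))
hc <- cluster_samples(v, top_n_features(v, min(2000, nrow(v))))
cluster_purity(hc, setNames(ex$design$group, ex$design$sample_id))
#> [1] 1
```

Cutting the complete-linkage dendrogram into two clusters separates normal
from tumor samples perfectly. The whole pipeline, with every intermediate
written as plain text plus a checksummed manifest, is one call:

```r
run_pipeline(default_run_config(outdir = "run1", seed = 1))
```

See `vignettes/smallrna-populations.Rmd` for the model, parameter meanings
and design notes.

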