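---
title: "Profiling small RNA populations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small RNA populations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallRNAtlas)
```

# Scope

`smallRNAtlas` analyses aligned small RNA-seq reads (18-36 nt) from tissues
in which three small RNA populations coexist: miRNAs (peak ~22 nt), piRNAs
(24-31 nt, cluster- and repeat-derived, with a strong 5' uridine bias) and
tRNA-derived small RNAs (tRFs ~20 nt and tRNA halves ~33 nt, cut
predominantly from the 5' end of mature tRNAs). The motivating application
is the comparison of normal testis with testicular germ cell tumor (TGCT)
tissue, where the piRNA population collapses globally while a small set of
stemness miRNAs (the miR-302/367 and miR-371-373 families) is strongly
upregulated.

The package covers the full downstream path: length/base-composition
signatures, strand-specific merging of alignments into *small RNA contigs*
(a proxy for piRNA precursor transcripts), annotation-based classification
with tRNA-fragment typing, a from-scratch negative-binomial exact test with
median-of-ratios normalization and shared dispersions, clustering and
volcano/heatmap table export, and 2^-ddCT qPCR quantification. Adapter
trimming and genome alignment are out of scope: the input is aligned,
BED-like records carrying the read sequence.

# The statistical model

## Normalization

Sample depth is normalized by median-of-ratios size factors: for sample $j$,

$$ s_j = \operatorname{median}_{i \,:\, \text{all } k_{i\cdot} > 0}
   \frac{k_{ij}}{(\prod_{v} k_{iv})^{1/m}} , $$

the median over features of the count divided by the feature's geometric
mean across the $m$ samples. This estimator assumes that a *majority of
features is unchanged* between conditions; the consequences for a global
loss of one RNA class are discussed under *Design choices* below.

## Dispersion estimation

Counts are modelled as negative binomial with mean $q_i s_j$ and variance
$q_i s_j + \alpha_i q_i^2 s_j^2$. Raw per-feature dispersions come from the
method of moments on normalized counts, pooling within-condition
variability across conditions with replicates:
$\hat\alpha_i = (v_i - \xi q_i)/q_i^2$ with $v_i$ the pooled within-group
variance, $q_i$ the overall mean of normalized counts and $\xi$ the mean
reciprocal size factor; negative estimates are floored at 0. A
mean-dispersion trend is then fitted:

* **parametric** — $\alpha(q) = a_0 + a_1/q$ via an iterated Gamma GLM with
  ratio-based outlier trimming, the natural choice for compact feature sets
  such as miRNAs;
* **local** — a running-median trend of $\log \hat\alpha$ against
  $\log q$ (window ~10 % of the features), used for large contig sets. The
  contract is a smooth decreasing trend; a running median was preferred
  over a local-regression smoother because it is robust to the mass of
  zero-variance features and has no tuning beyond the window.

Under **maximum sharing** each feature's final dispersion is
$\max(\hat\alpha_i, \alpha(q_i))$, floored at $10^{-8}$; this is
deliberately conservative, trading power for protection against
underestimated dispersions. Features with all-zero counts are kept in the
matrix but excluded from fitting and assigned $p = 1$.

## The exact test

For two conditions A and B a feature's counts are summed within condition
($k_A$, $k_B$). Conditioned on $k_A + k_B$, each sum is modelled as NB with
mean $q\,s_A$ (resp. $q\,s_B$) and variance
$q\,s_A + \alpha q^2 \sum_{j \in A} s_j^2$, and

$$ p = \frac{\sum_{a+b=k_A+k_B,\; P(a,b) \le P(k_A,k_B)} P(a,b)}
            {\sum_{a+b=k_A+k_B} P(a,b)} . $$

The test is exchangeable in the group labels, and its null type-I error is
verified by simulation in the acceptance suite. Fold changes are
$\log_2(\bar q_B / \bar q_A)$ on normalized group means, with the
conventions $x/0 \mapsto +\infty$, $0/x \mapsto -\infty$ (serialized as the
literals `Inf`/`-Inf`, which do occur for transcripts absent from the
control group) and $0/0$ undefined. Multiple testing is controlled by
Benjamini-Hochberg step-up adjustment; significance defaults to adjusted
$p < 10^{-6}$ (the tables of the motivating study report adjusted values;
a raw-p mode is available via `filter_significant(..., on = "pvalue")`).

## Variance stabilization

`vst()` integrates $1/\sqrt{q + a_1 q + a_0 q^2}$ under the fitted trend.
The parametric fit has the closed form

$$ \mathrm{vst}(q) = \log_2\!\frac{1 + a_1 + 2 a_0 q +
   2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0} , $$

which converges to $\log_2 q$ for large counts and to square-root
(Anscombe-type) stabilization as $a_0, a_1 \to 0$. For the local fit the
integral is evaluated by trapezoidal quadrature on a 2048-point log-spaced
grid and anchored to $\log_2$ at the high-count end. Sample clustering uses
Euclidean distances on variance-stabilized data with complete-linkage
agglomeration.

# Interval and classification conventions

* Coordinates are 0-based half-open in all BED I/O and 1-based closed
  inside R (the GenomicRanges convention); overlap means
  `startA < endB && startB < endA` in half-open terms.
* Contigs merge same-strand alignments of 24-36 nt with gaps up to 100 bp
  (boundary inclusive: a gap of exactly 100 still merges) and discard
  contigs supported by fewer than 100 alignment records. Multi-mapped reads
  contribute one unit per alignment record. A 24-35 nt read window — the
  alternative published wording of the inclusion rule — is available via
  `contig_params(max_read_len = 35)`; the default follows the
  methods-section wording (24-36).
* Classification precedence defaults to
  miRNA > tRNA > piRNA cluster > repeat > exon > unannotated, placing the
  most specific annotations first; it is fully configurable, and precedence
  only matters for reads overlapping several tracks. tRNA lookup is
  strand-aware (fragment origin is strand-specific); repeat/exon lookup is
  strand-ignorant. Length windows are 18-24 / 25-31 / 32-36 nt.
* tRNA fragments are typed by length alone: <= 24 nt tRF, >= 28 nt tRNA
  half, 25-27 nt ambiguous — boundaries bracketing the ~20 nt and ~30 nt
  descriptors of the two classes and configurable in `class_config()`. The
  end of origin is called 5'/3' when the read terminus lies within 2 nt of
  the mature tRNA end.
* Signature fractions (5'U, 5'G, 10A) are computed on *unique* sequences,
  while the length histogram uses all reads — the two denominators are
  intentionally different, matching how such panels are usually produced.
  T and U are equivalent on input; positions are 1-based from the 5' end.
  Information content is $2 - H$ bits with raw entropy $H$; no small-sample
  correction is applied (logo conventions differ here, and the uncorrected
  score is what the package's checks expect; a correction could be layered
  on the exported frequency matrices).

# The synthetic-data generator

`simulate_experiment()` emulates the read populations this analysis
assumes, so that every downstream stage can be exercised against a known
truth table. Design choices:

* **Reads are emitted pre-aligned** (coordinates + sequence); no aligner or
  sequencing-error model is simulated. Sequences are *generated*, not
  copied from the toy genome: identical loci yield identical sequences
  within a sample, positional biases are imposed at positions 1 and 10, and
  all other positions are uniform over A/C/G/U.
* **Study conditions.** Defaults: 12 normal vs 10 tumor samples, 100,000
  expected reads per sample, NB dispersion 0.05, log-normal library-size
  variation (sdlog 0.1). The piRNA population (cluster- and repeat-derived)
  carries 5'U with probability 0.70 and 10A with probability 0.35 in normal
  samples (0.25 = no bias in tumors); tRNA halves of 32-34 nt carry 5'G
  with probability 0.60 in all groups. Class mixture (normal):
  miRNA 0.26, piRNA clusters 0.18, repeats 0.16, tRNA halves 0.27,
  tRFs 0.04, exons 0.06, background 0.03 — chosen so that ~90 % of
  32-36 nt reads are tRNA-derived and the length histogram has its three
  modes at 22, 30 and 33 nt. Tumor samples scale the whole piRNA population
  by $2^{-5}$ and a designated set of 23 miRNA loci by $2^{+11}$ from a low
  baseline (0.2 reads/sample), reproducing near-zero normal counts and the
  occasional infinite fold change. A carcinoma-in-situ group interpolates
  normal and tumor parameters at a configurable mixture fraction (default
  0.5), reflecting its standing as a transitional state with a mixed cell
  population.
* **Annotation composition.** 114 piRNA clusters (the reference resource's
  cluster count), 150 repeat elements, 600 tRNA genes (the realistic
  genomic count) and 300 exons, placed without overlap on three 1-Mb
  chromosomes. The piRNA-affected features are thereby ~23 % of the contig
  set. This is a *fidelity constraint*, not a free dial: median-of-ratios
  normalization assumes a majority of unchanged features, and if most
  contigs carried the $2^{-5}$ shift the size factors would absorb it (the
  sample median ratio would sit inside the shifted mass), biasing every
  fold change upward and manufacturing false positives. Real contig sets
  satisfy the assumption — most merged contigs are not high-expression
  piRNA precursors — and the generator must too for the method to be
  evaluated under its operating conditions.
* **Multi-mapping.** 20 % of piRNA-population reads emit 2-5 alignment
  records (identical sequence, decoy loci of the same class, capped at
  100), mirroring multi-hit reporting limits of the usual aligner settings;
  the default counting policy counts every alignment record, so multi-locus
  piRNAs are retained.
* miRNA-class and tRF reads are emitted at 18-23 nt so the 24-36 nt contig
  window contains no miRNA-sized reads, matching the analysed miRNA length
  range (17-23 nt) of the motivating study.
* **What is not emulated:** sequencing errors and quality scores, adapters,
  isotype-level tRNA biology (anticodon families are labels only), genuine
  sequence homology between repeat copies, tumor mid-window take-over by
  tRNA reads (the loss appears in absolute counts, with window composition
  fixed per class), and real genome/annotation retrieval. Green tests on
  simulated data therefore certify the statistical machinery and the
  interval/classification logic, not robustness to alignment artifacts or
  annotation errors in real data.

# Numerical choices and degenerate inputs

* Gap rule: `reduce(min.gapwidth = max_gap + 1)`, i.e. "gaps up to
  100 bp" is boundary-inclusive.
* Dispersion floor $10^{-8}$; negative method-of-moments estimates floored
  at 0 *before* maximum sharing. When no feature shows extra-Poisson
  variance, the fitted trend is zero and finals sit at the floor (with a
  warning).
* The exact test compares split probabilities with a $1 + 10^{-7}$
  relative tolerance so that ties between symmetric splits are not broken
  by floating-point noise.
* Ranking ties in `top_n_features()` break lexicographically by feature id;
  "most highly expressed" means highest mean variance-stabilized value.
* All-zero features: $p = 1$, fold change undefined (0/0), excluded from
  size-factor geometric means and dispersion fitting.
* Empty read sets give all-zero histograms, not errors; lengths without
  unique sequences report `NA` fractions, not 0.
* qPCR: the >35-cycle negativity cutoff applies to the replicate mean by
  default (`cutoff_on = "replicate"` switches to single-replicate
  triggering); replicate CTs are averaged arithmetically; the calibrator is
  a single reference sample, so its RQ is exactly 1.
* Every operation that draws random numbers takes an explicit seed and
  restores the RNG state, so runs are reproducible end to end;
  `run_pipeline()` writes an md5 manifest and reruns are byte-identical.

# Problem sizes used in the checks

The package's own verification runs at desk scale, chosen to exercise every
code path with comfortable statistical margins: the full recovery check
simulates the default 22-sample design at 100,000 expected reads per sample
(~2 million alignment records) and completes in well under a minute; null
calibration uses 2,000 features at 10 vs 10 samples; oracle-equivalence
checks compare each interval/counting/clustering/testing primitive against
an independent brute-force implementation on 100 random small instances.
Counts reported by a full-size study (hundreds of millions of reads,
~184,000 contigs) are far beyond what a generator of this kind needs in
order to validate the statistics, and are not reproduced.

# Known limitations

* The exact test covers two-condition comparisons only; multi-factor
  designs and shrunken fold-change estimators are out of scope.
* The local dispersion trend is a running median, not a local regression;
  it matches the contract (smooth, decreasing, robust) but not any
  particular historical implementation detail.
* Under a true global loss affecting a majority of features,
  median-of-ratios normalization is not identifiable; the package does not
  attempt to detect or correct this, it documents the assumption (above)
  and the generator respects it.
* Classification is exclusive by precedence; overlapping annotation of a
  read to several classes is resolved, not reported as multi-label (the
  per-alignment table allows reconstructing multi-label views for
  multi-mapped reads).
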