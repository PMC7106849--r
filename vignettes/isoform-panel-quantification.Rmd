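---
title: "Isoform quantification from probe panels: models, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform quantification from probe panels: models, assumptions, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopanel)
```

## The measurement model

A targeted counting panel measures one gene with $m$ capture probes, each
hybridizing to a non-empty subset of the gene's $n$ isoforms. Writing
$A \in \{0,1\}^{m \times n}$ for the probe–isoform incidence matrix
($A_{ji} = 1$ iff probe $j$ targets isoform $i$), the expected probe signal
is linear in the unknown isoform expressions $x \ge 0$:

$$ y \approx A x, \qquad x \ge 0 .$$

`deconvolve_gene()` estimates $x$ by non-negative least squares,

$$ \hat x = \arg\min_{x \ge 0} \; \lVert y - A x \rVert^2 ,$$

solved with a Lawson–Hanson active-set iteration (`nnls_fit()`). The method
assumes (i) signal is additive across the isoforms a probe captures, with
equal per-molecule efficiency within a probe; (ii) probe-to-probe efficiency
differences are absorbed by the between-sample normalization and otherwise
ignored; (iii) noise is homoscedastic enough on the count scale that an
unweighted least-squares fit is sensible. Gene-level expression is defined
as $\sum_i \hat x_i$, which for a design containing a gene-level "max"
probe coincides with that probe's signal whenever the system is exactly
consistent.

### Identifiability

The fit is unique iff $\operatorname{rank}(A) = n$. Because $A$ is a small
0/1 matrix, rank is computed *exactly* by Bareiss fraction-free integer
elimination (`check_identifiability()`); floating-point rank with a
tolerance would be ambiguous precisely on the borderline designs one needs
to diagnose. Isoforms with identical columns of $A$ are reported as an
indistinguishable group — any split of their summed expression gives the
same fit, so per-isoform values inside a multi-member group are reported as
not estimable (`NA`) and only the group sum is meaningful
(`collapse_to_groups()` produces the matching group-level features). Rank
deficiency *not* explained by duplicated columns (e.g. one column equal to
the sum of two others) is flagged separately as `partially_identifiable`;
isoforms targeted by no probe at all are listed as `untargeted` rather than
silently reported as zero. The canonical full-rank construction is the
max-probe design (`design_max_probe_panel()`): one probe covering all $n$
isoforms plus $n-1$ singleton probes; the left-out isoform is recovered as
the max-probe signal minus the others.

### Normalization

`housekeeping_normalize()` rescales each sample so that the geometric mean
of its housekeeping probe counts equals the cohort-wide geometric mean of
those per-sample geometric means. Two references were possible — a fixed
anchor value or the cohort mean; the cohort mean was chosen because it is
symmetric in the samples and preserves the overall scale of the data (the
across-sample geometric mean of housekeeping signal is exactly invariant, a
property the tests assert). The canonical ten-gene housekeeping set
(`housekeeping_genes`) is the default for the bundled panel layout; any
housekeeping-class probes present in a panel are used otherwise. Technical
replicates are averaged (arithmetic mean of normalized counts,
`collapse_replicates()`) *before* deconvolution: averaging first reduces
noise entering the NNLS, whose non-negativity clip is a nonlinear step
after which averaging would no longer be unbiased.

### Transforms

Expression is carried on the raw scale until the final reporting step and
then transformed as $\log_2(x+1)$ (`log_transform()`). The log base is
configurable and immaterial for every rank-based statistic downstream;
base 2 makes fold changes read in doublings.

## Proportions and the agreement statistic

Within-gene proportions $p_{ij} = x_{ij} / \sum_j x_{ij}$ discard gene-level
scale and isolate splicing structure. Gene/sample combinations with zero
total expression are excluded and recorded, never imputed as uniform —
uniform imputation would shrink any between-platform difference toward zero
in exactly the low-expression stratum where platforms disagree most.

Two platforms' proportion tables are compared per sample by

$$ d = \frac{1}{n} \sum_{i=1}^{n} \frac{1}{m_i}
       \sum_{j=1}^{m_i} \left| p^{a}_{ij} - p^{b}_{ij} \right| $$

over the $n$ genes represented with identical isoform sets on both
platforms. $d$ is a scaled-L1 metric: symmetric, zero iff the tables agree,
and bounded in $[0, 1]$ — each gene's term is at most $2/m_i$, so the
maximum 1 is attained only when every gene has two isoforms and all mass
sits on disjoint isoforms. Genes estimable on only one platform are
excluded (intersection semantics); for non-identifiable designs the
comparison is made at group resolution after collapsing *both* platforms to
the same indistinguishable groups, which keeps $d$ well defined.

qPCR cycle thresholds enter the same space through the comparative-Ct rule
with a fixed per-cycle efficiency of 2 (configurable):
$q_j = E^{-Ct_j}$, $p_j = q_j / \sum q_j$. Any normalization that adds a
constant to all of a gene's Ct values (e.g. to total RNA input) cancels in
the proportions, so no explicit input-normalization step is needed or
implemented.

## The concordance battery

* **Per-sample Spearman** (`spearman_per_sample()`): rank correlation over
  shared features within each shared sample, average ranks for ties;
  invariant to monotone transforms, so raw and log inputs agree. Constant
  vectors yield `NA` with a warning rather than an arbitrary number.
* **Pooled correlation** (`pooled_correlation()`): one coefficient over all
  (feature, sample) dots. Pooling is deliberately reported *alongside* the
  per-sample mean — sample-specific offsets can pull the pooled value below
  the per-sample coefficients, and both views are informative.
* **Low-expression subset** (`low_expression_subset()`): features ranked by
  mean expression across samples within each platform; bottom
  $\lfloor N/3 \rfloor$ of each; intersection. Mean-across-samples ranking
  (rather than per-sample ranking) was chosen because it yields a single
  well-defined subset per platform pair; the floor convention makes the
  subset size deterministic.
* **Fold changes** (`fold_change_pairs()`): for a target tissue, the
  difference of $\log_2(x+1)$ values for every (target sample, other
  sample) pair and gene — exactly $|{\rm target}| \times |{\rm other}|
  \times G$ values; raw ratios are available behind a flag.
* **Differential expression** (`anova_de()`): per gene a one-way
  fixed-effects ANOVA F test across tissue groups; groups with fewer than
  two samples are dropped (no within-group variance estimate); ranking by
  ascending p with lexicographic gene-id tie-break so top-$k$ lists are
  deterministic. Raw p-values are the primary output; a Benjamini–Hochberg
  column is attached as clearly supplementary.
* **Rank-sum comparison** (`rank_sum_compare()`): two-sided Wilcoxon test
  between two sets of agreement statistics; exact null distribution for
  tie-free combined $n \le 20$, normal approximation with tie correction
  otherwise; an all-tied input returns $p = 1$ with a warning.

## What the simulator emulates — and what it does not

`simulation_config()` defaults describe a targeted cancer-isoform panel:
155 multi-isoform genes split 79/37/18/21 across 2/3/4/5-isoform
categories (the ">4" category is collapsed to exactly five isoforms, a
configurable simplification), max-probe designs throughout, ten
single-isoform housekeeping genes, fourteen spike-in control probes, 46
samples over six tissue types assigned round-robin, and two technical
replicates. Category allocation is deterministic (largest remainder) by
default so composition checks are exact; a multinomial mode exists for
sampling studies.

Expression truth: per-isoform log-normal baselines (meanlog 5, sdlog 1.5 on
the natural-log scale — median ≈ 150 counts with roughly three orders of
magnitude of dynamic range, typical of targeted counting data), an
independent log-normal per-sample biological factor (sd 0.5), housekeeping
genes held constant, and a configurable fraction (default 0.2) of genes
carrying a 4-fold shift in one tissue.

Measurement: probe counts are $y = A x_{\rm true}$ times two multiplicative
log-normal factors — one shared by a sample's replicates (`noise_sd`,
default 0.2: sample-preparation and hybridization-batch error) and one
independent per replicate (`replicate_sd`, default 0.1: counting noise) —
plus an additive background floor (default 0; the quantification applies no
background correction, so the default forward model matches it). The
sequencing-like view reassigns a fraction `ambiguity` of each gene's mass
uniformly among its isoforms before Poisson sampling — a one-parameter
caricature of shared-exon read ambiguity. The array-like view adds a
background floor that compresses the low-expression range. These
platform-bias forms are deliberate caricatures: they reproduce the
qualitative phenomena (isoform agreement below gene agreement;
low-expression compression) without claiming to model any real instrument's
error structure. Passing simulation tests therefore demonstrates internal
consistency and the *direction* of platform effects, not calibrated
agreement with any particular laboratory dataset: no probe-specific
affinity bias, no GC/length effects, no cross-hybridization between genes,
no library-preparation artifacts are modeled.

### Error propagation in max-probe designs

One structural property deserves emphasis. In a max-probe design the
left-out isoform is estimated as the max-probe signal minus the
isoform-specific signals, so its *absolute* error aggregates the noise of
every probe in the gene while its true value may be small: its *relative*
error is amplified by roughly the gene-total-to-isoform ratio. Directly
probed isoforms do not suffer this. In the bundled simulations at the
default 20% multiplicative probe noise, rank recovery of directly probed
isoforms is excellent while residual isoforms are substantially noisier,
and the median per-sample rank correlation between recovered and true
isoform expression lands in the high 0.8s rather than near 1 (the
acceptance script recomputes the exact value). This is the same mechanism
that makes isoform-level cross-platform agreement systematically worse than
gene-level agreement, and it is a property of the design class, not of the
solver: the NNLS estimate is exact whenever the system is consistent.

## Numerical choices

* NNLS: deterministic all-zero start; dual-feasibility tolerance
  $10^{-10} \max(1, \lVert A^\top y\rVert_\infty)$; rank-deficient passive
  sets filled via QR with `NA` coefficients zeroed (minimum-norm behavior);
  anti-cycling by the standard step-length rule. No randomness anywhere in
  the solver.
* Exact integer rank for designs; the test suite cross-checks it against a
  brute-force minor-expansion oracle up to 6×6.
* Proportions sum to 1 within $10^{-9}$ per gene and sample (asserted);
  comparative-Ct exponentiates after subtracting the per-gene minimum Ct
  for numerical stability (a shift invariance, not an approximation).
* TSV interchange writes 12 significant digits, which round-trips all
  quantities the package produces to well below every tolerance used.
* Degenerate inputs have defined behavior throughout: zero-expression genes
  are excluded-and-counted, constant vectors yield `NA` correlations with
  warnings, all-tied rank-sum inputs yield $p = 1$, single-sample tissue
  groups are dropped with warnings.

## Problem sizes used by the bundled checks

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen as the smallest sizes at which each property is
informative: the solver-vs-oracle comparison uses 500 random 2–4-isoform
instances; the proportion-metric property checks use 1,000 random table
pairs over an 8-gene set; rank-recovery uses 20 seeded simulations of the
full 150-gene panel with 4 samples each (per-sample statistics make sample
count a replication knob, not a power knob); the platform-trend and
ANOVA-null simulations use 60-gene × 8-sample and 600-gene × 30-sample
configurations respectively.

## Known limitations

* Probe efficiency heterogeneity is not modeled or corrected; real panels
  would benefit from per-probe calibration factors, which the linear model
  could absorb but which require spike-in or reference-sample data the
  package does not assume.
* The indistinguishable-group construction is exact only for duplicate
  columns; rank deficiency of other forms is flagged but the affected
  isoform combinations are not enumerated.
* Spike-in probes are parsed, simulated and excluded from quantification,
  but no quality-control rule is applied to them.
* The ANOVA F test assumes approximately normal within-group log
  expression; under the simulator's log-normal biological variation its
  type-I error runs slightly conservative (the acceptance script reports
  the realized rate).
* `d` weights every gene equally regardless of expression level; a
  precision-weighted variant would behave differently in the low-expression
  stratum.
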