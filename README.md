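# isopanel

Isoform-level quantification from targeted hybridization probe panels, and a
cross-platform concordance battery for comparing the result against other
expression platforms.

## The problem

Most multi-exon genes express several splice isoforms, and the isoforms of
one gene share exonic sequence. Targeted counting platforms (NanoString
nCounter style) measure a gene with a handful of 100-bp capture probes, each
of which hybridizes to one *or several* isoforms — typically one "max" probe
covering a region common to all isoforms (total gene expression) plus
isoform-specific probes. Recovering per-isoform expression from such probe
signals is a small deconvolution problem per gene, and whether it has a
unique answer depends entirely on the probe design.

`isopanel` implements that quantification and everything needed to judge it:

- **Design diagnostics.** For a gene with isoforms *1..n* and probes
  *1..m*, the 0/1 incidence matrix **A** has `A[j, i] = 1` iff probe *j*
  targets isoform *i*. The design identifies every isoform iff
  rank(**A**) = *n* (computed exactly, by integer elimination); isoforms
  with identical columns of **A** are grouped as indistinguishable, and
  only their summed expression is reported.
- **Quantification.** Probe counts are normalized per sample by the
  geometric mean of housekeeping-gene counts, technical replicates are
  averaged, and each gene's isoform expressions are estimated as

      x̂ = argmin ‖y − A x‖²   subject to   x ≥ 0,

  solved by a deterministic Lawson–Hanson active-set NNLS. Gene expression
  is the sum of the gene's isoform expressions; expression matrices are
  reported on the raw scale and as log₂(x+1).
- **Proportion metrics.** Within-gene isoform proportions
  `p_ij = x_ij / Σ_j x_ij`, and the platform-agreement statistic

      d = (1/n) Σ_i [ (1/m_i) Σ_j | p^a_ij − p^b_ij | ]  ∈ [0, 1],

  a scaled-L1 distance between two platforms' proportion tables (0 iff they
  agree). RT-qPCR cycle thresholds are converted to the same proportion
  space by the comparative-Ct rule `q_j = 2^(−Ct_j)`, `p_j = q_j / Σ q_j`.
- **Concordance battery.** Per-sample and pooled Spearman correlations at
  isoform and gene level, bottom-one-third low-expression subsets and their
  restricted correlations, target-tissue log fold-change pairs, one-way
  ANOVA differential-expression rankings across tissue types, and Wilcoxon
  rank-sum comparison of agreement statistics.
- **A multi-platform simulator** that generates ground-truth panels (155
  multi-isoform genes in a 79:37:18:21 mix of 2/3/4/5-isoform categories by
  default, 10 housekeeping genes, 14 spike-ins), probe counts
  `y = A·x + noise`, a sequencing-like count view with within-gene read
  ambiguity, an array-like view with a cross-hybridization background
  floor, and qPCR Ct tables — so every stage of the analysis is testable
  end to end without any external data.

It is aimed at anyone designing or analyzing targeted isoform panels, and at
anyone who wants a controlled sandbox for studying why isoform-level
agreement between platforms is systematically worse than gene-level
agreement.

## Worked example

A 4-isoform gene with the max-probe design, quantified from one sample's
probe intensities:

```r
library(isopanel)

fli1 <- gene_model("FLI1", c("NM_001271012", "NM_001167681",
                             "NM_001271010", "NM_002017"))
probes <- design_max_probe_panel(fli1)
inc <- build_incidence_matrix(fli1, probes)
inc
#> <incidence_matrix> 4 probes x 4 isoforms
#>          NM_001271012 NM_001167681 NM_001271010 NM_002017
#> FLI1_max            1            1            1         1
#> FLI1_p1             1            0            0         0
#> FLI1_p2             0            1            0         0
#> FLI1_p3             0            0            1         0
check_identifiability(inc)
#> <identifiability_report> rank 4; identifiable

deconvolve_gene(c(10, 2, 3, 1), inc)$values
#> NM_001271012 NM_001167681 NM_001271010    NM_002017
#>            2            3            1            4
```

The max probe reads 10 and the three isoform-specific probes read 2, 3 and
1, so the fourth isoform — which has no probe of its own — is recovered as
the residual 10 − (2+3+1) = 4, exactly the by-hand calculation the design
permits.

A full synthetic three-platform comparison:

```r
cfg <- simulation_config(n_genes = 40, n_samples = 12, seed = 42)
truth <- simulate_truth(simulate_panel(cfg), cfg)
views <- simulate_platform_views(truth)   # probe_capture / count / array
platform_agreement_report(views, panel_annotation(truth), truth$labels)
#> <concordance_report> platforms: probe_capture, count, array; 12 shared samples
#>   probe_capture_vs_count: median isoform R_s 0.843 | median gene R_s 0.957 | median d 0.082
#>   probe_capture_vs_array: median isoform R_s 0.870 | median gene R_s 0.930 | median d 0.086
#>   count_vs_array: median isoform R_s 0.931 | median gene R_s 0.953 | median d 0.044
```

Each line is one platform pair: the median per-sample Spearman correlation
of isoform expressions, of gene expressions, and the median per-sample
proportion difference *d*. Gene-level agreement exceeding isoform-level
agreement — here by ~0.1 of correlation on every pair — is the expected
signature of shared-exon ambiguity and residual-isoform error propagation;
the simulator reproduces it under realistic noise.

The same analyses run from the shell via
`Rscript inst/scripts/isopanel.R <simulate|quantify|proportions|compare|de>`
with a YAML config, `--out` and `--seed`.

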