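# sesvlinks

Integrated super-enhancer × structural-variant analysis for tumor
cohorts profiled with H3K27Ac ChIP-seq, whole-genome sequencing and
RNA-seq.

In many lung adenocarcinomas no actionable driver mutation is found,
yet hundreds of super-enhancers (SEs) and structural variants (SVs) are
detected per case. When an SV breakpoint lands in or near a
super-enhancer, the rearrangement can place strong regulatory activity
next to an oncogene ("enhancer hijacking") and drive outlier
over-expression with prognostic consequences. `sesvlinks` implements
the complete analysis chain for detecting such events and relating them
to outcome:

1. **SE calling** — stitch H3K27Ac peaks (gap ≤ 12.5 kb), rank stitched
   regions by total signal, and split super from typical enhancers at
   the slope-1 tangent of the scaled rank–signal curve (ROSE-style
   "hockey stick" cutoff).
2. **SV windowing** — consolidate SV calls (SURVIVOR-style merge,
   ±1 kb, type-matched) and expand every breakend into the 20 kb window
   `[pos − 10 kb, pos + 10 kb)`.
3. **SE–SV overlap** — intersect SE regions with breakpoint windows
   (≥ 1 bp), summarize per-sample `log2(count + 1)` frequencies, and
   compare cohorts with Student's two-sided t-test.
4. **Peak-to-gene links** — for consensus peaks within 0.5 Mb of a TSS,
   Pearson correlation *r* between peak signal and expression across
   samples, permutation p-value `p = (1 + #{|r_b| ≥ |r|})/(B + 1)`,
   Benjamini–Hochberg FDR, then the SE-to-gene table: genes with
   FDR < 0.05 annotated to **both** an SE and an SV, ranked by FDR.
   Scatter shape is scored with a least-squares line and the local
   outlier factor (k = 10, z-scored axes).
5. **Outliers and survival** — per-gene outlier fence Q3 + 1.5·IQR
   (type-7 quartiles), per-case outlier status over a gene set (e.g.
   the six-gene driver set CDK4, ERBB2, MDM2, FRS2, EGFR, CAV2), and
   Kaplan–Meier / log-rank stratification of recurrence-free survival.

Because patient-level data of this kind are usually access-restricted,
the package includes a synthetic-cohort generator with planted SE–SV-driven genes
and ground truth, so every stage — and the package's own validation —
runs end-to-end with no external data. See
`vignettes/sesv-methods.Rmd` for the full model description.

## Worked example

```r
library(sesvlinks)

co  <- generate_cohort(synthetic_config(seed = 7))   # 160 samples, 20 planted genes
res <- run_cohort_analysis(co, pipeline_params(seed = 7))

head(res$filtered[, c("gene_id", "symbol", "peak_id", "r", "p", "fdr", "max_lof")], 5)
#>   gene_id   symbol    peak_id     r        p     fdr max_lof
#> 1   G0039 GENE0039 peak_00019 0.578 0.000999 0.00517    4.75
#> 2   G0162 GENE0162 peak_00402 0.550 0.000999 0.00517    2.89
#> 3   G0060 GENE0060 peak_00114 0.548 0.000999 0.00517    2.82
#> 4   G0177 GENE0177 peak_00316 0.534 0.000999 0.00517    5.84
#> 5   G0026 GENE0026 peak_00068 0.526 0.000999 0.00517    3.20

res$cohort_test
#>         metric t_statistic  p_value mean_noncaga mean_caga
#> 1      log2_sv       0.966 3.36e-01         5.01     4.973
#> 2 log2_overlap       4.544 1.09e-05         1.05     0.294

mean(co$truth$planted_genes %in% res$filtered$gene_id)   # planted-gene recovery
#> [1] 1

c(chi2 = res$rfs$chi2, p = res$rfs$p)
#>        chi2           p
#> 38.4         5.7e-10
```

Reading the output: every planted gene reaches the SE-to-gene table at
the permutation floor `p = 1/1001` (B = 1000), with elevated max-LOF
scores marking the carrier samples as scatter outliers. SV frequency
does not differ between cohorts (`log2_sv`, p = 0.34) while SE–SV
overlap frequency is markedly higher in the non-CAGA arm where events
were planted (p ≈ 1e-5). The outlier-positive stratum (n = 48) shows
strongly reduced recurrence-free survival (log-rank χ² = 38.4).

File-based work uses the same functions behind a config:
`write_cohort()` emits narrowPeak/SV-VCF/TSV inputs, and
`run_all(config)` validates paths, runs every stage, writes TSV/BED
artifacts plus a JSON run manifest with parameters and checksums, and
is byte-identical across reruns of the same config and seed.

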