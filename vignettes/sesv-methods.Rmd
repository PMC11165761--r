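---
title: "Methods: integrated super-enhancer and structural-variant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated super-enhancer and structural-variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sesvlinks)
```

## The analysis in one paragraph

`sesvlinks` asks whether large H3K27Ac-defined enhancer clusters
(super-enhancers, SEs) co-localize with structural-variant (SV)
breakpoints in a tumor cohort, and whether the genes regulated by such
SE–SV regions show aberrant, clinically relevant over-expression. The
chain is: call SEs per sample by rank ordering of stitched peak signal;
consolidate SV calls and expand each breakend into a 20 kb window;
intersect SEs with windows; link peaks to genes by correlating peak
signal with expression across samples against a permutation null with
Benjamini–Hochberg (BH) control; keep genes annotated to both an SE and
an SV; flag expression outliers with the Q3 + 1.5·IQR fence; and compare
recurrence-free survival (RFS) between outlier-positive and -negative
cases with Kaplan–Meier curves and the log-rank test.

## Coordinates and overlap

All internal coordinates are 0-based half-open. BED-family input is read
verbatim; VCF positions are decremented on read and incremented on write
(a deletion record with `POS=1001`, `END=5000` has internal breakends
1000 and 5000, the edges of the half-open span). Two intervals overlap
when they share a chromosome and at least 1 bp — partial overlap and
complete containment count equally, and no minimum-fraction option is
applied by default. Chromosome names are compared after stripping an
optional `chr` prefix (configurable), because mixed GRCh38 naming
dialects are common. The overlap engine is
`GenomicRanges::findOverlaps`; the test suite checks it against an
all-pairs brute-force scan on a thousand random instances.

## Super-enhancer calling

Peaks from one sample are stitched transitively whenever the inter-peak
gap is at most `stitch_distance` (default 12,500 bp, the ROSE
convention; a gap exactly at the threshold merges). An optional TSS
exclusion zone (default off) removes promoter-contained peaks before
stitching. Stitched regions are ranked by total constituent signal,
rank and signal are rescaled to [0, 1], and the super/typical cutoff is
the point where a 45-degree support line first touches the scaled
rank–signal curve when raised from below — on a convex hockey-stick
curve this is exactly where the curve's slope drops through 1 scanning
from the high-signal end. We use the support-line formulation rather
than a literal left-to-right slope scan because it is well defined on
noisy, locally non-convex curves and guarantees two properties the scan
does not: labels are monotone in signal, and the region with the
strictly maximal signal is always super when any signal spread exists.
All-equal signals yield a flat curve and, by convention, zero
super-enhancers. Signals are used as provided, with no per-sample
normalization: the downstream peak–gene correlation is scale-invariant,
which is where cross-sample comparability matters.

## SV consolidation and breakpoint windows

Within a sample, two SV calls merge when their breakpoints agree
positionwise within `merge_dist` (default 1,000 bp) on matching
chromosomes and, by default, share the SV type — a simplified,
single-linkage re-implementation of the usual SURVIVOR screening step.
The representative of a merged group is its coordinate-smallest member
and carries the support count. Every breakend of every call (both ends
of DEL/DUP/INV/TRA, the single recorded position of an insertion)
becomes a window `[pos − flank, pos + flank)` clipped at zero; the
default flank of 10 kb realises the 20 kb region surrounding a
breakpoint that enters the SE intersection. Windowing both breakends is
the default because rearrangements act at both ends; a one-end mode is
available through the breakpoint table.

## Peak-to-gene and SE-to-gene links

Candidate pairs are consensus peaks within 0.5 Mb of a gene's TSS
(minimum distance from the peak interval, half-open). Each link's
statistic is the Pearson correlation between per-sample peak signal and
per-sample log-scale expression — Pearson because the displayed fit is
a straight least-squares line; Spearman is available by flag.
Significance comes from a per-link label-permutation null with the
add-one estimator `p = (1 + #{|r_b| ≥ |r_obs|})/(B + 1)` (B = 1000 by
default, attainable minimum 1/(B+1)); one seeded permutation-index
matrix is shared across the links of a run, which leaves each link's
marginal p-value exact while avoiding per-link RNG cost. BH is used for
FDR because the link family is large; links with zero variance on
either axis are dropped with a note. The SE-to-gene table keeps links
with FDR < 0.05 whose gene is annotated both to an overlapped SE region
(TSS within ±50 kb of the region) and to an SV (TSS within ±50 kb of a
breakpoint), collapsed to the best link per gene and ranked by FDR.

Scatter shape is scored two ways: an
ordinary least-squares line, and the classic local outlier factor with
k = 10 after per-axis z-scoring (peak signal and expression are on
incommensurate scales); ties at the k-distance include all equidistant
neighbors. LOF is validated against both a looped reference
implementation and scikit-learn.

## Outliers and survival

Per gene, quartiles are computed across all samples by linear
interpolation (R's type-7 convention — pinned and exposed because the
fence depends on it) and a sample is an outlier when its expression
strictly exceeds Q3 + 1.5·IQR. Only the upper tail is fenced: the
analysis targets over-expression. A case is outlier-positive when at
least one gene of the chosen set (the six-gene driver set CDK4, ERBB2,
MDM2, FRS2, EGFR, CAV2, or any user-supplied set) is an outlier.
Survival uses the product-limit estimator and the standard unweighted
1-df log-rank statistic (via the survival package), with RFS time in
months and censoring read from 0/1 or censored/recurrence labels.

## The synthetic cohort

Patient-level data of this kind are usually access-restricted, so the
package ships a generator whose defaults emulate such a study design
at desk scale: 120 non-CAGA + 40 CAGA samples, 3 chromosomes of 60 Mb,
200 genes, 300 consensus background peaks with i.i.d. log-normal(0, 1)
signal (heavy-tailed, so the rank curve is a convex hockey stick), and
Poisson(30) background SVs per sample. Twenty planted genes each
receive a cluster of 3–8 peaks near the TSS; each gene draws 8 carrier
samples from a positive pool comprising 40% of the non-CAGA cohort —
mirroring a design in which roughly 40% of cases harbor some SE–SV
event while any individual driven gene is rare. In carriers the cluster
peaks carry 10× signal, one SV breakpoint falls inside the cluster span
(so the 20 kb window must intersect the called SE), and expression is
shifted by 3 SD and raised above the non-carriers' Q3 + 2·IQR;
non-carrier values of planted genes are winsorized at their own fence
so they can never be flagged. RFS times are exponential with baseline
hazard 0.02/month, multiplied by 3 for truly positive cases, under
uniform administrative censoring on 12–60 months. One master seed
drives named sub-streams (genes, peaks, carriers, signal, svs,
expression, survival), so any stage regenerates independently and the
same config is byte-identical across runs.

What the generator does not emulate: read-level noise, copy-number
amplification and chromothripsis, peak presence/absence variation
across samples, correlated gene programs, and batch structure between
RNA-seq protocols. Passing recovery tests therefore show that the
pipeline's logic and statistics behave as designed under the stated
model, not that real cohorts will yield comparable effect sizes.

## Numerical choices and degenerate inputs

Sorted outputs break ties by (chromosome, start, end) for
reproducibility. An empty peak list yields an empty SE table rather
than an error; `rank_and_cut` on zero regions is an error because no
cutoff exists. Zero-variance link vectors give an undefined correlation
and are dropped with a logged count. The permutation p-value can never
be 0 by construction. `iqr_upper_bound` requires n ≥ 4; LOF requires
n ≥ k + 1 and defines the density ratio of exactly duplicated points as
1. The log-rank test refuses groups with zero total events. Problem
sizes in the test suite (cohorts of 160 samples, 20 recovery seeds,
B = 999–1000 permutations, 200–500 calibration replicates) were chosen
as the defaults of the study design the generator emulates.

## Known limitations

The SE caller reports stitched regions only, not constituent-level
output. Breakend orientation and inversion phase are ignored in
consolidation. The SE/SV gene annotation is TSS-proximity based; it
does not use topological domains or contact data. The permutation null
treats samples as exchangeable and does not model confounders. The
survival analysis is a two-group log-rank comparison without
multivariable adjustment.
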