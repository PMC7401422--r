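---
title: "Methods: weighted cross-study integration and pathway overrepresentation"
author: "metafold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted cross-study integration and pathway overrepresentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafold)
```

## The problem

Transcriptome studies of how trabecular-meshwork (TM) cells respond to
corticosteroids are typically tiny: one to six donors, sometimes with
technical replicates, each on its own array platform with its own gene
coverage.  No single study is conclusive, but together they carry a
consistent signal.  `metafold` implements a complete, testable pipeline
for that setting:

1. per-study preprocessing (quantile normalization, QC flags, replicate
   averaging) and differential statistics;
2. cross-study integration by evidence-weighted averaging of log2 fold
   changes and p-values;
3. a responder/nonresponder contrast for summary-level abundance data
   (mean FPKM per group) where no p-values exist;
4. pathway overrepresentation with a finite-population Z-score,
   permutation p-values and a three-part significance rule;
5. grouping of significant pathways into functional categories and a
   shared-gene network connecting them.

A synthetic-data generator with planted ground truth drives all testing.

## Per-study statistics

Expression values are log2 intensities throughout.  After quantile
normalization (delegated to `limma::normalizeQuantiles`, ties receiving
the mean of the rank-means they span — the standard convention),
replicates are averaged so each individual contributes one column per
condition and hence the same weight.  The treated-vs-control comparison
is unpaired across columns, because several eligible studies have a
single donor and a paired model would be undefined there.

The per-probe statistic is a two-sample pooled-variance t-test with
optional empirical-Bayes variance moderation.  Moderation fits a scaled
inverse-chi-square prior to the per-probe sample variances by moment
matching on the distribution of log variances (digamma/trigamma
inversion), then uses the posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ with $d_0 + d$ degrees of freedom.  This
is the standard small-sample stabilization for microarray data; a unit
test verifies that the implementation agrees with `limma::eBayes` to
numerical precision on a shared fixture.  Degenerate designs are handled
explicitly: one individual per group yields no residual degrees of
freedom and the probe is emitted with `p_value = 1` and a flag, never
NaN; zero-variance probes with a nonzero effect get the clamped minimum
p-value.

Probe-to-gene conversion may map several probes to one gene.  The record
kept is the one maximizing $|\mathrm{logFC} \cdot (-\log_{10} p)|$, i.e.
the largest change jointly in effect and evidence; exact ties go to the
lexicographically smallest probe id so results are reproducible.
Selection never alters the kept values.  Unmapped probes are counted and
reported.

## Cross-study integration

For a gene measured in $n$ studies with per-study log2 fold changes
$\mathrm{logFC}_i$ and p-values $p_i$:

$$\overline{\mathrm{logFC}} =
  \frac{\sum_i \mathrm{logFC}_i \cdot (-\log_{10} p_i)}
       {\sum_i (-\log_{10} p_i)},
  \qquad
  \bar w = \frac{\sum_i (-\log_{10} p_i)}{n},$$

with the combined p-value defined by back-transforming the average
weight, $\bar p = 10^{-\bar w}$ — the geometric mean of the $p_i$.  An
average weight of 4.33 therefore pairs with a combined p-value of about
5e-5, which is the consistency check we use in the tests.  Genes
measured in fewer than `k_min` of the studies (default 4 of 5) are
dropped; this both stabilizes the estimate and prevents large studies
that measure more genes from dominating the integrated list.  A gene is
called differentially expressed when $|\overline{\mathrm{logFC}}| >
0.58$ (about 1.5-fold on the original scale, since $2^{0.585} \approx
1.5$) and $\bar p < 0.05$, both strict inequalities.

Two numerical decisions matter here.  First, p-values are clamped at
1e-300 before taking $-\log_{10}$ so weights stay finite.  Second, if
every weight is zero (all $p_i = 1$, as happens for studies with no
residual degrees of freedom), the unweighted mean is returned and the
gene is flagged (`weight_fallback`) instead of being dropped on a 0/0.

The weighting deserves one note: a description of this scheme can also
be read as weighting studies by their number of individuals.  The
formula above — weights equal to $-\log_{10} p_i$ only — is the default,
since study size already enters through the p-values; an explicit
study-size multiplier ($w_i = n_i \cdot (-\log_{10} p_i)$) is available
behind `integration_config(size_weighted = TRUE)` for users who prefer
the other reading.  The two options are tested against each other.

## Responder/nonresponder contrast

Summary-level RNA-seq data (mean FPKM per gene for responders and
nonresponders, treated and control: $A, B, C, D$) admits no p-values, so
the contrast is purely fold-change based:

$$\mathrm{logFC}_R = \log_2\frac{A+1}{B+1},\qquad
  \mathrm{logFC}_{NR} = \log_2\frac{C+1}{D+1},$$

with the responder-specific signal $\mathrm{logFC}_R -
\mathrm{logFC}_{NR}$ and the overall treatment effect their mean.  The
+1 pseudocount is part of the definition (it prevents infinite values at
zero abundance) and is fixed; it is exposed only as an expert argument.
Changed genes are called by $| \cdot | > 0.58$ on whichever contrast the
run targets, strict, mirroring the integrated analysis.

## Pathway overrepresentation

With $N$ measured genes, $R$ changed, a pathway covering $n$ measured
genes of which $r$ changed, the score is the standardized excess under
sampling without replacement:

$$Z = \frac{r - nR/N}
          {\sqrt{n \frac{R}{N}\left(1-\frac{R}{N}\right)
                 \left(1-\frac{n-1}{N-1}\right)}}.$$

The denominator is exactly the hypergeometric standard deviation, which
the acceptance suite verifies by full enumeration for every valid
configuration up to $N = 40$.  When the variance is zero ($R = 0$,
$R = N$, or $n = N$) the score is defined as 0 and flagged rather than
NaN.

The permutation null permutes changed-gene labels across the measured
universe, preserving $R$ and every $n$; since $Z$ is monotone in $r$ at
fixed $(N, R, n)$, exceedance counting reduces to $r^* \ge r$, which we
evaluate for all pathways at once as one membership-matrix product per
permutation block.  Add-one smoothing, $(1 + \#\{r^* \ge r\})/(B + 1)$,
keeps permutation p-values strictly positive.  The test is one-sided
(overrepresentation), matching a rule that only flags positive Z.

A pathway is significant when $Z \ge 1.96$, permuted $p < 0.05$, and
$r > 3$ (i.e. at least 4 changed genes) — all three required.  No
multiple-testing adjustment modifies this call, because the joint rule
itself is the filter; a Benjamini–Hochberg column is emitted for
transparency only.  The universe is "the entire dataset": all genes
surviving the k-of-n filter for the integrated run, or all genes of the
contrast table for the abundance run — never the pathway-annotated
subset.

One calibration remark: for small pathways the permutation distribution
of $r$ is coarse, so attainable p-values are conservative.  Under a
fully random 5% changed-label null with pathways of 5–50 genes, the
fraction of pathways reaching $p < 0.05$ sits near the lower edge of the
nominal level (about 0.02–0.05 in our checks) rather than at 0.05
exactly.  This is a property of discrete permutation tests, not a bug.

## Functional categories and the shared-gene network

Grouping significant pathways into functional categories (ECM,
WNT-signaling, inflammation, ...) is in reality curation.  The
reference mode therefore takes a curated mapping file and copies it,
labelling unmapped pathways `"unassigned"`.  When no mapping is given,
an automated surrogate single-linkage clusters pathways on the Jaccard
similarity of their changed-gene sets, merging at similarity ≥ 0.3
(default; chosen so that pathways sharing roughly a third of their
changed genes merge, which matched block-structured fixtures well), and
labels each cluster by its largest pathway.  Every assignment records
its provenance so downstream readers can tell curation from surrogate.

The network links genes to the categories whose significant pathways
contain them, restricted to genes with $|\mathrm{logFC}| > 0.58$
(strict).  Gene nodes carry their logFC, an up/down direction, and
`n_clusters` — the number of categories they touch, which is the node
size in the field's standard rendering and the sort key of the
shared-gene table.  Exports are GraphML (attributes preserved) and SIF
(topology only); rendering is out of scope.

## The synthetic generator

`simulate_studies()` emulates the observed study landscape: 5 studies
with 1, 2, 5, 3 and 6 individuals by default, optional within-individual
replicates, each study covering a uniform random 85–100% of a shared
gene universe, 20% of genes carried by two probes (probes share the gene
effect plus a fixed probe-level offset, giving deduplication real work),
and additive Gaussian noise on the log2 scale (default SD 0.3).
Differential expression is planted at effect size ±1.0 log2 units,
concentrated in designated pathways (60% of their genes) over a 5%
background — the regime the recovery tests target.  Seeding uses one
master seed with fixed per-study offsets, so adding a study never
perturbs earlier ones.  Configurations whose coverage cannot leave any
gene in ≥4 studies (expected survivor count below 1 at the most
optimistic coverage) are rejected as infeasible.

`simulate_responder_table()` generates the four-column abundance table
on the FPKM scale with noise on $\log_2(x+1)$ and abundances clamped at
0.  By default the responder-specific genes are the planted DE genes
(signed consistently with their cross-study effect), so both analyses
see one shared biology and the contrast enrichment has pathway structure
to find; an alternative mode plants a flat effect on a random gene set
for calibration experiments.

What the generator does *not* emulate: platform-specific raw artifacts
(CEL-level background, RMA), count-level RNA-seq noise, correlated
probe effects, batch structure, and real pathway databases'
redundancy.  Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under the stated model, not
performance on any particular public dataset.

## Problem sizes and defaults used in validation

The shipped validation uses sizes chosen to exercise every code path at
desk scale: formula-fidelity oracles on 1,000 random tuples/tables;
permutation calibration on a 2,000-gene universe with 200 pathways of
5–50 genes, 1,000 permutations, 20 seeds; planted-signal recovery over
50 seeds; integration recovery over 5 seeds of 400-gene universes with
the default 5-study design; the Z-score enumeration over all valid
configurations with $N \le 40$; and a byte-determinism check of two
full pipeline runs.  `scripts/acceptance.R` recomputes exactly these
quantities from scratch against the installed package.

## Known limitations

* The QC stage flags samples by median inter-sample correlation
  (default threshold 0.8) plus zero-variance detection; it is an
  automated surrogate for what is, in practice, human judgment over
  diagnostic plots, and it will not reproduce any particular curated
  exclusion.
* The combined p-value is a geometric mean of per-study p-values, not a
  calibrated meta-analytic test (it is not Fisher's or Stouffer's
  method); it is used as a ranking/filter statistic together with the
  fold-change cutoff, and the false-positive rate of the joint call is
  what the recovery test controls.
* Studies contributing no p-value (single individual, no replicates)
  enter the weighted logFC with zero weight and dilute the average
  weight by construction; they still count toward the k-of-n filter.
* The Jaccard threshold for the clustering surrogate is a heuristic;
  curated mappings should be preferred whenever available.
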