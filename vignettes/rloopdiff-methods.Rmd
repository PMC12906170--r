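---
title: "Methods: differential R-loop calling and its integration with expression"
author: "rloopdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential R-loop calling and its integration with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopdiff)
```

# Scope and data model

`rloopdiff` analyses replicated DRIP-Seq count data on a fixed-width genome
tiling and joins the resulting differential R-loop regions with differential
gene expression. In memory, intervals are `GRanges` against a `Seqinfo`
genome (1-based closed, the Bioconductor convention); on disk, BED files use
0-based half-open coordinates and the readers/writers convert. Count
containers are `SummarizedExperiment`s whose `colData` carries the sample
design (`genotype`, `condition`, `replicate`, and the derived `group`
label). Feature identifiers for bins and regions are BED-style strings
(`chrom:start0-end`), which keeps region identity stable across contrasts
and files.

Overlap semantics follow `bedtools`: a query is retained when it shares at
least one base with a subject and is reported whole (`-wa`); half-open
abutment is not overlap. Merging joins book-ended intervals (distance 0),
matching `bedtools merge` defaults. Both operations are checked in the test
suite against per-base boolean-mask oracles on small genomes.

# The counting and filtering stages

Fragments are assigned to bins by their midpoint (0-based
`floor((start + end) / 2)`). Each fragment is counted exactly once; a
fragment spanning a bin boundary belongs to the bin holding its midpoint.
This was chosen over fractional or double counting because it conserves
totals and makes the count model exact for the simulator's inverse test.

Before testing a contrast (A, B), bins are filtered: a bin is kept when
*every* replicate of A, or every replicate of B, has a count strictly
greater than 20. The one-sided "either group" form matters — a region fully
present in only one condition (e.g. gained on treatment) must survive the
filter. Multiple-testing adjustment is applied only within the kept bins of
that contrast, so the tested family is the covered genome, not the full
tiling.

# The negative-binomial Wald engine

The engine is deliberately self-contained and minimal:

* **Normalization** — median-of-ratios: for features positive in all
  samples, a sample's size factor is the median of count-to-geometric-mean
  ratios. The median is taken on the ratio scale (with an even reference
  count, the median of ratios differs from the exponentiated median of
  log-ratios; the former is the defined estimator).
* **Dispersion** — per-feature method of moments on normalized counts:
  pooled within-group variance `v` (denominator `n − G`) and grand mean `μ`
  give `α = max(1e-8, (v − μ)/μ²)` under `var = μ + αμ²`. The floor keeps
  the information matrix finite for under-dispersed features.
* **Test** — per-group ratio-estimator rates
  `q_g = Σ K / Σ s` (an all-zero group receives a 0.5 pseudocount in the
  numerator so log rates stay finite), natural-log fold change
  `β_B − β_A`, Fisher information `I_g = Σ_j μ_gj/(1 + α μ_gj)` with
  `μ_gj = q_g s_j`, `se = √(1/I_A + 1/I_B)`, and a two-sided normal p
  value.

No fold-change shrinkage, outlier replacement, or independent filtering is
performed: the package targets direction and threshold behaviour, not
numeric parity with any particular large-sample estimator, and the
unshrunken fold change is what the downstream strict thresholds are applied
to. Calibration is enforced by test: on a null NB simulation (20 000
features, 6 vs 6, mean 50, dispersion 0.05) the type-I rate at nominal 0.05
must fall in [0.03, 0.08], and sensitivity at injected |log2FC| = 2
(mean 100, 3 vs 3) must exceed 0.9 under FDR < 0.05 with a fold-change
floor of 1.

Calling uses strict inequalities throughout — `padj < 0.05` and
`|log2FC| > 1` (genotype contrasts) or `> 1.5` (treatment contrasts) — so a
feature sitting exactly on a threshold is not called. Expression contrasts
deliberately use raw `p < 0.05` with no fold-change floor, preserving the
asymmetry between the DRIP and RNA analyses that the calling conventions of
the two upstream toolchains impose; the two modes are explicit in
`callDifferential()`.

# Peak validation and annotation

Significant bins become *bona fide* regions only when supported by peak
evidence from the condition in which their signal is higher: up bins are
intersected with the merged replicate peaks of the high condition (e.g. the
treated condition for treatment gains), down bins with the other side. For
the genotype contrast the two sides are the two genotypes' untreated peak
sets. Validation can only shrink call sets.

Annotation is single-label by region midpoint with precedence
promoter > TTS > gene body > intergenic. The promoter window is TSS
−1000/+100 bp and the TTS ("other") window TES −100/+1000 bp, strand-aware
and configurable; these are conventional defaults, not measured constants.
Midpoint assignment (rather than fractional overlap) guarantees one
category per region, and ties between genes are broken by smallest absolute
TSS distance then lexicographic gene id, making annotation deterministic.
Significant bins are *not* merged into wider regions before counting:
region counts are bin-granular, which is why region counts can far exceed
host-gene counts.

# Integration, perturbation and enrichment operators

A gene's R-loop direction is "accumulated" if it hosts at least one
validated accumulated region (likewise "depleted"); a gene hosting both
directions appears in both concordance rows, because region and gene counts
are otherwise not reconcilable. Concordance percentages are computed among
the DE host genes only (the pie denominators), and are reported as absent —
not zero — when no host gene is DE.

The six response groups partition the union of DE genes by per-genotype
direction; genes moving in opposite directions in the two genotypes are
quarantined in a separate discordant set rather than forced into a group,
so group sums need not equal naive per-genotype totals.

A region is *dampened* under a perturbation when its perturbed fold change
is strictly below the reference one (`lfc_pert < lfc_ref`, equivalently
`delta = lfc_ref − lfc_pert > 0`). Equality is not dampened. By default a
region absent from the perturbed table is an error; an opt-in
`assumeNull = TRUE` scores it as `lfc_pert = 0` for coverage-mismatched
inputs, and the pipeline instead restricts to regions tested in both
contrasts, which keeps the classified set well-defined without inventing
fold changes. Cross-treatment consistency tiers (significant-consistent /
nonsignificant-consistent / nonconsistent) are disjoint and exhaustive over
the reference regions present in the second table, so their fractions sum
to 1 per direction.

Enrichment is a flat hypergeometric upper tail against a user-supplied GMT
term map and explicit background, BH-adjusted within the tested terms;
term-set similarity between gene groups is the Jaccard index of their
`q < 0.05` enriched-term sets. No term-graph propagation or clustering is
attempted.

# The synthetic study and what it does (not) show

`simulationConfig()` fixes the emulated study conditions: a 2 × 1 Mb
genome at 500 bp bins, two genotypes (C control, AT mutant) crossed with
four conditions (untreated, irradiated, peroxide-treated, and irradiated
under RNase H1 overexpression), three replicates each. Baseline bin mean
λ0 = 50 with a 3× enrichment inside true R-loop regions keeps typical bins
above the count filter at realistic shallow-coverage depth; NB dispersion
0.05 matches well-behaved replicate variability; library-size factors are
uniform on [0.7, 1.4]. True regions are unions of whole bins (so truth
evaluation is exact at bin granularity), 70% placed inside genes, with
injected |log2FC| in [1.5, 3] — large effects chosen for recovery testing,
not as a claim about real effect-size distributions. The mutant genotype's
treatment log-effects are the control's scaled by the attenuation
`a = 0.4`; RNase H1 scales treatment effects by the suppression
`σ = 0.3`; the peroxide condition shares the irradiation truth with
independent counting noise (a shared damage response). A host gene of a
true region is made DE with the same sign with probability `ρ = 0.9`.
Replicate peak sets are the true footprint minus 5% false-negative
dropouts plus 5% decoys.

Randomness is organized as one labeled substream per output object, derived
from the master seed, so generating an additional output never perturbs the
others, and identical configurations are byte-identical on disk — the
determinism the acceptance checks assert.

The generator emulates count structure, not sequence: there are no reads,
no GC or mappability bias, no input-track subtraction, no strand-specific
(DRIPc-style) signal, and peak errors are interval dropouts/decoys rather
than a peak-caller's behaviour. Passing recovery tests therefore shows the
*inference machinery* is correct under the stated model; it does not show
robustness to alignment artifacts or covariate biases in real DRIP-Seq.

# Numerical choices and degenerate inputs

Tests sized for routine runs use the 2 Mb default genome (4000 bins,
24 samples), with engine calibration at 20 000 features; the full suite and
the acceptance script each complete in about a minute on one core.
Degenerate inputs are defined: empty genomes, empty region sets and empty
queries raise errors naming the problem; empty peak sets validly drop a
direction; a feature set with no all-positive row cannot be normalized and
says so; BH inputs outside [0, 1] are rejected. The interface is the R
package surface itself — `simulateStudy()` writes a complete study
directory with a ready `config.yaml`, and `runPipeline()` consumes one,
aborting with the failing stage's name on any stage error.

# Known limitations

Single-factor contrasts only (no batch covariates), no dispersion
shrinkage across features, bin-granular regions (no merging of adjacent
significant bins), single-label annotation without exon/intron or CpG
categories, and flat enrichment without term clustering. These reflect the
package's scope: the binned differential workflow and its integration
logic, kept small enough to verify end to end against ground truth.
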