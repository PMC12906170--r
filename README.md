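# rloopdiff

Differential R-loop analysis from genome-binned DRIP-Seq counts, and its
integration with differential gene expression.

R-loops — three-stranded structures of an RNA–DNA hybrid plus a displaced
single DNA strand — are measured genome-wide by DRIP-Seq (S9.6
immunoprecipitation followed by sequencing). Comparing R-loop landscapes
between genotypes or treatments (e.g. a DNA-damage–response mutant vs
control, irradiated vs untreated, with or without RNase H1 overexpression)
requires calling *accumulated* and *depleted* regions from replicated count
data, validating them against independent peak evidence, tying them to
genes, and asking whether transcription moves with them. `rloopdiff`
implements that workflow as a tested, reusable R package for epigenomics
analysts, together with a seeded synthetic-data generator with known ground
truth for end-to-end verification.

## The model

The genome is tiled into fixed-width bins (default *w* = 500 bp). Bins with
read counts > 20 in all replicates of either compared group are kept. For
kept bin *i* and sample *j*, counts are modeled as negative binomial,

&nbsp;&nbsp;&nbsp;&nbsp;K<sub>ij</sub> ~ NB(mean = s<sub>j</sub> q<sub>ig</sub>, variance = μ + α<sub>i</sub>μ²),

with median-of-ratios size factors s<sub>j</sub>, method-of-moments
dispersions α<sub>i</sub>, and per-group rates estimated by the ratio
estimator q<sub>ig</sub> = Σ<sub>j∈g</sub>K<sub>ij</sub> / Σ<sub>j∈g</sub>s<sub>j</sub>.
The Wald statistic for a contrast (A, B) uses the Fisher information
I<sub>g</sub> = Σ<sub>j∈g</sub> μ<sub>gj</sub>/(1 + α<sub>i</sub>μ<sub>gj</sub>):

&nbsp;&nbsp;&nbsp;&nbsp;z = (ln q<sub>B</sub> − ln q<sub>A</sub>) / √(1/I<sub>A</sub> + 1/I<sub>B</sub>),&nbsp;&nbsp; p = 2(1 − Φ(|z|)),

with Benjamini–Hochberg adjustment within the tested bin family.
Significant bins (FDR < 0.05 and |log2FC| > 1 for genotype contrasts, > 1.5
for treatment contrasts; strict inequalities) are retained only when they
overlap (≥ 1 bp) the merged replicate peaks of the condition in which their
signal is higher — the *bona fide* regions. Regions are annotated to genes
by midpoint with precedence promoter > TTS > gene body > intergenic.
Downstream operators quantify R-loop/expression concordance, six-group
genotype×treatment response classes, RNase H1 sensitivity (a region is
*dampened* when log2FC<sub>perturbed</sub> < log2FC<sub>reference</sub>),
three-tier cross-treatment consistency, effect-size correlation, and
hypergeometric term enrichment with Jaccard similarity of enriched-term
sets.

## Worked example

Simulate the default study (2 × 1 Mb genome, 500 bp bins, genotypes C/AT ×
conditions UT/IR/H2O2/RH.IR, 3 replicates each, attenuation a = 0.4,
suppression σ = 0.3) and run the full pipeline:

```r
library(rloopdiff)
cfg <- simulationConfig(seed = 7)
st  <- simulateStudy(cfg, dir = "study")
res <- runPipeline("study")

res$results$drip$baseline$calls
#> DifferentialCalls [baseline]: 122 up, 42 down

res$results$integration$concordance$baseline
#>             hostGenes deUp deDown notDe    pctUp   pctDown
#> accumulated        43   36      2     5 94.73684  5.263158
#> depleted           14    2     10     2 16.66667 83.333333

res$results$perturbation$attenuation$summary
#>          class   n pct
#> 1     dampened 148 100
#> 2 not_dampened   0   0

res$results$perturbation$correlation
#> r = 0.765 (p = 1.2e-29, n = 148)
```

Reading the output: the genotype contrast calls 122 accumulated and 42
depleted peak-validated bins; of the accumulated-region host genes that are
differentially expressed, 95% are upregulated (the concordance pie);
every true treatment-response region is dampened when RNase H1 suppresses
R-loop formation (σ = 0.3); and the two DNA-damage treatments, which share
the same injected truth, show strongly correlated effect sizes. All outputs
are also written as TSV under `study/out/` and listed with row counts in
`res$manifest`.

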