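Package: rloopdiff
Title: Differential R-Loop Analysis from Binned DRIP-Seq Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-binned differential R-loop (DRIP-Seq) analysis and its
    integration with differential expression. Tiles a genome into fixed-width
    bins, filters bins by replicate read counts, tests bins with a
    negative-binomial Wald engine using median-of-ratios normalization,
    validates significant bins against condition-specific peak sets
    (direction-aware), annotates validated regions to gene models
    (promoter/gene body/TTS/intergenic), joins R-loop calls with differential
    expression (concordance summaries, genotype-by-treatment response groups,
    Venn partitions), classifies RNase H1 sensitivity (dampened vs increased
    regions and their host genes), measures cross-treatment consistency and
    effect correlation, and performs hypergeometric term enrichment with
    Jaccard similarity between enriched-term sets. Includes a seeded
    synthetic-data generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DifferentialPeakCalling, Sequencing, Coverage
RoxygenNote: 7.3.3
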