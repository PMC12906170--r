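# small, fast configuration reused across blocks
quick_config <- function(...) {
  defaults <- list(chromLengths = c(c1 = 2e5, c2 = 2e5), nGenes = 40L,
                   nBaselineUp = 10L, nBaselineDown = 4L,
                   nTreatmentUp = 12L, nTreatmentDown = 6L,
                   nFreeDeGenes = 8L, seed = 21L)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

test_that("attenuation and coupling parameters shape the ground truth exactly", {
  t0 <- simulateTruth(quick_config(attenuation = 0))
  expect_true(all(mcols(t0$truth$regions$AT.IR)$lfc == 0))

  t1 <- simulateTruth(quick_config(attenuation = 1))
  expect_identical(mcols(t1$truth$regions$AT.IR)$lfc,
                   mcols(t1$truth$regions$C.IR)$lfc)

  # rho = 1: every true-region host gene is DE with matching sign
  tc <- simulateTruth(quick_config(rho = 1))
  reg <- tc$truth$regions$C.IR
  hit <- findOverlaps(reg, tc$genes, ignore.strand = TRUE)
  hosts <- mcols(tc$genes)$gene_id[subjectHits(hit)]
  signs <- sign(mcols(reg)$lfc[queryHits(hit)])
  de <- tc$truth$genes$C.IR
  expect_true(all(hosts %in% names(de)))
  # sign matches wherever a host gene's regions agree on direction
  perGene <- tapply(signs, hosts, unique)
  clear <- names(perGene)[lengths(perGene) == 1L]
  expect_true(all(sign(de[clear]) == unlist(perGene[clear])))

  # suppression scales the RNase H1 contrast truth
  expect_equal(mcols(tc$truth$regions$C.RH.IR)$lfc,
               0.3 * mcols(tc$truth$regions$C.IR)$lfc)

  # true regions sit on bin boundaries
  expect_true(all((start(reg) - 1L) %% 500 == 0))

  # determinism
  expect_identical(simulateTruth(quick_config()), simulateTruth(quick_config()))

  expect_error(simulateTruth(quick_config(nTreatmentUp = 100000L)),
               "exceed genome capacity")
})

test_that("bin counts follow the configured negative-binomial construction", {
  # alpha = 0, no effects, unit size factors: Poisson(lambda0)
  cfg <- quick_config(alphaTrue = 0, lambda0 = 30, enrichment = 1,
                      sizeFactorRange = c(1, 1),
                      nBaselineUp = 0L, nBaselineDown = 0L,
                      nTreatmentUp = 0L, nTreatmentDown = 0L)
  sim <- simulateTruth(cfg)
  design <- studyDesign(cfg, conditions = c("UT", "IR"))
  se <- simulateBinCounts(sim$genome, sim$truth, design, cfg)
  k <- assay(se)
  N <- length(k)
  expect_lte(abs(mean(k) - 30), 3 * sqrt(30 / N))
  expect_equal(mean(colMeans(k) / 30), 1, tolerance = 0.05)

  # injected effect: treated/untreated group mean ratio tracks 2^lfc
  cfg2 <- quick_config(alphaTrue = 0.02, sizeFactorRange = c(1, 1),
                       lambda0 = 200, repsPerGroup = 6L)
  sim2 <- simulateTruth(cfg2)
  design2 <- studyDesign(cfg2, genotypes = "C", conditions = c("UT", "IR"))
  se2 <- simulateBinCounts(sim2$genome, sim2$truth, design2, cfg2)
  bins <- rowRanges(se2)
  reg <- sim2$truth$regions$C.IR
  hit <- findOverlaps(bins, reg, ignore.strand = TRUE)
  i <- queryHits(hit)[1]
  lfc <- mcols(reg)$lfc[subjectHits(hit)[1]]
  g <- colData(se2)$condition
  ratio <- mean(assay(se2)[i, g == "IR"]) / mean(assay(se2)[i, g == "UT"])
  expect_equal(log2(ratio), lfc, tolerance = 0.45)

  # determinism
  se2b <- simulateBinCounts(sim2$genome, sim2$truth, design2, cfg2)
  expect_identical(assay(se2), assay(se2b))
})

test_that("peak simulation respects false-negative and false-positive rates", {
  cfg <- quick_config(peakFN = 0, peakFP = 0)
  sim <- simulateTruth(cfg)
  pk <- simulatePeaks(sim$genome, sim$truth, cfg, keys = c("C.UT", "AT.UT"))
  fp <- sim$truth$footprint
  for (rep in pk$C.UT)
    expect_true(all(rep == fp))

  cfgFN <- quick_config(peakFN = 1, peakFP = 0)
  simFN <- simulateTruth(cfgFN)
  pkFN <- simulatePeaks(simFN$genome, simFN$truth, cfgFN, keys = "C.UT")
  expect_true(all(lengths(pkFN$C.UT) == 0L))

  cfgFP <- quick_config(peakFN = 0, peakFP = 0.1)
  simFP <- simulateTruth(cfgFP)
  pkFP <- simulatePeaks(simFP$genome, simFP$truth, cfgFP, keys = "C.UT")
  for (rep in pkFP$C.UT) {
    decoys <- rep[!overlapsAny(rep, simFP$truth$footprint)]
    expect_gte(length(decoys), 0)
    expect_lte(length(decoys), length(simFP$truth$footprint))
    # every non-decoy peak is exactly a footprint interval
    hits <- rep[overlapsAny(rep, simFP$truth$footprint)]
    expect_true(all(overlapsAny(hits, simFP$truth$footprint, type = "equal")))
  }
})

test_that("expression counts carry the injected gene effects", {
  cfg <- quick_config(alphaTrue = 0.02, sizeFactorRange = c(1, 1),
                      repsPerGroup = 8L, rho = 1)
  sim <- simulateTruth(cfg)
  design <- studyDesign(cfg, genotypes = "C", conditions = c("UT", "IR"))
  se <- simulateExpressionCounts(sim$genes, sim$truth, design, cfg)
  de <- sim$truth$genes$C.IR
  g <- colData(se)$condition
  gene <- names(de)[which.max(abs(de))]
  ratio <- mean(assay(se)[gene, g == "IR"]) / mean(assay(se)[gene, g == "UT"])
  expect_equal(log2(ratio), unname(de[gene]), tolerance = 0.5)

  # no-effect genes: groupwise mean ratio near 1
  null <- setdiff(rownames(se), names(de))
  ratios <- rowMeans(assay(se)[null, g == "IR"]) /
    rowMeans(assay(se)[null, g == "UT"])
  expect_equal(median(log2(ratios)), 0, tolerance = 0.2)

  expect_identical(assay(se),
                   assay(simulateExpressionCounts(sim$genes, sim$truth,
                                                  design, cfg)))
})

test_that("fragment simulation inverts exactly under the midpoint rule", {
  genome <- genomeDef(c(c1 = 50000L))
  bins <- makeBins(genome, 500L)

  mcols(bins)$mean <- 0
  expect_length(simulateFragments(bins, seed = 2), 0L)

  mcols(bins)$mean <- 4
  frags <- simulateFragments(bins, fragLen = 300L, seed = 2)
  counts <- countFragmentsIntoBins(frags, bins)
  expect_equal(sum(counts), length(frags))
  # per-bin counts equal the generating Poisson draws: re-simulating with the
  # same seed and re-counting must agree bin by bin
  frags2 <- simulateFragments(bins, fragLen = 300L, seed = 2)
  expect_identical(counts, countFragmentsIntoBins(frags2, bins))

  # edge sweep: fragments spanning bin boundaries land in exactly one bin
  edge <- bins[1:2]
  mcols(edge)$mean <- c(50, 50)
  fr <- simulateFragments(edge, fragLen = 300L, seed = 3)
  ct <- countFragmentsIntoBins(fr, bins)
  expect_equal(sum(ct), length(fr))
  expect_equal(sum(ct[1:2]), length(fr))   # none drift beyond the two bins
})
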