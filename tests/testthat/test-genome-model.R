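test_that("binning tiles each chromosome without gaps or overlaps", {
  bins <- makeBins(genomeDef(c(c1 = 1250L)), 500L)
  expect_equal(start(bins) - 1L, c(0L, 500L, 1000L))
  expect_equal(end(bins), c(500L, 1000L, 1250L))

  one <- makeBins(genomeDef(c(c1 = 500L)), 500L)
  expect_length(one, 1L)
  expect_equal(c(start(one) - 1L, end(one)), c(0L, 500L))

  two <- makeBins(genomeDef(c(c1 = 1000L, c2 = 700L)), 500L)
  expect_length(two, 4L)
  expect_equal(mcols(two)$index, 1:4)
  expect_equal(as.character(seqnames(two))[4L], "c2")
  expect_equal(c(start(two)[4L] - 1L, end(two)[4L]), c(500L, 700L))

  # per-base partition oracle on an awkward genome
  lens <- c(a = 1237L, b = 499L, c = 500L, d = 2000L)
  bins <- makeBins(genomeDef(lens), 500L)
  expect_equal(sum(width(bins)), sum(lens))
  mask <- coverage_mask(bins, as.list(lens))
  expect_true(all(unlist(mask)))                     # no gaps
  expect_equal(sum(lengths(mask)), sum(width(bins))) # no overlaps

  expect_error(makeBins(genomeDef(c(c1 = 100L)), 0L), "width")
  expect_error(genomeDef(integer()), "no chromosomes")
})

test_that("interval intersection keeps whole queries on >= 1 bp overlap", {
  q <- gr0("c1", 1000, 1500)
  expect_length(intersectAny(q, gr0("c1", 1400, 2000)), 1L)
  expect_identical(start(intersectAny(q, gr0("c1", 1400, 2000))), start(q))
  # half-open abutment is not overlap
  expect_length(intersectAny(q, gr0("c1", 1500, 2000)), 0L)
  expect_length(intersectAny(GRanges(), q), 0L)
})

test_that("intersection and merge agree with per-base mask oracles", {
  set.seed(42)
  lens <- list(c1 = 10000L, c2 = 10000L)
  for (rep in 1:3) {
    q <- random_intervals(200, lens)
    s <- random_intervals(200, lens)
    got <- intersectAny(q, s)
    want <- oracle_intersect(q, s, lens)
    expect_equal(sort(got), sort(want))

    x <- random_intervals(500, lens, maxWidth = 300)
    merged <- mergeIntervals(x)
    maskIn <- coverage_mask(x, lens)
    maskOut <- coverage_mask(merged, lens)
    expect_identical(maskOut, maskIn)                       # same coverage
    expect_equal(length(merged), sum(vapply(maskIn, mask_runs, 1L)))  # minimal
    expect_false(is.unsorted(start(merged)[as.character(seqnames(merged)) == "c1"]))
  }
  # abutting intervals merge (bedtools merge distance-0 behaviour)
  m <- mergeIntervals(c(gr0("c1", 0, 100), gr0("c1", 100, 200)))
  expect_length(m, 1L)
  expect_equal(c(start(m) - 1L, end(m)), c(0L, 200L))
  m2 <- mergeIntervals(c(gr0("c1", 0, 100), gr0("c1", 50, 150)))
  expect_equal(c(start(m2) - 1L, end(m2)), c(0L, 150L))
})

test_that("region annotation follows midpoint precedence and is deterministic", {
  idx <- tiny_index()   # g1 (+) span [2000,5000), g2 (-) span [12000,15000)
  # midpoint 1650 falls in the + promoter [1000, 2100)
  ann <- annotateRegions(gr0("c1", 1400, 1900), idx)
  expect_equal(ann$category, "promoter")
  expect_equal(ann$gene_id, "g1")
  expect_equal(ann$tss_distance, -350)

  expect_equal(annotateRegions(gr0("c1", 3000, 3500), idx)$category, "gene_body")
  inter <- annotateRegions(gr0("c1", 8000, 8500), idx)
  expect_equal(inter$category, "intergenic")
  expect_true(is.na(inter$gene_id))

  # minus-strand promoter sits right of the gene end
  annm <- annotateRegions(gr0("c1", 15200, 15300), idx)
  expect_equal(annm$category, "promoter")
  expect_equal(annm$gene_id, "g2")

  # TTS window beats gene body, promoter beats TTS
  tts <- annotateRegions(gr0("c1", 4950, 4960), idx)   # just inside g1 end
  expect_equal(tts$category, "tts_other")

  # determinism incl. tie-breaks
  r <- gr0("c1", c(1400, 3000, 8000), c(1900, 3500, 8500))
  expect_identical(annotateRegions(r, idx), annotateRegions(r, idx))

  far <- suppressWarnings(gr0("c1", 25000, 25100,
                              genome = genomeDef(c(c1 = 20000L))))
  expect_error(annotateRegions(far, idx), "outside genome")
})

test_that("annotation distributions are exact fractions that sum to one", {
  d <- annotationDistribution(c(rep("gene_body", 3), "intergenic"))
  expect_equal(unname(d$fractions["gene_body"]), 0.75)
  expect_equal(unname(d$fractions["intergenic"]), 0.25)
  expect_equal(sum(d$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(annotationDistribution(rep("promoter", 5))$fractions["promoter"]), 1)
  expect_error(annotationDistribution(character()), "no regions")

  set.seed(7)
  idx <- tiny_index()
  regions <- random_intervals(100, list(c1 = 20000L), maxWidth = 200)
  ann <- annotateRegions(regions, idx)
  d <- annotationDistribution(ann)
  recount <- table(factor(ann$category, names(d$counts)))
  expect_equal(unname(d$counts), as.integer(recount))
})

test_that("metagene profiles match a naive per-region resampling", {
  genome <- genomeDef(c(c1 = 50000L))
  bins <- makeBins(genome, 500L)

  mcols(bins)$score <- 3.5
  regions <- gr0("c1", c(10000, 30000), c(12000, 33000), genome)
  prof <- metageneProfile(bins, regions, bodyPoints = 10, flankBp = 1000,
                          flankPoints = 5)
  expect_equal(prof, rep(3.5, 20))

  # signal only inside regions: flanks must be zero
  mcols(bins)$score <- as.numeric(overlapsAny(bins, regions))
  prof <- metageneProfile(bins, regions, bodyPoints = 4, flankBp = 2000,
                          flankPoints = 3)
  expect_equal(prof[1:3], c(0, 0, 0))        # upstream flank points
  expect_equal(prof[4:7], rep(1, 4))         # body fully covered

  set.seed(11)
  mcols(bins)$score <- runif(length(bins))
  regions <- random_intervals(10, list(c1 = 50000L), maxWidth = 3000)
  got <- metageneProfile(bins, regions, bodyPoints = 7, flankBp = 1500,
                         flankPoints = 4)
  want <- oracle_metagene(bins, regions, 7, 1500, 4)
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(metageneProfile(bins, regions, bodyPoints = 0), "bodyPoints")
  expect_error(metageneProfile(bins, GRanges()), "nonempty")
})
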