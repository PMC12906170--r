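#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: two genotypes
#' (`C`, control; `AT`, mutant) crossed with four treatments (`UT` untreated,
#' `IR` irradiated, `H2O2` peroxide-treated, `RH.IR` irradiated under RNase H1
#' overexpression), three replicates each. True differential R-loop regions
#' are unions of whole bins with injected log2 fold changes; the mutant
#' genotype's treatment effects are scaled by the attenuation factor `a`, and
#' RNase H1 scales treatment effects by the suppression factor `sigma`.
#'
#' @param chromLengths genome spec (named lengths, bp).
#' @param binWidth bin width in bp.
#' @param nGenes number of non-overlapping gene models to place.
#' @param geneWidthRange min/max gene length (bp).
#' @param repsPerGroup replicates per genotype x condition group.
#' @param lambda0 baseline mean bin count.
#' @param enrichment multiplier on `lambda0` inside true R-loop regions.
#' @param alphaTrue NB dispersion (`var = mu + alpha mu^2`).
#' @param sizeFactorRange range of per-sample library-size factors.
#' @param nBaselineUp,nBaselineDown true accumulated/depleted region counts
#'   for the genotype (AT vs C, untreated) contrast.
#' @param nTreatmentUp,nTreatmentDown true region counts for the treatment
#'   (IR vs UT) contrast.
#' @param regionBins bins per true region.
#' @param lfcRange magnitude range of injected |log2FC| for regions.
#' @param fracIntragenic fraction of true regions placed inside genes.
#' @param rho coupling probability: chance a true region's host gene is DE in
#'   the same direction.
#' @param attenuation `a` in `[0, 1]`: scales the AT genotype's treatment
#'   log-effects.
#' @param suppression `sigma` in `[0, 1]`: scales IR log-effects under RNase
#'   H1 overexpression.
#' @param peakFN,peakFP per-replicate peak false-negative dropout rate and
#'   false-positive decoy rate.
#' @param exprMean mean expression baseline per gene (lognormal around it).
#' @param exprLfcRange magnitude range of injected gene |log2FC|.
#' @param nFreeDeGenes additional DE genes not coupled to any region.
#' @param seed master seed; every output object draws from a labeled
#'   substream derived from it.
#' @return list of validated settings (class `rloop_sim_config`).
#' @export
simulationConfig <- function(chromLengths = c(chr1 = 1e6, chr2 = 1e6),
                             binWidth = 500L,
                             nGenes = 200L,
                             geneWidthRange = c(2000L, 6000L),
                             repsPerGroup = 3L,
                             lambda0 = 50,
                             enrichment = 3,
                             alphaTrue = 0.05,
                             sizeFactorRange = c(0.7, 1.4),
                             nBaselineUp = 60L, nBaselineDown = 20L,
                             nTreatmentUp = 80L, nTreatmentDown = 40L,
                             regionBins = 2L,
                             lfcRange = c(1.5, 3),
                             fracIntragenic = 0.7,
                             rho = 0.9,
                             attenuation = 0.4,
                             suppression = 0.3,
                             peakFN = 0.05, peakFP = 0.05,
                             exprMean = 100,
                             exprLfcRange = c(1, 2.5),
                             nFreeDeGenes = 40L,
                             seed = 1L) {
  cfg <- list(chromLengths = chromLengths, binWidth = as.integer(binWidth),
              nGenes = as.integer(nGenes), geneWidthRange = geneWidthRange,
              repsPerGroup = as.integer(repsPerGroup), lambda0 = lambda0,
              enrichment = enrichment, alphaTrue = alphaTrue,
              sizeFactorRange = sizeFactorRange,
              nBaselineUp = nBaselineUp, nBaselineDown = nBaselineDown,
              nTreatmentUp = nTreatmentUp, nTreatmentDown = nTreatmentDown,
              regionBins = as.integer(regionBins), lfcRange = lfcRange,
              fracIntragenic = fracIntragenic, rho = rho,
              attenuation = attenuation, suppression = suppression,
              peakFN = peakFN, peakFP = peakFP, exprMean = exprMean,
              exprLfcRange = exprLfcRange,
              nFreeDeGenes = as.integer(nFreeDeGenes), seed = as.integer(seed))
  rates <- c(cfg$fracIntragenic, cfg$rho, cfg$attenuation, cfg$suppression,
             cfg$peakFN, cfg$peakFP)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$lambda0 <= 0) stop("lambda0 must be > 0")
  if (cfg$alphaTrue < 0) stop("alphaTrue must be >= 0")
  if (any(!is.finite(cfg$lfcRange))) stop("effect ranges must be finite")
  class(cfg) <- "rloop_sim_config"
  cfg
}

# Labeled substream: deterministic seed per output object so adding one
# output never perturbs another. FNV-style string hash folded into [0, 2^31).
substream_seed <- function(seed, label) {
  h <- 2166136261
  for (b in utf8ToInt(label)) h <- ((h * 16777619) %% 2147483647 + b) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, label))
  expr
}

#' The full-factorial study design
#'
#' @param config a [simulationConfig()].
#' @param genotypes,conditions levels to cross.
#' @return data.frame with columns `sample`, `genotype`, `condition`,
#'   `replicate`, `group` (`genotype.condition`).
#' @export
studyDesign <- function(config,
                        genotypes = c("C", "AT"),
                        conditions = c("UT", "IR", "H2O2", "RH.IR")) {
  d <- expand.grid(replicate = seq_len(config$repsPerGroup),
                   condition = conditions, genotype = genotypes,
                   stringsAsFactors = FALSE)
  d$group <- paste(d$genotype, d$condition, sep = ".")
  d$sample <- paste(d$group, d$replicate, sep = "_r")
  d[, c("sample", "genotype", "condition", "replicate", "group")]
}

sample_lfc <- function(n_up, n_down, range) {
  mag <- runif(n_up + n_down, range[1L], range[2L])
  mag * rep(c(1, -1), c(n_up, n_down))
}

#' Simulate genome, gene models and ground truth
#'
#' Places non-overlapping genes uniformly, then samples bin-aligned true
#' regions (a configured fraction inside genes) for the genotype (baseline)
#' and treatment contrasts with injected log2 fold changes drawn from
#' `lfcRange`. The mutant genotype's treatment effects are exactly
#' `attenuation` times the control's; RNase H1 effects are `suppression`
#' times the IR effects; the peroxide treatment shares the IR truth (a common
#' damage response with independent counting noise). A `rho` fraction of
#' region host genes is made DE with the same sign; `nFreeDeGenes` further
#' DE genes are region-independent.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` (Seqinfo), `genes` (GRanges with `gene_id`),
#'   and `truth` (list: `regions` per contrast as GRanges with `lfc`,
#'   `footprint`, `genes` per contrast as named lfc vectors, and the echoed
#'   parameters).
#' @export
simulateTruth <- function(config) {
  genome <- genomeDef(config$chromLengths)
  bins <- makeBins(genome, config$binWidth)

  genes <- with_substream(config$seed, "genes", {
    sl <- GenomeInfoDb::seqlengths(genome)
    chs <- character(0); ss <- integer(0); es <- integer(0)
    tries <- 0L
    while (length(chs) < config$nGenes && tries < config$nGenes * 50L) {
      tries <- tries + 1L
      chr <- sample(names(sl), 1L)
      w <- round(runif(1L, config$geneWidthRange[1L], config$geneWidthRange[2L]))
      if (w >= sl[chr]) next
      s <- floor(runif(1L, 1, sl[chr] - w))
      e <- s + w - 1L
      # keep genes separated so promoter/TTS windows rarely collide
      same <- chs == chr
      if (!any(same & ss <= e + 2000L & es >= s - 2000L)) {
        chs <- c(chs, chr); ss <- c(ss, as.integer(s)); es <- c(es, as.integer(e))
      }
    }
    placed <- GenomicRanges::GRanges(
      chs, IRanges::IRanges(ss, es),
      strand = sample(c("+", "-"), length(chs), replace = TRUE),
      seqinfo = genome)
    placed <- GenomicRanges::sort(placed, ignore.strand = TRUE)
    S4Vectors::mcols(placed)$gene_id <- sprintf("g%04d", seq_along(placed))
    placed
  })

  pick_regions <- function(nUp, nDown, label, exclude = NULL) {
    with_substream(config$seed, label, {
      nReg <- nUp + nDown
      intra <- IRanges::overlapsAny(bins, genes, ignore.strand = TRUE)
      # candidate starts: runs of regionBins consecutive bins on one chrom
      k <- config$regionBins
      okStart <- seq_len(length(bins) - k + 1L)
      sameChr <- as.character(GenomicRanges::seqnames(bins))
      okStart <- okStart[sameChr[okStart] == sameChr[okStart + k - 1L]]
      wantIntra <- rbinom(1L, nReg, config$fracIntragenic)
      startIsIntra <- intra[okStart]
      used <- rep(FALSE, length(bins))
      if (!is.null(exclude))
        used[IRanges::overlapsAny(bins, exclude, ignore.strand = TRUE)] <- TRUE
      draw <- function(pool, n) {
        out <- integer(0)
        pool <- sample(pool)
        for (s in pool) {
          if (length(out) >= n) break
          if (!any(used[s:(s + k - 1L)])) {
            out <- c(out, s)
            used[s:(s + k - 1L)] <<- TRUE
          }
        }
        out
      }
      sIntra <- draw(okStart[startIsIntra], wantIntra)
      sInter <- draw(okStart[!startIsIntra], nReg - length(sIntra))
      starts <- c(sIntra, sInter)
      if (length(starts) < nReg)
        stop("requested regions exceed genome capacity")
      reg <- GenomicRanges::GRanges(
        sameChr[starts],
        IRanges::IRanges(GenomicRanges::start(bins)[starts],
                         GenomicRanges::end(bins)[starts + k - 1L]),
        seqinfo = genome)
      reg <- reg[sample(length(reg))]    # shuffle before sign assignment
      S4Vectors::mcols(reg)$lfc <- sample_lfc(nUp, nDown, config$lfcRange)
      names(reg) <- regionId(reg)
      GenomicRanges::sort(reg)
    })
  }

  baseline <- pick_regions(config$nBaselineUp, config$nBaselineDown,
                           "regions.baseline")
  treatment <- pick_regions(config$nTreatmentUp, config$nTreatmentDown,
                            "regions.treatment", exclude = baseline)

  couple_genes <- function(reg, label) {
    with_substream(config$seed, label, {
      hit <- GenomicRanges::findOverlaps(reg, genes, ignore.strand = TRUE)
      host <- tapply(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit),
                     function(i) i[1L])
      lfcs <- S4Vectors::mcols(reg)$lfc[as.integer(names(host))]
      gid <- S4Vectors::mcols(genes)$gene_id[unlist(host)]
      keepFirst <- !duplicated(gid)
      gid <- gid[keepFirst]; lfcs <- lfcs[keepFirst]
      coupled <- runif(length(gid)) < config$rho
      mag <- runif(sum(coupled), config$exprLfcRange[1L], config$exprLfcRange[2L])
      de <- setNames(mag * sign(lfcs[coupled]), gid[coupled])
      free <- setdiff(S4Vectors::mcols(genes)$gene_id, gid)
      nFree <- min(config$nFreeDeGenes, length(free))
      freeId <- sample(free, nFree)
      freeLfc <- setNames(
        runif(nFree, config$exprLfcRange[1L], config$exprLfcRange[2L]) *
          sample(c(1, -1), nFree, replace = TRUE), freeId)
      c(de, freeLfc)
    })
  }

  genesBaseline <- couple_genes(baseline, "genes.baseline")
  genesTreatment <- couple_genes(treatment, "genes.treatment")

  truth <- list(
    regions = list(
      baseline = baseline,                     # AT.UT vs C.UT
      C.IR = treatment,                        # IR vs UT in control
      AT.IR = scale_lfc(treatment, config$attenuation),
      C.H2O2 = treatment,
      AT.H2O2 = scale_lfc(treatment, config$attenuation),
      C.RH.IR = scale_lfc(treatment, config$suppression)),
    footprint = mergeIntervals(c(GenomicRanges::granges(baseline),
                                 GenomicRanges::granges(treatment))),
    genes = list(
      baseline = genesBaseline,
      C.IR = genesTreatment,
      AT.IR = genesTreatment * config$attenuation),
    params = list(attenuation = config$attenuation,
                  suppression = config$suppression,
                  rho = config$rho, alphaTrue = config$alphaTrue))
  list(genome = genome, genes = genes, truth = truth)
}

scale_lfc <- function(reg, f) {
  S4Vectors::mcols(reg)$lfc <- S4Vectors::mcols(reg)$lfc * f
  reg
}

# per-bin injected log2FC for one sample state (genotype, condition)
bin_delta <- function(bins, truth, genotype, condition, config) {
  delta <- numeric(length(bins))
  add <- function(reg) {
    hit <- GenomicRanges::findOverlaps(bins, reg, ignore.strand = TRUE)
    delta[S4Vectors::queryHits(hit)] <<- delta[S4Vectors::queryHits(hit)] +
      S4Vectors::mcols(reg)$lfc[S4Vectors::subjectHits(hit)]
  }
  if (genotype == "AT") add(truth$regions$baseline)
  condScale <- switch(condition, UT = 0, IR = 1, H2O2 = 1,
                      RH.IR = config$suppression)
  treatScale <- if (genotype == "AT") config$attenuation else 1
  if (condScale != 0) {
    reg <- truth$regions$C.IR
    S4Vectors::mcols(reg)$lfc <- S4Vectors::mcols(reg)$lfc *
      condScale * treatScale
    add(reg)
  }
  delta
}

#' Simulate DRIP-Seq bin counts
#'
#' Counts are NB draws with mean `s_j * lambda_i * 2^Delta_ij`, where
#' `lambda_i` is `lambda0 * enrichment` inside the true R-loop footprint and
#' `lambda0` elsewhere, `Delta_ij` is the injected log2FC applicable to
#' sample `j`'s genotype/condition, and `s_j` is the sample's library-size
#' factor drawn from `sizeFactorRange`. `alphaTrue = 0` gives Poisson counts.
#'
#' @param genome Seqinfo from [simulateTruth()].
#' @param truth the truth component of [simulateTruth()].
#' @param design data.frame from [studyDesign()].
#' @param config the [simulationConfig()].
#' @return `RangedSummarizedExperiment` with assay `counts`, `rowRanges` =
#'   bins, `colData` = design.
#' @export
simulateBinCounts <- function(genome, truth, design, config) {
  if (any(table(design$group) < 2L)) stop("need >= 2 samples per group")
  bins <- makeBins(genome, config$binWidth)
  lam <- rep(config$lambda0, length(bins))
  lam[IRanges::overlapsAny(bins, truth$footprint, ignore.strand = TRUE)] <-
    config$lambda0 * config$enrichment

  sf <- with_substream(config$seed, "sizefactors.bins",
    runif(nrow(design), config$sizeFactorRange[1L], config$sizeFactorRange[2L]))

  states <- unique(design[, c("genotype", "condition")])
  dmat <- matrix(0, length(bins), nrow(design))
  for (i in seq_len(nrow(states))) {
    d <- bin_delta(bins, truth, states$genotype[i], states$condition[i], config)
    cols <- design$genotype == states$genotype[i] &
      design$condition == states$condition[i]
    dmat[, cols] <- d
  }
  mu <- sweep(2^dmat * lam, 2L, sf, "*")
  counts <- with_substream(config$seed, "counts.bins", {
    k <- if (config$alphaTrue > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$alphaTrue)
    else rpois(length(mu), mu)
    matrix(k, nrow(mu), ncol(mu))
  })
  dimnames(counts) <- list(names(bins), design$sample)
  cd <- S4Vectors::DataFrame(design, row.names = design$sample)
  cd$sizeFactorTrue <- sf
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = bins, colData = cd)
}

#' Simulate replicate peak sets
#'
#' Each replicate's peaks are the true R-loop footprint intervals minus
#' false-negative dropouts (each interval dropped with probability `peakFN`)
#' plus false-positive decoys (count `Binomial(n_true, peakFP)`, one bin wide,
#' never overlapping the footprint).
#'
#' @inheritParams simulateBinCounts
#' @param keys group keys to generate peaks for (default all design groups).
#' @return named list (one entry per key) of lists of replicate `GRanges`.
#' @export
simulatePeaks <- function(genome, truth, config,
                          keys = as.vector(outer(c("C", "AT"),
                                c("UT", "IR", "H2O2", "RH.IR"),
                                paste, sep = "."))) {
  bins <- makeBins(genome, config$binWidth)
  fp <- truth$footprint
  decoyPool <- bins[!IRanges::overlapsAny(bins, fp, ignore.strand = TRUE)]
  with_substream(config$seed, "peaks", {
    out <- lapply(keys, function(key) {
      lapply(seq_len(config$repsPerGroup), function(r) {
        keep <- runif(length(fp)) >= config$peakFN
        nDecoy <- rbinom(1L, length(fp), config$peakFP)
        decoys <- decoyPool[sample(length(decoyPool), min(nDecoy, length(decoyPool)))]
        GenomicRanges::sort(c(GenomicRanges::granges(fp[keep]),
                              GenomicRanges::granges(decoys)))
      })
    })
    names(out) <- keys
    out
  })
}

#' Merge replicate peak sets into a condition-level peak library
#'
#' @param peaks nested list from [simulatePeaks()] (or read from BED files):
#'   key -> list of replicate `GRanges`.
#' @return named list of merged, sorted, non-overlapping `GRanges`.
#' @export
mergePeakLibrary <- function(peaks) {
  lapply(peaks, function(reps)
    mergeIntervals(do.call(c, lapply(reps, GenomicRanges::granges))))
}

#' Simulate RNA-Seq gene counts
#'
#' Gene-level analogue of [simulateBinCounts()]: lognormal per-gene baselines
#' around `exprMean`, injected `truth$genes` effects per contrast state
#' (genotype effects for AT samples, treatment effects for treated samples,
#' attenuated in AT), NB noise with `alphaTrue`.
#'
#' @inheritParams simulateBinCounts
#' @param genes `GRanges` with `gene_id`, from [simulateTruth()].
#' @return `SummarizedExperiment` with assay `counts` (genes x samples).
#' @export
simulateExpressionCounts <- function(genes, truth, design, config) {
  gid <- S4Vectors::mcols(genes)$gene_id
  base <- with_substream(config$seed, "expr.baseline",
    rlnorm(length(gid), log(config$exprMean), 0.4))
  sf <- with_substream(config$seed, "sizefactors.expr",
    runif(nrow(design), config$sizeFactorRange[1L], config$sizeFactorRange[2L]))

  gene_delta <- function(genotype, condition) {
    d <- numeric(length(gid))
    add <- function(v, scale = 1) {
      i <- match(names(v), gid)
      d[i] <<- d[i] + v * scale
    }
    if (genotype == "AT") add(truth$genes$baseline)
    if (condition %in% c("IR", "H2O2", "RH.IR")) {
      if (genotype == "AT") add(truth$genes$AT.IR) else add(truth$genes$C.IR)
    }
    d
  }
  states <- unique(design[, c("genotype", "condition")])
  dmat <- matrix(0, length(gid), nrow(design))
  for (i in seq_len(nrow(states))) {
    cols <- design$genotype == states$genotype[i] &
      design$condition == states$condition[i]
    dmat[, cols] <- gene_delta(states$genotype[i], states$condition[i])
  }
  mu <- sweep(2^dmat * base, 2L, sf, "*")
  counts <- with_substream(config$seed, "counts.expr", {
    k <- if (config$alphaTrue > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$alphaTrue)
    else rpois(length(mu), mu)
    matrix(k, nrow(mu), ncol(mu))
  })
  dimnames(counts) <- list(gid, design$sample)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = genes,
    colData = S4Vectors::DataFrame(design, row.names = design$sample))
}

#' Simulate sequencing fragments from per-bin means
#'
#' Draws `Poisson(mean)` fragments per bin with midpoints uniform in the bin
#' and a fixed fragment length; counting the fragments back into the bins by
#' the midpoint rule recovers the Poisson draws exactly (fragments are
#' shifted, never truncated, at chromosome edges so midpoints stay put except
#' within `fragLen/2` of an edge).
#'
#' @param bins `GRanges` bins with numeric `mean` metadata column.
#' @param fragLen fragment length in bp.
#' @param seed integer seed.
#' @return `GRanges` of fragments.
#' @export
simulateFragments <- function(bins, fragLen = 300L, seed = 1L) {
  mu <- S4Vectors::mcols(bins)$mean
  if (is.null(mu)) stop("bins must carry a 'mean' column")
  if (any(mu < 0)) stop("means must be >= 0")
  with_substream(seed, "fragments", {
    n <- rpois(length(bins), mu)
    if (sum(n) == 0L)
      return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(bins)))
    i <- rep(seq_along(bins), n)
    s0 <- GenomicRanges::start(bins)[i] - 1L
    e0 <- GenomicRanges::end(bins)[i]
    mid0 <- s0 + floor(runif(length(i)) * (e0 - s0))
    h <- fragLen %/% 2L
    fs0 <- mid0 - h
    sl <- GenomeInfoDb::seqlengths(bins)[as.character(
      GenomicRanges::seqnames(bins))][i]
    fs0 <- pmax(0L, pmin(fs0, sl - fragLen))
    GenomicRanges::GRanges(GenomicRanges::seqnames(bins)[i],
                           IRanges::IRanges(fs0 + 1L, fs0 + fragLen),
                           seqinfo = GenomeInfoDb::seqinfo(bins))
  })
}
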