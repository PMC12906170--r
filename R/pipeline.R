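#' Write a complete synthetic study to disk
#'
#' Generates genome, gene models, ground truth, DRIP bin counts, expression
#' counts, replicate peak sets and a term annotation, and writes them in the
#' package's on-disk formats (TSV/BED/GMT) together with a ready-to-run
#' pipeline configuration (`config.yaml`). Fully reproducible from the
#' config seed.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with `dir`, the written `paths`, and the
#'   in-memory `data` (genome, genes, truth, bin and expression
#'   `SummarizedExperiment`s, peak list, terms).
#' @export
simulateStudy <- function(config = simulationConfig(), dir = tempfile("study")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)

  sim <- simulateTruth(config)
  design <- studyDesign(config)
  binSE <- simulateBinCounts(sim$genome, sim$truth, design, config)
  exprSE <- simulateExpressionCounts(sim$genes, sim$truth, design, config)
  peaks <- simulatePeaks(sim$genome, sim$truth, config)
  terms <- simulateTerms(sim$genes, sim$truth, config)

  p <- list(genome = file.path(dir, "genome.tsv"),
            bin_counts = file.path(dir, "counts_bins.tsv"),
            expression_counts = file.path(dir, "counts_genes.tsv"),
            design = file.path(dir, "design.tsv"),
            genes = file.path(dir, "genes.bed"),
            peaks_dir = file.path(dir, "peaks"),
            gmt = file.path(dir, "terms.gmt"),
            truth_regions = file.path(dir, "truth_regions.tsv"),
            truth_genes = file.path(dir, "truth_genes.tsv"),
            config = file.path(dir, "config.yaml"))

  writeGenomeTsv(sim$genome, p$genome)
  writeCountsTsv(SummarizedExperiment::assay(binSE), p$bin_counts)
  writeCountsTsv(SummarizedExperiment::assay(exprSE), p$expression_counts)
  writeDesignTsv(design, p$design)
  gb <- sim$genes
  S4Vectors::mcols(gb)$name <- S4Vectors::mcols(gb)$gene_id
  writeBed(gb, p$genes)
  for (key in names(peaks))
    for (r in seq_along(peaks[[key]]))
      writeBed(peaks[[key]][[r]],
               file.path(p$peaks_dir, sprintf("%s_rep%d.bed", key, r)))
  writeGmt(terms, p$gmt)

  tr <- do.call(rbind, lapply(names(sim$truth$regions), function(ct) {
    reg <- sim$truth$regions[[ct]]
    data.frame(contrast = ct, region_id = regionId(reg),
               lfc = S4Vectors::mcols(reg)$lfc)
  }))
  write_tsv(tr, p$truth_regions)
  tg <- do.call(rbind, lapply(names(sim$truth$genes), function(ct)
    data.frame(contrast = ct, gene_id = names(sim$truth$genes[[ct]]),
               lfc = unname(sim$truth$genes[[ct]]))))
  write_tsv(tg, p$truth_genes)

  runCfg <- defaultRunConfig(config)
  yaml::write_yaml(runCfg, p$config)

  invisible(list(dir = dir, paths = p,
                 data = list(genome = sim$genome, genes = sim$genes,
                             truth = sim$truth, design = design,
                             bins = binSE, expression = exprSE,
                             peaks = peaks, terms = terms)))
}

# random gene-set terms plus one term concentrated in the coupled
# treatment-response genes, so enrichment has signal to find
simulateTerms <- function(genes, truth, config, nTerms = 25L) {
  gid <- S4Vectors::mcols(genes)$gene_id
  with_substream(config$seed, "terms", {
    sizes <- sample(10:40, nTerms, replace = TRUE)
    terms <- lapply(sizes, function(s) sample(gid, min(s, length(gid))))
    names(terms) <- sprintf("TERM_%03d", seq_len(nTerms))
    resp <- names(truth$genes$C.IR)[truth$genes$C.IR > 0]
    pad <- sample(setdiff(gid, resp), min(10L, length(setdiff(gid, resp))))
    terms$DAMAGE_RESPONSE <- unique(c(resp, pad))
    terms
  })
}

#' Default pipeline configuration for the simulated study design
#'
#' Encodes the study's contrasts and thresholds: the genotype (baseline)
#' contrast at |log2FC| > 1, the treatment contrasts at |log2FC| > 1.5, all
#' at FDR < 0.05 with direction-aware peak validation; expression contrasts
#' at raw p < 0.05 with no fold-change floor.
#'
#' @param config a [simulationConfig()] (for bin width and seed).
#' @return nested list, writable as YAML.
#' @export
defaultRunConfig <- function(config = simulationConfig()) {
  dc <- function(name, a, b, lfc, upk, downk)
    list(name = name, group_a = a, group_b = b, lfc_min = lfc,
         fdr_max = 0.05, up_peaks = upk, down_peaks = downk)
  ec <- function(name, a, b) list(name = name, group_a = a, group_b = b,
                                  p_max = 0.05)
  list(
    seed = config$seed,
    bin_width = config$binWidth,
    min_count = 20,
    annotation = list(promoter_up = 1000, promoter_down = 100,
                      tts_up = 100, tts_down = 1000),
    drip_contrasts = list(
      dc("baseline", "C.UT", "AT.UT", 1.0, "AT.UT", "C.UT"),
      dc("C.IR", "C.UT", "C.IR", 1.5, "C.IR", "C.UT"),
      dc("AT.IR", "AT.UT", "AT.IR", 1.5, "AT.IR", "AT.UT"),
      dc("C.H2O2", "C.UT", "C.H2O2", 1.5, "C.H2O2", "C.UT"),
      dc("C.RH.IR", "C.UT", "C.RH.IR", 1.5, "C.RH.IR", "C.UT")),
    expression_contrasts = list(
      ec("baseline", "C.UT", "AT.UT"),
      ec("C.IR", "C.UT", "C.IR"),
      ec("AT.IR", "AT.UT", "AT.IR")),
    integration = list(
      concordance = list(list(drip = "baseline", expression = "baseline")),
      response_groups = list(expression_1 = "C.IR", expression_2 = "AT.IR"),
      venn = list(a = "C.IR", b = "AT.IR")),
    perturbation = list(reference = "C.IR", perturbed = "C.RH.IR",
                        consistency_b = "C.H2O2",
                        correlation = c("C.IR", "C.H2O2")),
    enrichment = list(fdr_max = 0.05))
}

#' Run the full differential R-loop pipeline
#'
#' Composes the analysis end to end: bin filtering, NB Wald testing with BH
#' adjustment per contrast, thresholded calling, direction-aware peak
#' validation, gene annotation, expression testing and calling,
#' concordance/response-group/Venn integration, perturbation classification
#' (dampened regions, gene sensitivity, cross-treatment consistency, effect
#' correlation) and term enrichment with Jaccard similarity. Every stage's
#' output is written as TSV/BED under `outDir` and listed, with row counts,
#' in the returned manifest. The run is deterministic given its inputs.
#'
#' @param dataDir directory written by [simulateStudy()] (or laid out the
#'   same way), containing `config.yaml`.
#' @param outDir output directory (default `<dataDir>/out`).
#' @param config optional config list overriding `config.yaml`.
#' @return list with `manifest` (data.frame file/rows) and `results` (all
#'   in-memory stage outputs).
#' @export
runPipeline <- function(dataDir, outDir = file.path(dataDir, "out"),
                        config = NULL) {
  if (is.null(config)) {
    cfgPath <- file.path(dataDir, "config.yaml")
    if (!file.exists(cfgPath)) stop("config error: missing ", cfgPath)
    config <- yaml::read_yaml(cfgPath)
  }
  need <- c("genome.tsv", "counts_bins.tsv", "counts_genes.tsv",
            "design.tsv", "genes.bed", "terms.gmt")
  miss <- need[!file.exists(file.path(dataDir, need))]
  if (length(miss)) stop("config error: missing input file ", miss[1L])
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  genome <- readGenomeTsv(file.path(dataDir, "genome.tsv"))
  binCounts <- readCountsTsv(file.path(dataDir, "counts_bins.tsv"))
  exprCounts <- readCountsTsv(file.path(dataDir, "counts_genes.tsv"))
  design <- readDesignTsv(file.path(dataDir, "design.tsv"))
  genes <- readGenesBed(file.path(dataDir, "genes.bed"), genome)
  terms <- readGmt(file.path(dataDir, "terms.gmt"))
  bins <- makeBins(genome, config$bin_width)
  groups <- design$group[match(colnames(binCounts), design$sample)]
  exprGroups <- design$group[match(colnames(exprCounts), design$sample)]

  ann <- config$annotation
  index <- annotationIndex(genes, ann$promoter_up, ann$promoter_down,
                           ann$tts_up, ann$tts_down)

  # replicate peaks per group key, merged into the condition peak library
  peakFiles <- list.files(file.path(dataDir, "peaks"), full.names = TRUE,
                          pattern = "_rep[0-9]+\\.bed$")
  if (length(peakFiles) == 0L) stop("config error: no peak files found")
  peakKey <- sub("_rep[0-9]+\\.bed$", "", basename(peakFiles))
  peakSets <- split(peakFiles, peakKey)
  peaks <- mergePeakLibrary(lapply(peakSets, function(fs)
    lapply(fs, readBed, genome = genome)))

  manifest <- data.frame(file = character(), rows = integer())
  emit <- function(x, name) {
    path <- file.path(outDir, name)
    write_tsv(x, path)
    manifest <<- rbind(manifest, data.frame(file = name, rows = nrow(x)))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- differential R-loop bins, validation, annotation ---
  drip <- list()
  for (ct in config$drip_contrasts) {
    drip[[ct$name]] <- run_stage(paste0("drip:", ct$name), {
      kept <- filterBins(binCounts, ct$group_a, ct$group_b,
                         config$min_count, groups = groups)
      tab <- nbDifferential(kept, groups, c(ct$group_a, ct$group_b))
      calls <- callDifferential(tab, fdrMax = ct$fdr_max,
                                lfcMin = ct$lfc_min, contrast = ct$name)
      for (key in c(ct$up_peaks, ct$down_peaks))
        if (!key %in% names(peaks))
          stop("missing peak set for (", key, ")")
      validated <- validateWithPeaks(calls, bins, peaks,
                                     ct$up_peaks, ct$down_peaks)
      annot <- annotateCalls(validated, index)
      emit(data.frame(feature_id = rownames(tab), tab),
           sprintf("drip_%s_table.tsv", ct$name))
      emit(annot$table, sprintf("drip_%s_annotation.tsv", ct$name))
      list(table = tab, calls = calls, validated = validated, annot = annot)
    })
  }

  # --- differential expression ---
  expr <- list()
  for (ct in config$expression_contrasts) {
    expr[[ct$name]] <- run_stage(paste0("expression:", ct$name), {
      tab <- nbDifferential(exprCounts, exprGroups,
                            c(ct$group_a, ct$group_b))
      calls <- callDifferential(tab, pMax = ct$p_max, contrast = ct$name)
      emit(data.frame(gene_id = rownames(tab), tab),
           sprintf("expression_%s_table.tsv", ct$name))
      list(table = tab, calls = calls)
    })
  }

  # --- integration ---
  integration <- run_stage("integration", {
    conc <- lapply(config$integration$concordance, function(pair) {
      d <- drip[[pair$drip]]; e <- expr[[pair$expression]]
      s <- overlapRegionsWithDegs(d$annot$upGenes, d$annot$downGenes, e$calls)
      emit(data.frame(direction = rownames(s), s),
           sprintf("concordance_%s.tsv", pair$drip))
      s
    })
    names(conc) <- vapply(config$integration$concordance, `[[`, "", "drip")
    rg <- config$integration$response_groups
    groupsRG <- classifyResponseGroups(expr[[rg$expression_1]]$calls,
                                       expr[[rg$expression_2]]$calls)
    gm <- data.frame(
      group = rep(c("I", "II", "III", "IV", "V", "VI", "discordant"),
                  vapply(groupsRG[1:7], length, 1L)),
      gene_id = unlist(groupsRG[1:7], use.names = FALSE))
    emit(gm, "response_groups.tsv")
    vn <- config$integration$venn
    venn <- vennPartition(regionId(drip[[vn$a]]$validated$up),
                          regionId(drip[[vn$b]]$validated$up))
    emit(data.frame(part = c("aOnly", "shared", "bOnly"),
                    n = vapply(venn, length, 1L)), "venn_accumulated.tsv")
    cls <- summarizeExpressionByRloopClass(
      drip$baseline$annot$upGenes, drip$baseline$annot$downGenes,
      expr$baseline$table)
    emit(data.frame(class = rownames(cls), cls), "rloop_class_summary.tsv")
    list(concordance = conc, responseGroups = groupsRG, venn = venn,
         classSummary = cls)
  })

  # --- perturbation ---
  pert <- run_stage("perturbation", {
    pc <- config$perturbation
    refTab <- drip[[pc$reference]]$table
    pertTab <- drip[[pc$perturbed]]$table
    refUp <- upCalls(drip[[pc$reference]]$calls)
    common <- intersect(refUp, rownames(pertTab))
    att <- classifyAttenuation(refTab, pertTab, common)
    emit(att$records, "attenuation_records.tsv")
    emit(att$summary, "attenuation_summary.tsv")
    sens <- aggregateGeneSensitivity(att$records,
                                     drip[[pc$reference]]$annot$table)
    emit(data.frame(
      class = rep(c("only_dampened", "only_increased", "both"),
                  vapply(sens, length, 1L)),
      gene_id = unlist(sens, use.names = FALSE)), "gene_sensitivity.tsv")
    bTab <- drip[[pc$consistency_b]]$table
    refCalls <- drip[[pc$reference]]$calls
    sub <- methods::new("DifferentialCalls",
                        up = intersect(refCalls@up, rownames(bTab)),
                        down = intersect(refCalls@down, rownames(bTab)),
                        contrast = refCalls@contrast, params = refCalls@params)
    tiers <- crossTreatmentConsistency(sub, bTab)
    emit(data.frame(direction = rownames(tiers), tiers),
         "consistency_tiers.tsv")
    corRegions <- intersect(
      upCalls(drip[[pc$correlation[[1L]]]]$calls),
      rownames(drip[[pc$correlation[[2L]]]]$table))
    corr <- effectCorrelation(drip[[pc$correlation[[1L]]]]$table,
                              drip[[pc$correlation[[2L]]]]$table, corRegions)
    emit(data.frame(r = corr$r, p = corr$p, n = corr$n),
         "effect_correlation.tsv")
    list(attenuation = att, sensitivity = sens, tiers = tiers,
         correlation = corr)
  })

  # --- enrichment ---
  enrich <- run_stage("enrichment", {
    background <- S4Vectors::mcols(genes)$gene_id
    geneSets <- Filter(length, list(
      I = integration$responseGroups$I,
      II = integration$responseGroups$II,
      III = integration$responseGroups$III))
    tables <- lapply(geneSets, function(g)
      tryCatch(hypergeometricEnrichment(g, terms, background,
                                        config$enrichment$fdr_max),
               error = function(e) NULL))
    tables <- Filter(Negate(is.null), tables)
    for (nm in names(tables))
      emit(tables[[nm]], sprintf("enrichment_group_%s.tsv", nm))
    sets <- lapply(tables, enrichedTerms)
    jac <- outer(seq_along(sets), seq_along(sets),
                 Vectorize(function(i, j) jaccardIndex(sets[[i]], sets[[j]])))
    dimnames(jac) <- list(names(sets), names(sets))
    if (length(sets))
      emit(data.frame(group = rownames(jac), jac, check.names = FALSE),
           "jaccard_matrix.tsv")
    list(tables = tables, jaccard = jac)
  })

  write_tsv(manifest, file.path(outDir, "manifest.tsv"))
  list(manifest = manifest,
       results = list(drip = drip, expression = expr,
                      integration = integration, perturbation = pert,
                      enrichment = enrich))
}
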