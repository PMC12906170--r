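#' Classify regions as dampened under a perturbation
#'
#' Compares each region's treatment log2 fold change in a reference contrast
#' (e.g. IR/UT) against the perturbed contrast (e.g. RH.IR/UT, RNase H1
#' overexpressed). A region is `dampened` when the perturbed fold change is
#' strictly smaller than the reference one (`lfc_pert < lfc_ref`), otherwise
#' `not_dampened`; `delta = lfc_ref - lfc_pert`, so dampened is `delta > 0`.
#'
#' @param tableRef,tablePert data.frames from [nbDifferential()] covering the
#'   regions (rownames = region ids).
#' @param regions character region ids to classify.
#' @param assumeNull when `TRUE`, regions missing from `tablePert` are scored
#'   with `lfc_pert = 0` instead of raising an error.
#' @return list with `records` (region, lfc_ref, lfc_pert, delta, class) and
#'   `summary` (counts and percentages per class).
#' @export
classifyAttenuation <- function(tableRef, tablePert, regions,
                                assumeNull = FALSE) {
  missRef <- setdiff(regions, rownames(tableRef))
  if (length(missRef)) stop("region missing from reference table: ", missRef[1L])
  missPert <- setdiff(regions, rownames(tablePert))
  if (length(missPert) && !assumeNull)
    stop("region missing from perturbed table: ", missPert[1L])
  lfcRef <- tableRef[regions, "log2FoldChange"]
  lfcPert <- rep(0, length(regions))
  have <- regions %in% rownames(tablePert)
  lfcPert[have] <- tablePert[regions[have], "log2FoldChange"]
  delta <- lfcRef - lfcPert
  cls <- ifelse(lfcPert < lfcRef, "dampened", "not_dampened")
  records <- data.frame(region = regions, lfc_ref = lfcRef,
                        lfc_pert = lfcPert, delta = delta, class = cls,
                        stringsAsFactors = FALSE)
  nD <- sum(cls == "dampened")
  summary <- data.frame(class = c("dampened", "not_dampened"),
                        n = c(nD, length(regions) - nD),
                        pct = 100 * c(nD, length(regions) - nD) /
                          max(length(regions), 1L))
  list(records = records, summary = summary)
}

#' Aggregate region sensitivity classes to genes
#'
#' A gene's sensitivity follows from the classes of the regions it hosts:
#' genes with only dampened regions, only increased (not-dampened) regions,
#' or both. The three sets are disjoint and cover every gene hosting a
#' classified region.
#'
#' @param records data.frame from [classifyAttenuation()] (`$records`).
#' @param regionGenes data.frame mapping `region_id` to `gene_id` (e.g. the
#'   `table` of [annotateCalls()]); intergenic regions (`NA` gene) are
#'   ignored.
#' @return list with character sets `onlyDampened`, `onlyIncreased`, `both`.
#' @export
aggregateGeneSensitivity <- function(records, regionGenes) {
  m <- merge(records, regionGenes[, c("region_id", "gene_id")],
             by.x = "region", by.y = "region_id")
  m <- m[!is.na(m$gene_id), , drop = FALSE]
  damp <- unique(m$gene_id[m$class == "dampened"])
  incr <- unique(m$gene_id[m$class == "not_dampened"])
  list(onlyDampened = sort(setdiff(damp, incr)),
       onlyIncreased = sort(setdiff(incr, damp)),
       both = sort(intersect(damp, incr)))
}

#' Three-tier cross-treatment consistency
#'
#' For the reference-significant accumulated regions, classifies each by its
#' behaviour in a second treatment's table: tier 1 (significant-consistent)
#' when `log2FoldChange > lfcMin` and `padj < fdrMax`; tier 2
#' (nonsignificant-consistent) when `log2FoldChange > 0` but not tier 1;
#' tier 3 (nonconsistent) when `log2FoldChange <= 0`. Mirrored with flipped
#' signs for depleted regions.
#'
#' @param callsRef a [DifferentialCalls-class] from the reference treatment.
#' @param tableB data.frame from [nbDifferential()] for the second treatment,
#'   covering all called regions.
#' @param fdrMax,lfcMin significance thresholds applied in treatment B
#'   (defaults 0.05 and 1.5).
#' @return data.frame with rows `accumulation` and `depletion` and columns
#'   `n`, `significant`, `nonsignificant`, `nonconsistent` (fractions summing
#'   to 1 per direction) plus the raw tier counts.
#' @export
crossTreatmentConsistency <- function(callsRef, tableB,
                                      fdrMax = 0.05, lfcMin = 1.5) {
  one <- function(ids, sgn) {
    miss <- setdiff(ids, rownames(tableB))
    if (length(miss)) stop("region missing from treatment-B table: ", miss[1L])
    lfc <- sgn * tableB[ids, "log2FoldChange"]
    q <- tableB[ids, "padj"]
    t1 <- lfc > lfcMin & !is.na(q) & q < fdrMax
    t3 <- lfc <= 0
    t2 <- !t1 & !t3
    n <- length(ids)
    data.frame(n = n, nSignificant = sum(t1), nNonsignificant = sum(t2),
               nNonconsistent = sum(t3),
               significant = if (n) sum(t1) / n else NA_real_,
               nonsignificant = if (n) sum(t2) / n else NA_real_,
               nonconsistent = if (n) sum(t3) / n else NA_real_)
  }
  out <- rbind(one(callsRef@up, 1), one(callsRef@down, -1))
  rownames(out) <- c("accumulation", "depletion")
  out
}

#' Correlation of effect sizes between two contrasts
#'
#' Pearson correlation of log2 fold changes over a shared region set, with a
#' two-sided p value from the t transform on `n - 2` degrees of freedom
#' (e.g. genetic loss vs chemical inhibition of the same pathway).
#'
#' @param table1,table2 data.frames from [nbDifferential()].
#' @param regions character region ids present in both tables.
#' @return list with `r`, `p`, `n`.
#' @export
effectCorrelation <- function(table1, table2, regions) {
  miss <- setdiff(regions, intersect(rownames(table1), rownames(table2)))
  if (length(miss)) stop("region missing from a table: ", miss[1L])
  x <- table1[regions, "log2FoldChange"]
  y <- table2[regions, "log2FoldChange"]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 common regions")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
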