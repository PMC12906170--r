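#' Concordance of R-loop directions with differential expression
#'
#' Genes hosting at least one validated region of a direction are
#' cross-tabulated against the DE call sets. Percentages are computed among
#' the DE genes of that direction only (the pie denominators), and are absent
#' (`NA`) when no host gene is DE. A gene hosting regions of both directions
#' contributes to both rows.
#'
#' @param upGenes,downGenes character vectors of genes hosting accumulated /
#'   depleted regions (e.g. from [annotateCalls()]).
#' @param deCalls a [DifferentialCalls-class] from the expression contrast.
#' @return data.frame with rows `accumulated` and `depleted` and columns
#'   `hostGenes`, `deUp`, `deDown`, `notDe`, `pctUp`, `pctDown`.
#' @export
overlapRegionsWithDegs <- function(upGenes, downGenes, deCalls) {
  one <- function(genes) {
    nUp <- length(intersect(genes, deCalls@up))
    nDown <- length(intersect(genes, deCalls@down))
    nDe <- nUp + nDown
    data.frame(hostGenes = length(genes), deUp = nUp, deDown = nDown,
               notDe = length(genes) - nDe,
               pctUp = if (nDe > 0) 100 * nUp / nDe else NA_real_,
               pctDown = if (nDe > 0) 100 * nDown / nDe else NA_real_)
  }
  out <- rbind(one(unique(upGenes)), one(unique(downGenes)))
  rownames(out) <- c("accumulated", "depleted")
  out
}

#' Expression change distributions by R-loop class
#'
#' Partitions the tested genes into `accumulated` (hosting >= 1 accumulated
#' region), `depleted` (hosting >= 1 depleted region and no accumulated one)
#' and `unchanged`, and summarizes each class's expression log2 fold-change
#' distribution.
#'
#' @param upGenes,downGenes host-gene vectors per R-loop direction.
#' @param deTable data.frame from [nbDifferential()] (rownames = genes).
#' @return data.frame per class: `n`, `median`, `q1`, `q3` of
#'   `log2FoldChange`.
#' @export
summarizeExpressionByRloopClass <- function(upGenes, downGenes, deTable) {
  genes <- rownames(deTable)
  cls <- rep("unchanged", length(genes))
  cls[genes %in% downGenes] <- "depleted"
  cls[genes %in% upGenes] <- "accumulated"
  one <- function(k) {
    lfc <- deTable$log2FoldChange[cls == k]
    data.frame(n = length(lfc),
               median = if (length(lfc)) median(lfc) else NA_real_,
               q1 = if (length(lfc)) unname(quantile(lfc, 0.25)) else NA_real_,
               q3 = if (length(lfc)) unname(quantile(lfc, 0.75)) else NA_real_)
  }
  out <- rbind(one("accumulated"), one("depleted"), one("unchanged"))
  rownames(out) <- c("accumulated", "depleted", "unchanged")
  out
}

#' Six-group response classification across two genotypes
#'
#' Partitions the union of DE genes by direction of change in each genotype:
#' group I (genotype-1-only up), II (genotype-1-only down), III (shared up),
#' IV (shared down), V (genotype-2-only up), VI (genotype-2-only down).
#' Genes changing in opposite directions in the two genotypes are quarantined
#' in a `discordant` set and belong to none of I-VI.
#'
#' @param calls1,calls2 [DifferentialCalls-class] objects over the same gene
#'   universe (e.g. control and mutant IR responses).
#' @return list with gene sets `I`..`VI`, `discordant`, and a `counts`
#'   integer vector including per-genotype totals.
#' @export
classifyResponseGroups <- function(calls1, calls2) {
  up1 <- calls1@up; down1 <- calls1@down
  up2 <- calls2@up; down2 <- calls2@down
  discordant <- union(intersect(up1, down2), intersect(down1, up2))
  g <- list(I = setdiff(up1, union(up2, down2)),
            II = setdiff(down1, union(up2, down2)),
            III = intersect(up1, up2),
            IV = intersect(down1, down2),
            V = setdiff(up2, union(up1, down1)),
            VI = setdiff(down2, union(up1, down1)),
            discordant = discordant)
  g$counts <- c(vapply(g[1:7], length, 1L),
                total1Up = length(up1), total1Down = length(down1),
                total2Up = length(up2), total2Down = length(down2))
  g
}

#' Three-way Venn partition of two sets
#'
#' @param setA,setB vectors of comparable elements.
#' @return list with disjoint `aOnly`, `shared`, `bOnly`.
#' @export
vennPartition <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  list(aOnly = setdiff(setA, setB),
       shared = intersect(setA, setB),
       bOnly = setdiff(setB, setA))
}
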