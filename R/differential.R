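#' @importFrom stats median pnorm p.adjust quantile rpois rnbinom runif
#'   rbinom rlnorm setNames cor cor.test phyper complete.cases
NULL

check_counts <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (length(groups) != ncol(counts))
    stop("design must label every sample")
  counts
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each feature with strictly positive
#' counts in every sample, the ratio of its count to its geometric mean across
#' samples is formed; a sample's size factor is the median of these ratios.
#'
#' @param counts nonnegative integer matrix (features x samples).
#' @return positive numeric vector, one factor per sample.
#' @export
estimateSizeFactors <- function(counts) {
  counts <- check_counts(counts, rep("g", ncol(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) stop("cannot normalize: no feature with all-positive counts")
  k <- counts[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(k)))
  sf <- apply(k, 2L, function(x) median(x / geo))
  setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimates
#'
#' For each feature, counts are normalized by the size factors and pooled
#' within-group moments are taken: `mu` is the mean of the normalized counts
#' and `v` the pooled within-group variance (denominator `n - G` for `G`
#' groups). The NB dispersion under `var = mu + alpha mu^2` is
#' `alpha = max(alphaMin, (v - mu) / mu^2)`.
#'
#' @param counts feature x sample count matrix.
#' @param sizeFactors from [estimateSizeFactors()].
#' @param groups sample group labels (character/factor, length = ncol).
#' @param alphaMin dispersion floor (default 1e-8).
#' @return numeric dispersion per feature.
#' @export
estimateDispersions <- function(counts, sizeFactors, groups,
                                alphaMin = 1e-8) {
  counts <- check_counts(counts, groups)
  x <- sweep(counts, 2L, sizeFactors, "/")
  groups <- as.character(groups)
  gl <- unique(groups)
  n <- ncol(x)
  ss <- matrix(0, nrow(x), 1L)
  for (g in gl) {
    xg <- x[, groups == g, drop = FALSE]
    ss <- ss + rowSums((xg - rowMeans(xg))^2)
  }
  df <- n - length(gl)
  v <- if (df > 0) ss[, 1L] / df else rep(0, nrow(x))
  mu <- rowMeans(x)
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- alphaMin
  pmax(alphaMin, alpha)
}

#' Negative-binomial Wald test between two groups
#'
#' Group rates are ratio estimators `q_g = sum(K_ij) / sum(s_j)` over the
#' group's samples (a 0.5 pseudocount is added to the numerator of an
#' all-zero group). The natural-log fold change `beta_B - beta_A` is tested
#' with a Wald z using the Fisher information
#' `I_g = sum_j mu_gj / (1 + alpha_i mu_gj)` with `mu_gj = q_g s_j`, giving
#' `se = sqrt(1/I_A + 1/I_B)` and a two-sided normal p value.
#'
#' @param counts feature x sample count matrix.
#' @param sizeFactors,dispersions per-sample factors and per-feature
#'   dispersions.
#' @param groups sample group labels.
#' @param contrast character of length 2, `c(groupA, groupB)`; the reported
#'   `log2FoldChange` is B over A.
#' @return data.frame with rownames = feature ids and columns `baseMean`
#'   (mean normalized count over the contrast samples), `log2FoldChange`,
#'   `lfcSE` (on the log2 scale), `stat`, `pvalue`.
#' @export
nbWaldTest <- function(counts, sizeFactors, dispersions, groups, contrast) {
  counts <- check_counts(counts, groups)
  groups <- as.character(groups)
  stopifnot(length(contrast) == 2L)
  jA <- which(groups == contrast[1L])
  jB <- which(groups == contrast[2L])
  if (length(jA) < 2L || length(jB) < 2L)
    stop("each contrast group needs >= 2 samples")

  rate <- function(j) {
    tot <- rowSums(counts[, j, drop = FALSE])
    (tot + 0.5 * (tot == 0)) / sum(sizeFactors[j])
  }
  qA <- rate(jA); qB <- rate(jB)
  info <- function(q, j) {
    mu <- outer(q, sizeFactors[j])
    rowSums(mu / (1 + dispersions * mu))
  }
  iA <- info(qA, jA); iB <- info(qB, jB)
  seLn <- sqrt(1 / iA + 1 / iB)
  dBeta <- log(qB) - log(qA)
  z <- dBeta / seLn
  norm <- sweep(counts[, c(jA, jB), drop = FALSE], 2L,
                sizeFactors[c(jA, jB)], "/")
  data.frame(baseMean = rowMeans(norm),
             log2FoldChange = dBeta / log(2),
             lfcSE = seLn / log(2),
             stat = z,
             pvalue = 2 * pnorm(-abs(z)),
             row.names = rownames(counts))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment, applied within the tested feature family.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return adjusted q values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run the full differential test for one contrast
#'
#' Convenience wrapper: size factors, dispersions, Wald test and BH
#' adjustment (within the tested feature set).
#'
#' @inheritParams nbWaldTest
#' @return data.frame as [nbWaldTest()] plus a `padj` column.
#' @export
nbDifferential <- function(counts, groups, contrast) {
  counts <- check_counts(counts, groups)
  j <- groups %in% contrast
  sub <- counts[, j, drop = FALSE]
  sf <- estimateSizeFactors(sub)
  disp <- estimateDispersions(sub, sf, groups[j])
  tab <- nbWaldTest(sub, sf, disp, groups[j], contrast)
  tab$padj <- bhAdjust(tab$pvalue)
  tab
}

#' Thresholded differential call sets
#'
#' Holds the up ("accumulated"/upregulated) and down ("depleted"/
#' downregulated) feature sets of one contrast together with the thresholds
#' that produced them.
#'
#' @slot up,down character feature sets (disjoint).
#' @slot contrast label of the contrast.
#' @slot params list echoing the thresholds used.
#' @export
setClass("DifferentialCalls",
  representation(up = "character", down = "character",
                 contrast = "character", params = "list"))

setValidity("DifferentialCalls", function(object) {
  if (length(intersect(object@up, object@down)))
    return("up and down sets must be disjoint")
  TRUE
})

setMethod("show", "DifferentialCalls", function(object) {
  cat("DifferentialCalls [", object@contrast, "]: ",
      length(object@up), " up, ", length(object@down), " down\n", sep = "")
})

#' @describeIn DifferentialCalls accessors for the call sets.
#' @param calls a `DifferentialCalls`.
#' @export
upCalls <- function(calls) calls@up

#' @describeIn DifferentialCalls accessor for the down set.
#' @export
downCalls <- function(calls) calls@down

#' Apply significance and fold-change thresholds
#'
#' Default (FDR mode): up features have `padj < fdrMax` and
#' `log2FoldChange > lfcMin`; down features mirror with `< -lfcMin`. All
#' inequalities are strict. When `pMax` is supplied (raw-p mode, as used for
#' expression calls) the raw p value is thresholded instead and no
#' fold-change floor is applied (direction by the sign of the fold change).
#'
#' @param table data.frame from [nbDifferential()] (needs `log2FoldChange`
#'   and `padj`, or `pvalue` in raw-p mode).
#' @param fdrMax FDR threshold (default 0.05).
#' @param lfcMin absolute log2 fold-change floor (default 1).
#' @param pMax optional raw-p threshold switching to raw-p mode.
#' @param contrast label stored on the result.
#' @return a [DifferentialCalls-class] object.
#' @export
callDifferential <- function(table, fdrMax = 0.05, lfcMin = 1,
                             pMax = NULL, contrast = "contrast") {
  lfc <- table$log2FoldChange
  ids <- rownames(table)
  if (is.null(pMax)) {
    sig <- !is.na(table$padj) & table$padj < fdrMax
    up <- sig & lfc > lfcMin
    down <- sig & lfc < -lfcMin
    params <- list(mode = "fdr", fdrMax = fdrMax, lfcMin = lfcMin)
  } else {
    sig <- !is.na(table$pvalue) & table$pvalue < pMax
    up <- sig & lfc > 0
    down <- sig & lfc < 0
    params <- list(mode = "raw-p", pMax = pMax, lfcMin = 0)
  }
  methods::new("DifferentialCalls", up = ids[up], down = ids[down],
               contrast = contrast, params = params)
}
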