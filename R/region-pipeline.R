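#' Count fragments into genome bins by the midpoint rule
#'
#' Each fragment is counted exactly once, in the bin containing its midpoint
#' (0-based `floor((start0 + end)/2)`), so totals are conserved and no
#' fragment is double-counted across bin boundaries.
#'
#' @param fragments `GRanges` of fragments.
#' @param bins `GRanges` from [makeBins()].
#' @return named integer vector of per-bin counts (one entry per bin).
#' @export
countFragmentsIntoBins <- function(fragments, bins) {
  counts <- setNames(integer(length(bins)), names(bins))
  if (length(fragments) == 0L) return(counts)
  mid0 <- region_midpoint0(fragments)
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  sl <- GenomeInfoDb::seqlengths(bins)
  bad <- !chrom %in% names(sl) | mid0 < 0 |
    (!is.na(sl[chrom]) & mid0 >= sl[chrom])
  if (any(bad)) stop("fragment outside genome: ", regionId(fragments[bad][1L]))
  mids <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid0 + 1L, mid0 + 1L))
  GenomeInfoDb::seqlevels(mids) <- GenomeInfoDb::seqlevels(bins)
  hit <- GenomicRanges::findOverlaps(mids, bins, ignore.strand = TRUE)
  tab <- tabulate(S4Vectors::subjectHits(hit), nbins = length(bins))
  counts[] <- tab
  counts
}

#' Replicate read-count bin filter
#'
#' A bin is kept when every replicate of group A, or every replicate of
#' group B, has a count strictly greater than `minCount`. Filtering before
#' testing restricts the tested (and BH-adjusted) family to covered bins.
#'
#' @param counts feature x sample matrix or `SummarizedExperiment` with a
#'   `group` colData column.
#' @param groupA,groupB the two group labels.
#' @param minCount threshold (default 20; strict `>`).
#' @param groups group labels when `counts` is a matrix.
#' @return the input restricted to kept bins.
#' @export
filterBins <- function(counts, groupA, groupB, minCount = 20, groups = NULL) {
  if (methods::is(counts, "SummarizedExperiment")) {
    groups <- SummarizedExperiment::colData(counts)$group
    m <- SummarizedExperiment::assay(counts)
  } else m <- counts
  stopifnot(!is.null(groups))
  jA <- groups == groupA
  jB <- groups == groupB
  if (!any(jA) || !any(jB)) stop("both groups must be present in the design")
  keep <- rowSums(m[, jA, drop = FALSE] > minCount) == sum(jA) |
    rowSums(m[, jB, drop = FALSE] > minCount) == sum(jB)
  counts[keep, ]
}

#' Direction-aware peak validation of differential bins
#'
#' Significant bins are retained only when they overlap (>= 1 bp) the merged
#' peak set of the condition in which their signal is higher: up bins are
#' intersected with the `upKey` peaks, down bins with the `downKey` peaks.
#' Bins passing are the "bona fide" differential R-loop regions.
#'
#' @param calls a [DifferentialCalls-class] over bins (feature ids are
#'   region ids).
#' @param bins `GRanges` named by the same ids (e.g. from [makeBins()]), or
#'   `NULL` to parse coordinates from the ids.
#' @param peaks a merged peak library from [mergePeakLibrary()].
#' @param upKey,downKey names of the peak sets validating each direction.
#' @return list with `up` and `down` `GRanges` (subsets of the called bins)
#'   and a `provenance` record of the contrast and peak keys.
#' @export
validateWithPeaks <- function(calls, bins = NULL, peaks, upKey, downKey) {
  for (key in c(upKey, downKey))
    if (!key %in% names(peaks)) stop("missing peak set: ", key)
  grab <- function(ids) {
    if (is.null(bins)) parseRegionId(ids)
    else {
      miss <- setdiff(ids, names(bins))
      if (length(miss)) stop("bin not found: ", miss[1L])
      bins[ids]
    }
  }
  up <- grab(calls@up)
  down <- grab(calls@down)
  list(up = intersectAny(up, peaks[[upKey]]),
       down = intersectAny(down, peaks[[downKey]]),
       provenance = list(contrast = calls@contrast,
                         upKey = upKey, downKey = downKey))
}

#' Annotate validated regions and summarize
#'
#' Annotates each direction's validated regions with [annotateRegions()] and
#' reports the per-direction category distribution and the deduplicated list
#' of genic host genes (regions annotated as promoter, gene body or TTS).
#'
#' @param validated list from [validateWithPeaks()].
#' @param index an [AnnotationIndex].
#' @return list with `table` (direction, region_id, category, gene_id,
#'   tss_distance), `upGenes`, `downGenes`, `upDistribution`,
#'   `downDistribution` (the last two `NULL` for empty directions).
#' @export
annotateCalls <- function(validated, index) {
  one <- function(gr, direction) {
    if (length(gr) == 0L)
      return(data.frame(direction = character(), region_id = character(),
                        category = character(), gene_id = character(),
                        tss_distance = integer()))
    ann <- annotateRegions(gr, index)
    cbind(direction = direction, ann)
  }
  tabUp <- one(validated$up, "up")
  tabDown <- one(validated$down, "down")
  genic <- function(tab) sort(unique(tab$gene_id[tab$category != "intergenic" &
                                                   !is.na(tab$gene_id)]))
  list(table = rbind(tabUp, tabDown),
       upGenes = genic(tabUp),
       downGenes = genic(tabDown),
       upDistribution = if (nrow(tabUp)) annotationDistribution(tabUp) else NULL,
       downDistribution = if (nrow(tabDown)) annotationDistribution(tabDown) else NULL)
}
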