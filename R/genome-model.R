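#' Define a genome as an ordered set of chromosome lengths
#'
#' The genome definition is the coordinate frame for bins, peaks, regions and
#' gene models. Internally it is a [GenomeInfoDb::Seqinfo] object; all in-memory
#' intervals are `GRanges` (1-based, closed), while BED files on disk use the
#' 0-based half-open convention and are converted on read/write.
#'
#' @param chromLengths named integer/numeric vector of chromosome lengths (bp).
#' @return A `Seqinfo` object.
#' @examples
#' genomeDef(c(chr1 = 1e6, chr2 = 7e5))
#' @export
genomeDef <- function(chromLengths) {
  if (length(chromLengths) == 0L) stop("no chromosomes")
  nms <- names(chromLengths)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("chromosome names must be unique and non-empty")
  if (any(chromLengths < 1)) stop("chromosome lengths must be >= 1")
  GenomeInfoDb::Seqinfo(seqnames = nms,
                        seqlengths = as.integer(chromLengths))
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is covered by consecutive, non-overlapping bins of `width`
#' bp; the last bin of a chromosome is truncated at the chromosome end. Bin
#' indices run consecutively over chromosomes in genome order, and bin names
#' are BED-style region ids (`chrom:start0-end`).
#'
#' @param genome a `Seqinfo` from [genomeDef()] (or a named length vector).
#' @param width bin width in bp (default 500).
#' @return `GRanges` of bins with metadata column `index`.
#' @examples
#' makeBins(genomeDef(c(c1 = 1250)), width = 500)
#' @export
makeBins <- function(genome, width = 500L) {
  genome <- as_seqinfo(genome)
  if (length(GenomeInfoDb::seqnames(genome)) == 0L) stop("no chromosomes")
  if (width < 1) stop("width must be >= 1")
  bins <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(genome),
                                    tilewidth = as.integer(width),
                                    cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqinfo(bins) <- genome
  S4Vectors::mcols(bins)$index <- seq_along(bins)
  names(bins) <- regionId(bins)
  bins
}

as_seqinfo <- function(genome) {
  if (methods::is(genome, "Seqinfo")) return(genome)
  genomeDef(genome)
}

#' BED-style region identifiers
#'
#' Formats each range as `chrom:start0-end` with a 0-based half-open span, the
#' id convention used for bin/region feature names throughout the package.
#'
#' @param gr a `GRanges`.
#' @return character vector of ids.
#' @export
regionId <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Parse BED-style region identifiers back into ranges
#'
#' @param ids character ids as produced by [regionId()].
#' @param genome optional `Seqinfo` to attach.
#' @return `GRanges` named by `ids`.
#' @export
parseRegionId <- function(ids, genome = NULL) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region id: ", ids[bad][1L])
  chrom <- vapply(m, `[`, "", 2L)
  s0 <- as.integer(vapply(m, `[`, "", 3L))
  e <- as.integer(vapply(m, `[`, "", 4L))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e))
  if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
  names(gr) <- ids
  gr
}

#' Retain query intervals overlapping any subject interval
#'
#' Whole-query reporting with a minimum overlap of 1 bp (`bedtools intersect
#' -wa -u` semantics): each retained query is returned unmodified, once.
#' Half-open abutment is not overlap.
#'
#' @param queries,subjects `GRanges`.
#' @return the subset of `queries` overlapping at least one subject.
#' @export
intersectAny <- function(queries, subjects) {
  IRanges::subsetByOverlaps(queries, subjects, minoverlap = 1L)
}

#' Merge overlapping and abutting intervals
#'
#' Returns the minimal sorted set of non-overlapping intervals covering the
#' same bases; book-ended (abutting) intervals are joined, matching
#' `bedtools merge` at distance 0.
#'
#' @param intervals `GRanges`.
#' @return merged, sorted `GRanges`.
#' @export
mergeIntervals <- function(intervals) {
  GenomicRanges::reduce(GenomicRanges::sort(intervals))
}

#' Gene-model annotation index
#'
#' Holds gene spans with strand plus the window extents (bp) defining the
#' promoter (around the TSS) and the TTS ("other") category (around the TES).
#' Windows are strand-aware: on the + strand the promoter covers
#' `[TSS - promoterUp, TSS + promoterDown)` in 0-based coordinates, mirrored
#' on the - strand.
#'
#' @slot genes `GRanges` with metadata column `gene_id` and strand `+`/`-`.
#' @slot promoterUp,promoterDown,ttsUp,ttsDown window extents in bp.
#' @export
setClass("AnnotationIndex",
  representation(genes = "GRanges", promoterUp = "numeric",
                 promoterDown = "numeric", ttsUp = "numeric",
                 ttsDown = "numeric"))

setValidity("AnnotationIndex", function(object) {
  g <- object@genes
  if (is.null(S4Vectors::mcols(g)$gene_id))
    return("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(S4Vectors::mcols(g)$gene_id))
    return("gene_id values must be unique")
  if (any(!as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
    return("gene strand must be '+' or '-'")
  ext <- c(object@promoterUp, object@promoterDown, object@ttsUp, object@ttsDown)
  if (any(ext < 0)) return("window extents must be >= 0")
  TRUE
})

#' @describeIn AnnotationIndex constructor. Defaults follow common
#'   promoter/TTS conventions: TSS -1000/+100 bp and TES -100/+1000 bp.
#' @param genes `GRanges` with `gene_id` metadata and strand.
#' @param promoterUp,promoterDown bp upstream/downstream of the TSS.
#' @param ttsUp,ttsDown bp upstream/downstream of the TES.
#' @export
annotationIndex <- function(genes, promoterUp = 1000, promoterDown = 100,
                            ttsUp = 100, ttsDown = 1000) {
  methods::new("AnnotationIndex", genes = genes, promoterUp = promoterUp,
               promoterDown = promoterDown, ttsUp = ttsUp, ttsDown = ttsDown)
}

setMethod("show", "AnnotationIndex", function(object) {
  cat("AnnotationIndex with", length(object@genes), "genes;",
      sprintf("promoter TSS -%g/+%g bp, TTS window TES -%g/+%g bp\n",
              object@promoterUp, object@promoterDown,
              object@ttsUp, object@ttsDown))
})

#' @describeIn AnnotationIndex accessor for the gene models.
#' @param index an `AnnotationIndex`.
#' @export
annotationGenes <- function(index) index@genes

# 0-based midpoint of 1-based closed ranges: floor((start0 + end)/2)
region_midpoint0 <- function(gr) {
  (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
}

#' Annotate regions to gene models
#'
#' Assigns each region a single category by testing its midpoint with the
#' precedence promoter > TTS ("other") > gene body > intergenic. Ties among
#' genes within the winning category are broken by smallest absolute TSS
#' distance, then lexicographic `gene_id`, so the assignment is deterministic.
#' The signed `tss_distance` is measured from the region midpoint to the
#' assigned gene's TSS in the gene's reading direction.
#'
#' @param regions `GRanges` to annotate.
#' @param index an [AnnotationIndex].
#' @return data.frame with one row per region: `region_id`, `category`
#'   (`promoter`, `tts_other`, `gene_body`, `intergenic`), `gene_id`
#'   (`NA` iff intergenic) and `tss_distance`.
#' @export
annotateRegions <- function(regions, index) {
  stopifnot(methods::is(index, "AnnotationIndex"))
  genes <- index@genes
  sl <- GenomeInfoDb::seqlengths(regions)
  if (!all(is.na(sl))) {
    idx <- match(as.character(GenomicRanges::seqnames(regions)), names(sl))
    bad <- !is.na(sl[idx]) & GenomicRanges::end(regions) > sl[idx]
    if (any(bad)) stop("region outside genome: ", regionId(regions[bad][1L]))
  }

  mid0 <- region_midpoint0(regions)
  n <- length(regions)
  gid <- as.character(S4Vectors::mcols(genes)$gene_id)
  pos <- as.character(GenomicRanges::strand(genes)) == "+"
  gs0 <- GenomicRanges::start(genes) - 1L
  ge <- GenomicRanges::end(genes)
  tss0 <- ifelse(pos, gs0, ge - 1L)
  tes0 <- ifelse(pos, ge - 1L, gs0)

  # candidate (region, gene) pairs: genes on the same chromosome whose
  # maximal window could contain the midpoint
  reach <- max(index@promoterUp, index@promoterDown,
               index@ttsUp, index@ttsDown)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(genes) - as.integer(reach)),
                     GenomicRanges::end(genes) + as.integer(reach)))
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(regions),
                                 IRanges::IRanges(mid0 + 1L, mid0 + 1L))
  GenomeInfoDb::seqlevels(mids) <- GenomeInfoDb::seqlevels(win)
  hits <- GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  d_tss <- ifelse(pos[sh], mid0[qh] - tss0[sh], tss0[sh] - mid0[qh])
  d_tes <- ifelse(pos[sh], mid0[qh] - tes0[sh], tes0[sh] - mid0[qh])
  in_prom <- d_tss >= -index@promoterUp & d_tss < index@promoterDown
  in_tts <- d_tes >= -index@ttsUp & d_tes < index@ttsDown
  in_body <- mid0[qh] >= gs0[sh] & mid0[qh] < ge[sh]
  # precedence encoded as a rank: 1 promoter, 2 tts_other, 3 gene_body
  rank <- ifelse(in_prom, 1L, ifelse(in_tts, 2L, ifelse(in_body, 3L, NA)))

  out <- data.frame(region_id = regionId(regions),
                    category = rep("intergenic", n),
                    gene_id = NA_character_,
                    tss_distance = NA_integer_,
                    stringsAsFactors = FALSE)
  keep <- !is.na(rank)
  if (any(keep)) {
    cand <- data.frame(q = qh[keep], g = sh[keep], rank = rank[keep],
                       d = d_tss[keep])
    ord <- order(cand$q, cand$rank, abs(cand$d), gid[cand$g])
    cand <- cand[ord, , drop = FALSE]
    best <- cand[!duplicated(cand$q), , drop = FALSE]
    cats <- c("promoter", "tts_other", "gene_body")
    out$category[best$q] <- cats[best$rank]
    out$gene_id[best$q] <- gid[best$g]
    out$tss_distance[best$q] <- best$d
  }
  out
}

#' Category distribution of annotated regions
#'
#' @param annotations data.frame from [annotateRegions()], or a character
#'   vector of categories.
#' @return list with integer `counts` and `fractions` summing to 1 over the
#'   four categories.
#' @export
annotationDistribution <- function(annotations) {
  cats <- if (is.data.frame(annotations)) annotations$category else annotations
  if (length(cats) == 0L) stop("no regions")
  lev <- c("promoter", "gene_body", "tts_other", "intergenic")
  bad <- setdiff(unique(cats), lev)
  if (length(bad)) stop("unknown category: ", bad[1L])
  counts <- table(factor(cats, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  list(counts = counts, fractions = counts / sum(counts))
}

#' Average signal profile over scaled regions
#'
#' Computes a metagene-style profile: each region's body is linearly rescaled
#' to `bodyPoints` sampling positions, flanks of `flankBp` bp are sampled at
#' `flankPoints` fixed-resolution positions on each side, and the profile is
#' the mean signal across regions at each position. Positions outside the
#' covered signal (or the genome) contribute 0.
#'
#' @param signal `GRanges` (typically bins) with a numeric `score` column.
#' @param regions `GRanges`; must be nonempty.
#' @param bodyPoints number of body sampling positions (>= 1).
#' @param flankBp flank extent in bp.
#' @param flankPoints sampling positions per flank.
#' @return numeric vector of length `flankPoints + bodyPoints + flankPoints`.
#' @export
metageneProfile <- function(signal, regions, bodyPoints = 50L,
                            flankBp = 2000L, flankPoints = 20L) {
  if (length(regions) == 0L) stop("regions must be nonempty")
  if (bodyPoints < 1) stop("bodyPoints must be >= 1")
  score <- S4Vectors::mcols(signal)$score
  if (is.null(score)) stop("signal must carry a 'score' column")

  s0 <- GenomicRanges::start(regions) - 1L
  e <- GenomicRanges::end(regions)
  w <- e - s0
  up <- outer(rep(1, length(regions)), (seq_len(flankPoints) - 0.5) *
                flankBp / max(flankPoints, 1L)) - flankBp + s0
  body <- s0 + outer(w, (seq_len(bodyPoints) - 0.5) / bodyPoints)
  down <- outer(rep(1, length(regions)), (seq_len(flankPoints) - 0.5) *
                  flankBp / max(flankPoints, 1L)) + e
  pos0 <- floor(cbind(up, body, down))   # 0-based base positions
  npt <- ncol(pos0)

  chrom <- rep(as.character(GenomicRanges::seqnames(regions)), npt)
  p1 <- as.integer(pos0) + 1L
  ok <- p1 >= 1L
  sl <- GenomeInfoDb::seqlengths(signal)
  if (!all(is.na(sl))) {
    lim <- sl[chrom]
    ok <- ok & (is.na(lim) | p1 <= lim)
  }
  vals <- numeric(length(p1))
  if (any(ok)) {
    pts <- GenomicRanges::GRanges(chrom[ok], IRanges::IRanges(p1[ok], p1[ok]))
    GenomeInfoDb::seqlevels(pts) <- GenomeInfoDb::seqlevels(signal)
    hits <- GenomicRanges::findOverlaps(pts, signal, ignore.strand = TRUE)
    v <- numeric(sum(ok))
    v[S4Vectors::queryHits(hits)] <- score[S4Vectors::subjectHits(hits)]
    vals[ok] <- v
  }
  colMeans(matrix(vals, ncol = npt))
}
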