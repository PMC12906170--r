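suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# Independent oracles used across the suite. All deliberately naive:
# per-base boolean masks for interval arithmetic, explicit loops and
# enumeration elsewhere, so they share no code path with the package.

# per-base coverage mask of GRanges over a small genome (named lengths)
coverage_mask <- function(gr, chromLengths) {
  masks <- lapply(names(chromLengths), function(ch) {
    m <- logical(chromLengths[[ch]])
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    for (i in which(sel)) {
      m[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
    }
    m
  })
  names(masks) <- names(chromLengths)
  masks
}

# random intervals on a small genome
random_intervals <- function(n, chromLengths, maxWidth = 400) {
  chrom <- sample(names(chromLengths), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(chromLengths[[chrom[i]]] - w[i], 1L), 1L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1L))
}

# brute-force whole-query intersection: query retained iff any base shared
oracle_intersect <- function(queries, subjects, chromLengths) {
  mask <- coverage_mask(subjects, chromLengths)
  keep <- vapply(seq_along(queries), function(i) {
    ch <- as.character(GenomicRanges::seqnames(queries))[i]
    any(mask[[ch]][GenomicRanges::start(queries)[i]:
                     GenomicRanges::end(queries)[i]])
  }, TRUE)
  queries[keep]
}

# number of maximal TRUE runs in a logical vector
mask_runs <- function(m) {
  r <- rle(m)
  sum(r$values)
}

# Benjamini-Hochberg step-up computed directly from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# median-of-ratios size factors written independently (prod-based geomean)
oracle_size_factors <- function(counts) {
  allpos <- apply(counts, 1L, function(x) all(x > 0))
  k <- counts[allpos, , drop = FALSE]
  geo <- apply(k, 1L, function(x) prod(x)^(1 / length(x)))
  apply(k, 2L, function(col) stats::median(col / geo))
}

# exact hypergeometric upper tail by combinatorial summation
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Pearson r from the definition
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# naive per-region metagene resampling (explicit loops)
oracle_metagene <- function(signal, regions, bodyPoints, flankBp, flankPoints) {
  score_at <- function(ch, pos1) {
    hit <- which(as.character(GenomicRanges::seqnames(signal)) == ch &
                   GenomicRanges::start(signal) <= pos1 &
                   GenomicRanges::end(signal) >= pos1)
    if (length(hit)) S4Vectors::mcols(signal)$score[hit[1L]] else 0
  }
  total <- flankPoints + bodyPoints + flankPoints
  prof <- matrix(0, length(regions), total)
  for (i in seq_along(regions)) {
    ch <- as.character(GenomicRanges::seqnames(regions))[i]
    s0 <- GenomicRanges::start(regions)[i] - 1
    e <- GenomicRanges::end(regions)[i]
    col <- 0L
    for (k in seq_len(flankPoints)) {
      col <- col + 1L
      pos0 <- floor(s0 - flankBp + (k - 0.5) * flankBp / flankPoints)
      prof[i, col] <- if (pos0 < 0) 0 else score_at(ch, pos0 + 1)
    }
    for (k in seq_len(bodyPoints)) {
      col <- col + 1L
      pos0 <- floor(s0 + (k - 0.5) / bodyPoints * (e - s0))
      prof[i, col] <- score_at(ch, pos0 + 1)
    }
    for (k in seq_len(flankPoints)) {
      col <- col + 1L
      pos0 <- floor(e + (k - 0.5) * flankBp / flankPoints)
      prof[i, col] <- score_at(ch, pos0 + 1)
    }
  }
  colMeans(prof)
}

# a tiny annotation fixture reused by several files: two genes on a 20 kb
# chromosome, one per strand
tiny_index <- function() {
  genome <- rloopdiff::genomeDef(c(c1 = 20000L))
  genes <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(2001, 12001), c(5000, 15000)),
    strand = c("+", "-"), seqinfo = genome)
  S4Vectors::mcols(genes)$gene_id <- c("g1", "g2")
  rloopdiff::annotationIndex(genes)
}

gr0 <- function(chrom, start0, end0, genome = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome
  gr
}
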