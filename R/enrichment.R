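#' Read a GMT term annotation
#'
#' @param path GMT file (term, description, genes...).
#' @return named list term -> character gene set.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the query over-represents the term's genes
#' against the background universe: `p = P(X >= k)` for
#' `X ~ Hypergeometric(K, N - K, n)` with overlap `k`, term size `K`, query
#' size `n` and background size `N`. Query genes outside the background are
#' dropped (with a message); term genes are intersected with the background.
#' BH adjustment is applied within the tested term family.
#'
#' @param query character gene set.
#' @param terms named list term -> gene set (e.g. from [readGmt()]).
#' @param background character gene universe.
#' @param fdrMax threshold defining the enriched-term set (default 0.05,
#'   strict `<`).
#' @return data.frame per term (`term`, `k`, `K`, `n`, `N`, `p`, `q`) with
#'   attribute `enriched` holding the `q < fdrMax` term names.
#' @export
hypergeometricEnrichment <- function(query, terms, background,
                                     fdrMax = 0.05) {
  background <- unique(background)
  query <- unique(query)
  dropped <- setdiff(query, background)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the background dropped")
  query <- intersect(query, background)
  if (length(query) == 0L) stop("empty query after background intersection")
  N <- length(background)
  n <- length(query)
  K <- vapply(terms, function(g) length(intersect(g, background)), 1L)
  k <- vapply(terms, function(g) length(intersect(g, query)), 1L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(terms), k = k, K = K, n = n, N = N,
                    p = p, q = bhAdjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "enriched") <- out$term[out$q < fdrMax]
  out
}

#' @describeIn hypergeometricEnrichment extract the enriched-term set.
#' @param enrichment result of `hypergeometricEnrichment`.
#' @export
enrichedTerms <- function(enrichment) attr(enrichment, "enriched")

#' Jaccard index of two term sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#' Used to compare the enriched-term signatures of gene groups.
#'
#' @param termsA,termsB character term sets.
#' @return numeric in `[0, 1]`.
#' @export
jaccardIndex <- function(termsA, termsB) {
  termsA <- unique(termsA); termsB <- unique(termsB)
  u <- length(union(termsA, termsB))
  if (u == 0L) return(0)
  length(intersect(termsA, termsB)) / u
}
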