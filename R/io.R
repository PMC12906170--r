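#' Read a genome definition from a two-column TSV or FASTA index
#'
#' Accepts either a plain `name<TAB>length` table or a `.fai` layout (the
#' first two columns are used in both cases).
#'
#' @param path file path.
#' @return a `Seqinfo` (see [genomeDef()]).
#' @export
readGenomeTsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  genomeDef(setNames(as.integer(tab[[2L]]), tab[[1L]]))
}

#' @describeIn readGenomeTsv write the companion two-column TSV.
#' @param genome a `Seqinfo`.
#' @export
writeGenomeTsv <- function(genome, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(genome),
               GenomeInfoDb::seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write BED intervals
#'
#' Files use 0-based half-open coordinates (BED); in memory the package uses
#' `GRanges` (1-based closed). BED6 `name` columns are exposed as the
#' `gene_id`/`name` metadata column.
#'
#' @param path BED file path.
#' @param genome optional `Seqinfo` to attach.
#' @return `GRanges`.
#' @export
readBed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
  }
  gr
}

#' @describeIn readBed write ranges as BED (names become column 4).
#' @param gr `GRanges` to write.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from BED6
#'
#' @param path BED6 file (name = gene id, strand required).
#' @param genome optional `Seqinfo`.
#' @return `GRanges` with metadata column `gene_id`.
#' @export
readGenesBed <- function(path, genome = NULL) {
  gr <- readBed(path, genome)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("gene BED must carry names (column 4)")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = nm)
  gr
}

#' Read/write count tables (feature_id + one column per sample)
#'
#' @param path TSV path.
#' @return integer matrix with feature rownames.
#' @export
readCountsTsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' @describeIn readCountsTsv writer.
#' @param counts matrix with feature rownames.
#' @export
writeCountsTsv <- function(counts, path) {
  tab <- data.frame(feature_id = rownames(counts), counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the sample design table
#'
#' @param path TSV with columns sample, genotype, condition, replicate, group.
#' @return data.frame.
#' @export
readDesignTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @describeIn readDesignTsv writer.
#' @param design data.frame.
#' @export
writeDesignTsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a term map as GMT
#'
#' @param terms named list term -> gene set.
#' @param path output path.
#' @export
writeGmt <- function(terms, path) {
  lines <- vapply(names(terms), function(t)
    paste(c(t, "na", terms[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
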