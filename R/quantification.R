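#' @include AllClasses.R annotation.R
#' @importFrom GenomicRanges GRanges width start end strand seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom stats setNames
NULL

#' FPKM from a read count
#'
#' Reads (fragments) per kilobase of exon model per million mapped reads:
#' \code{count * 1e9 / (length * librarySize)}, with the gene length taken as
#' the union-exon length (each exonic base counted once across isoforms).
#' Vectorised over its arguments with the usual recycling.
#'
#' @param count non-negative read count(s).
#' @param length gene length(s) in nt, positive.
#' @param librarySize total mapped reads, positive.
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
#' @export
fpkm <- function(count, length, librarySize) {
  # double arithmetic: integer length * librarySize would overflow
  count <- as.numeric(count)
  length <- as.numeric(length)
  librarySize <- as.numeric(librarySize)
  if (any(length <= 0)) stop("gene length must be positive")
  if (any(librarySize <= 0)) stop("library size must be positive")
  if (any(count < 0)) stop("read counts must be non-negative")
  count * 1e9 / (length * librarySize)
}

#' FPKM matrix from per-cell count tables
#'
#' Element-wise application of \code{\link{fpkm}} to a gene-by-cell count
#' matrix. Every gene must have a length; a missing gene is an error, never a
#' silent zero.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), cells
#'   in columns (colnames = cell ids).
#' @param lengths named numeric vector of union-exon lengths (nt).
#' @param librarySizes total mapped reads per cell: a single number or a
#'   vector of one value per column of \code{counts}.
#' @return A \code{SummarizedExperiment} with one assay \code{"fpkm"}.
#' @export
fpkmMatrix <- function(counts, lengths, librarySizes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("count matrix must have gene ids as rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("gene(s) missing from lengths: ", paste(missing, collapse = ", "))
  if (length(librarySizes) == 1L)
    librarySizes <- rep(librarySizes, ncol(counts))
  if (length(librarySizes) != ncol(counts))
    stop("librarySizes must have one value per cell")
  if (any(librarySizes <= 0)) stop("library size must be positive")
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene length must be positive")
  if (any(counts < 0)) stop("read counts must be non-negative")
  mat <- counts * 1e9
  mat <- sweep(mat, 1, len, "/")
  mat <- sweep(mat, 2, librarySizes, "/")
  SummarizedExperiment(assays = list(fpkm = mat))
}

#' Partition a gene's exons by overlap with an opposite-strand gene
#'
#' For a target gene overlapped by a gene on the opposite strand, splits the
#' target's union exons into the region shared with the antisense gene's
#' exons (where reads are strand-ambiguous in non-strand-specific data) and
#' the exclusive remainder. Only exonic intersections count as ambiguous.
#'
#' @param target,antisense \code{GRanges} of the two genes' union exons
#'   (stranded); same chromosome, opposite strands.
#' @return A list with \code{exclusive} and \code{ambiguous} \code{GRanges}
#'   plus their total widths \code{exclusive_nt} and \code{ambiguous_nt}.
#' @export
ambiguityPartition <- function(target, antisense) {
  if (!length(target)) stop("target gene has no exons")
  tchr <- unique(as.character(seqnames(target)))
  achr <- unique(as.character(seqnames(antisense)))
  if (length(tchr) != 1L || length(achr) != 1L || tchr != achr)
    stop("target and antisense genes must lie on a single shared chromosome")
  tstr <- unique(as.character(strand(target)))
  astr <- unique(as.character(strand(antisense)))
  if (length(tstr) != 1L || length(astr) != 1L || tstr == astr)
    stop("ambiguity convention applies to opposite-strand gene pairs only")
  amb <- GenomicRanges::intersect(target, antisense, ignore.strand = TRUE)
  excl <- GenomicRanges::setdiff(target, antisense, ignore.strand = TRUE)
  list(
    exclusive = excl, ambiguous = amb,
    exclusive_nt = sum(width(excl)), ambiguous_nt = sum(width(amb))
  )
}

#' Under/over FPKM bounds for an antisense-overlapped gene
#'
#' In non-strand-specific RNA-seq, reads falling in exonic regions shared
#' between a gene and an opposite-strand gene cannot be assigned a strand.
#' The gene's expression is therefore reported as a pair of bounds: the
#' underestimated FPKM excludes the ambiguous reads, the overestimated FPKM
#' includes them. Both bounds divide by the full union-exon length of the
#' target gene, so the underestimate is a true lower bound under the fixed
#' gene model. \code{under <= over} always, with equality iff no ambiguous
#' reads.
#'
#' @param target,antisense \code{GRanges} of union exons (see
#'   \code{\link{ambiguityPartition}}).
#' @param countExclusive reads in the exclusive region of the target.
#' @param countAmbiguous reads in the shared region.
#' @param librarySize total mapped reads.
#' @return A list with \code{under}, \code{over} (FPKM) and the
#'   \code{partition}.
#' @export
ambiguityBounds <- function(target, antisense, countExclusive, countAmbiguous,
                            librarySize) {
  if (countExclusive < 0 || countAmbiguous < 0)
    stop("read counts must be non-negative")
  part <- ambiguityPartition(target, antisense)
  len <- sum(width(GenomicRanges::reduce(target)))
  list(
    under = fpkm(countExclusive, len, librarySize),
    over = fpkm(countExclusive + countAmbiguous, len, librarySize),
    partition = part
  )
}

#' Export an ambiguity partition as BED
#'
#' Writes the exclusive and ambiguous intervals in BED format (0-based
#' half-open; coordinates are converted at this boundary), with the region
#' class in the name column, so external read counters can assign reads to
#' the two regions.
#'
#' @param partition result of \code{\link{ambiguityPartition}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePartitionBed <- function(partition, path) {
  bedLine <- function(gr, label) {
    if (!length(gr)) return(character(0))
    paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr), label,
          sep = "\t")
  }
  writeLines(c(bedLine(partition$exclusive, "exclusive"),
               bedLine(partition$ambiguous, "ambiguous")), path)
  invisible(path)
}

#' Read an FPKM matrix TSV
#'
#' Genes in rows, cells in columns; the first column holds gene ids.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and cell colnames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  if (any(is.na(mat))) stop("expression matrix contains missing values: ", path)
  if (any(mat < 0)) stop("expression matrix contains negative values: ", path)
  mat
}

#' Write an FPKM matrix TSV
#'
#' @param mat numeric matrix or \code{SummarizedExperiment} with an
#'   \code{"fpkm"} assay.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
  mat <- .asFpkmMatrix(mat)
  df <- data.frame(gene_id = rownames(mat), signif(mat, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## accept a plain matrix or a SummarizedExperiment with an "fpkm" assay
.asFpkmMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    x <- if ("fpkm" %in% nm) assay(x, "fpkm") else assay(x, 1)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}
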