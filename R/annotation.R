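#' @include AllClasses.R AllGenerics.R
#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
NULL

## extract one attribute from GTF column 9, accepting both the
## `key "value";` dialect and the `key=value` dialect
.extractAttr <- function(attrs, key) {
  out <- rep(NA_character_, length(attrs))
  pat1 <- paste0('(^|; ?)', key, ' +"([^"]*)"')
  hit1 <- grepl(pat1, attrs)
  out[hit1] <- sub(paste0('.*(^|; ?)', key, ' +"([^"]*)".*'), "\\2",
                   attrs[hit1])
  pat2 <- paste0('(^|; ?)', key, ' *= *"?([^";]+)"?')
  hit2 <- !hit1 & grepl(pat2, attrs)
  out[hit2] <- sub(paste0('.*(^|; ?)', key, ' *= *"?([^";]+)"?.*'), "\\2",
                   attrs[hit2])
  out
}

#' Read a GTF file into a GeneAnnotation
#'
#' Parses exon records from a GTF file (9 tab-separated fields, 1-based
#' inclusive coordinates), groups them by transcript and gene, and computes
#' the union-exon length of every gene (each exonic base counted once across
#' all isoforms). Non-exon features are ignored for length computation.
#' Attribute parsing accepts both the \code{key "value";} GTF dialect and the
#' \code{key=value} dialect; unknown attributes are ignored. Duplicate exon
#' records (same transcript and coordinates) are deduplicated with a warning.
#'
#' @param path path to a GTF file.
#' @return A \linkS4class{GeneAnnotation}; biotypes are \code{NA} until
#'   \code{\link{classifyBiotype}} is run.
#' @seealso \code{\link{classifyBiotype}}, \code{\link{filterMinLength}},
#'   \code{\link{writeGtf}}
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "11", "20", ".", "+", ".",
#'   'gene_id "g1"; transcript_id "NM_000001";', sep = "\t"), gtf)
#' parseGtf(gtf)
#' @export
parseGtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) stop("GTF file contains no feature lines: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF: expected 9 tab-separated fields at line ",
         lineno[which(nf != 9L)[1]])
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)

  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- is.na(start) | is.na(end) | end < start | start < 1L
  if (any(bad))
    stop("malformed GTF: invalid coordinates at line ", lineno[which(bad)[1]])
  strand <- m[, 7]
  badStrand <- !strand %in% c("+", "-")
  if (any(badStrand))
    stop("malformed GTF: strand must be '+' or '-' at line ",
         lineno[which(badStrand)[1]])

  isExon <- m[, 3] == "exon"
  if (!any(isExon)) stop("GTF file contains no exon features: ", path)
  attrs <- m[isExon, 9]
  gid <- .extractAttr(attrs, "gene_id")
  tid <- .extractAttr(attrs, "transcript_id")
  miss <- is.na(gid) | is.na(tid)
  if (any(miss))
    stop("malformed GTF: exon record lacks gene_id or transcript_id at line ",
         lineno[isExon][which(miss)[1]])
  gname <- .extractAttr(attrs, "gene_name")
  gname[is.na(gname)] <- gid[is.na(gname)]
  srcClass <- .extractAttr(attrs, "gene_biotype")
  srcClass[is.na(srcClass)] <- m[isExon, 2][is.na(srcClass)]

  ex <- data.frame(
    chrom = m[isExon, 1], start = start[isExon], end = end[isExon],
    strand = strand[isExon], gene_id = gid, transcript_id = tid,
    gene_name = gname, source_class = srcClass,
    stringsAsFactors = FALSE
  )

  dup <- duplicated(ex[, c("transcript_id", "chrom", "start", "end", "strand")])
  if (any(dup)) {
    warning(sum(dup), " duplicate exon record(s) deduplicated")
    ex <- ex[!dup, , drop = FALSE]
  }

  ## per-transcript consistency: one chromosome, one strand, disjoint exons
  byTx <- split(seq_len(nrow(ex)), ex$transcript_id)
  for (ii in byTx) {
    if (length(unique(ex$chrom[ii])) > 1L ||
        length(unique(ex$strand[ii])) > 1L)
      stop("transcript ", ex$transcript_id[ii[1]],
           " has exons on multiple chromosomes or strands")
    o <- order(ex$start[ii])
    s <- ex$start[ii][o]; e <- ex$end[ii][o]
    if (length(s) > 1L && any(s[-1] <= e[-length(e)]))
      stop("transcript ", ex$transcript_id[ii[1]],
           " has overlapping exons within one isoform")
  }

  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  mcols(exons)$gene_id <- ex$gene_id
  mcols(exons)$transcript_id <- ex$transcript_id
  mcols(exons)$gene_name <- ex$gene_name
  mcols(exons)$source_class <- ex$source_class

  .buildGeneAnnotation(exons)
}

.buildGeneAnnotation <- function(exons) {
  gid <- mcols(exons)$gene_id
  ids <- sort(unique(gid))
  ul <- unionExonLength(exons)
  first <- match(ids, gid)
  gchrom <- as.character(GenomicRanges::seqnames(exons))[first]
  gstrand <- as.character(GenomicRanges::strand(exons))[first]
  ## a gene must live on one chromosome/strand
  agg <- tapply(paste(as.character(GenomicRanges::seqnames(exons)),
                      as.character(GenomicRanges::strand(exons))),
                gid, function(z) length(unique(z)))
  if (any(agg > 1L))
    stop("gene ", names(agg)[which(agg > 1L)[1]],
         " has exons on multiple chromosomes or strands")
  genes <- DataFrame(
    gene_id = ids,
    gene_name = mcols(exons)$gene_name[first],
    chrom = gchrom,
    strand = gstrand,
    union_length = as.integer(ul[ids]),
    biotype = rep(NA_character_, length(ids)),
    biotype_reason = rep(NA_character_, length(ids))
  )
  new("GeneAnnotation", exons = exons, genes = genes)
}

#' Union-exon gene length
#'
#' Length of the merged exon set of each gene: the total number of bases
#' covered by at least one exon of any isoform, each base counted at most
#' once. This is the gene length used in the FPKM denominator.
#'
#' @param object a \linkS4class{GeneAnnotation}, or a \code{GRanges} of exons
#'   carrying a \code{gene_id} metadata column.
#' @return Named integer vector of union-exon lengths (nt) per gene.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 51), c(100, 150)), strand = "+")
#' S4Vectors::mcols(gr)$gene_id <- "g"
#' unionExonLength(gr)  # 150: [1,100] and [51,150] merge
#' @export
unionExonLength <- function(object) {
  exons <- if (is(object, "GeneAnnotation")) object@exons else object
  if (!length(exons)) return(setNames(integer(0), character(0)))
  red <- GenomicRanges::reduce(
    GenomicRanges::split(exons, mcols(exons)$gene_id)
  )
  lens <- sum(GenomicRanges::width(red))
  setNames(as.integer(lens), names(lens))
}

#' Classify genes as coding, noncoding or excluded
#'
#' Applies RefSeq accession-prefix rules: a gene is coding if any transcript
#' carries the prefix NM_, XM_, NP_ or XP_; it is noncoding if any transcript
#' carries NR_ or XR_ or is annotated as lincRNA, and no coding trigger
#' applies. A noncoding-evidenced gene is reclassified coding when a
#' read-through into a coding gene is possible, operationalised as any exonic
#' same-strand overlap with a coding-evidenced gene (the partner is named in
#' the audit reason). Genes with no recognised evidence are excluded rather
#' than guessed. The result is deterministic and invariant to gene order.
#'
#' @param object a \linkS4class{GeneAnnotation}.
#' @return The annotation with \code{biotype} and \code{biotype_reason}
#'   columns filled in.
#' @export
classifyBiotype <- function(object) {
  stopifnot(is(object, "GeneAnnotation"))
  exons <- object@exons
  genes <- object@genes
  tid <- mcols(exons)$transcript_id
  srcClass <- mcols(exons)$source_class
  gid <- mcols(exons)$gene_id

  codingTx <- grepl("^(NM_|XM_|NP_|XP_)", tid)
  ncTx <- grepl("^(NR_|XR_)", tid) | srcClass == "lincRNA"

  hasCoding <- tapply(codingTx, gid, any)[genes$gene_id]
  hasNc <- tapply(ncTx, gid, any)[genes$gene_id]

  ## same-strand exonic overlap of noncoding-evidenced genes with
  ## coding-evidenced genes (read-through possibility)
  ue <- unionExons(object)
  flat <- unlist(ue)
  flatGene <- rep(names(ue), lengths(ue))
  codingGene <- genes$gene_id[hasCoding]
  ov <- findOverlaps(flat, flat[flatGene %in% codingGene],
                     ignore.strand = FALSE)
  qg <- flatGene[queryHits(ov)]
  sg <- flatGene[flatGene %in% codingGene][subjectHits(ov)]
  partner <- tapply(sg[qg != sg], qg[qg != sg],
                    function(z) sort(unique(z))[1])

  biotype <- character(nrow(genes))
  reason <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    if (hasCoding[i] && hasNc[i]) {
      biotype[i] <- "coding"
      reason[i] <- "coding accession prefix present alongside noncoding evidence; resolved to coding"
    } else if (hasCoding[i]) {
      biotype[i] <- "coding"
      reason[i] <- "RefSeq coding accession prefix (NM_/XM_/NP_/XP_)"
    } else if (hasNc[i]) {
      p <- if (!is.null(partner) && g %in% names(partner)) partner[[g]] else NA
      if (!is.null(p) && !is.na(p)) {
        biotype[i] <- "coding"
        reason[i] <- paste0("possible read-through: same-strand exonic overlap with coding gene ", p)
      } else {
        biotype[i] <- "noncoding"
        reason[i] <- "RefSeq noncoding prefix (NR_/XR_) or lincRNA annotation; no same-strand overlap with a coding gene"
      }
    } else {
      biotype[i] <- "excluded"
      reason[i] <- "no recognised coding or noncoding evidence"
    }
  }
  genes$biotype <- biotype
  genes$biotype_reason <- reason
  initialize(object, genes = genes)
}

#' Filter genes by union-exon length
#'
#' Retains genes whose union-exon length is strictly greater than
#' \code{minLen} (default 200 nt, the conventional lncRNA length bound; a
#' gene of exactly 200 nt is removed).
#'
#' @param object a \linkS4class{GeneAnnotation}.
#' @param minLen minimum length in nt (exclusive).
#' @return The filtered \linkS4class{GeneAnnotation}.
#' @export
filterMinLength <- function(object, minLen = 200) {
  stopifnot(is(object, "GeneAnnotation"))
  keep <- object@genes$union_length > minLen
  ids <- object@genes$gene_id[keep]
  exKeep <- mcols(object@exons)$gene_id %in% ids
  initialize(object, exons = object@exons[exKeep],
             genes = object@genes[keep, , drop = FALSE])
}

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneAnnotation", function(object) object@genes$gene_id)

#' @rdname accessors
#' @export
setMethod("geneTable", "GeneAnnotation", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("unionLengths", "GeneAnnotation", function(object)
  setNames(object@genes$union_length, object@genes$gene_id))

#' @rdname accessors
#' @export
setMethod("biotypes", "GeneAnnotation", function(object)
  setNames(object@genes$biotype, object@genes$gene_id))

#' @rdname accessors
#' @export
setMethod("exonRanges", "GeneAnnotation", function(object) object@exons)

#' @rdname accessors
#' @param gene optional gene id; if given, the merged exons of that gene are
#'   returned as a \code{GRanges}, otherwise a \code{GRangesList} over genes.
setMethod("unionExons", "GeneAnnotation", function(object, gene = NULL) {
  red <- GenomicRanges::reduce(
    GenomicRanges::split(object@exons, mcols(object@exons)$gene_id)
  )
  if (is.null(gene)) return(red)
  if (!gene %in% names(red)) stop("unknown gene id: ", gene)
  red[[gene]]
})

#' @rdname accessors
setMethod("unionExons", "GRanges", function(object, gene = NULL) {
  red <- GenomicRanges::reduce(
    GenomicRanges::split(object, mcols(object)$gene_id)
  )
  if (is.null(gene)) red else red[[gene]]
})

#' Write the per-gene table as TSV
#'
#' Columns: gene_id, gene_name, chrom, strand, union_length, biotype,
#' biotype_reason.
#'
#' @param object a \linkS4class{GeneAnnotation}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeGeneTable <- function(object, path) {
  stopifnot(is(object, "GeneAnnotation"))
  utils::write.table(as.data.frame(object@genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene table TSV
#'
#' @param path a TSV written by \code{\link{writeGeneTable}} (or any table
#'   with at least gene_id and biotype columns).
#' @return A data.frame.
#' @export
readGeneTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "biotype") %in% colnames(df)))
    stop("gene table must have gene_id and biotype columns: ", path)
  df
}

#' Write a GeneAnnotation back to GTF
#'
#' Emits one exon line per exon record, in the \code{key "value";} dialect,
#' carrying gene_id, transcript_id, gene_name and gene_biotype. Round-trips
#' through \code{\link{parseGtf}}.
#'
#' @param object a \linkS4class{GeneAnnotation}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeGtf <- function(object, path) {
  stopifnot(is(object, "GeneAnnotation"))
  ex <- object@exons
  mc <- mcols(ex)
  lines <- paste(
    as.character(GenomicRanges::seqnames(ex)), "hetflag", "exon",
    GenomicRanges::start(ex), GenomicRanges::end(ex), ".",
    as.character(GenomicRanges::strand(ex)), ".",
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
            mc$gene_id, mc$transcript_id, mc$gene_name, mc$source_class),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
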