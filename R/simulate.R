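#' @include AllClasses.R quantification.R
#' @importFrom stats rnorm runif rbinom plnorm qlnorm pnorm
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Construct a SimulationSpec
#'
#' Defaults plant the study regime: 96 cells, 2000 genes per biotype,
#' high-heterogeneity probability 0.74 for lncRNAs and 0.35 for mRNAs among
#' moderately expressed genes. The class distributions of expressing-cell
#' counts scale with the cell count — the high-heterogeneity class is centred
#' at 5% of cells (at least 2), the low class at 75% — keeping the two
#' populations well separated at every dataset size used in practice
#' (36 to 96 cells).
#'
#' @param nCells,nLnc,nMrna dataset dimensions.
#' @param pHighLnc,pHighMrna planted per-biotype high-heterogeneity
#'   probabilities for moderate-expression genes.
#' @param nHighMean,nHighSd,nLowMean,nLowSd class distributions of N
#'   (Gaussian on integers, rounded and clamped to [1, nCells]).
#' @param pBright fraction of genes whose maximum FPKM exceeds 30.
#' @param brightHighScale multiplier on pHigh* for bright genes.
#' @param brightNHighMean,brightNHighSd,brightNLowMean,brightNLowSd class N
#'   distributions for bright genes; defaults place them in more cells than
#'   moderate genes (abundance couples with breadth of expression), so the
#'   high-expression stratum shows lower cell-to-cell variation.
#' @param magMeanLog,magSdLog log-normal FPKM model for positive cells of
#'   moderate genes, truncated to (3, 30].
#' @param brightMagMeanLog log-normal location for bright genes, truncated to
#'   (3, 300].
#' @param backgroundNoise sub-threshold uniform noise in (0, 3) for
#'   non-expressing cells instead of exact zeros.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(nCells = 96L, nLnc = 2000L, nMrna = 2000L,
                           pHighLnc = 0.74, pHighMrna = 0.35,
                           nHighMean = max(2, round(0.05 * nCells)),
                           nHighSd = max(1, 0.3 * nHighMean),
                           nLowMean = round(0.75 * nCells),
                           nLowSd = max(2, 0.1 * nLowMean),
                           pBright = 0.2, brightHighScale = 0.5,
                           brightNHighMean = max(4, round(0.15 * nCells)),
                           brightNHighSd = max(1.5, 0.3 * brightNHighMean),
                           brightNLowMean = round(0.92 * nCells),
                           brightNLowSd = max(1.5, 0.04 * nCells),
                           magMeanLog = log(8), magSdLog = 0.5,
                           brightMagMeanLog = log(45),
                           backgroundNoise = FALSE, seed = 1L) {
  new("SimulationSpec",
    nCells = as.integer(nCells), nLnc = as.integer(nLnc),
    nMrna = as.integer(nMrna),
    pHighLnc = pHighLnc, pHighMrna = pHighMrna,
    nHighMean = nHighMean, nHighSd = nHighSd,
    nLowMean = nLowMean, nLowSd = nLowSd,
    pBright = pBright, brightHighScale = brightHighScale,
    brightNHighMean = brightNHighMean, brightNHighSd = brightNHighSd,
    brightNLowMean = brightNLowMean, brightNLowSd = brightNLowSd,
    magMeanLog = magMeanLog, magSdLog = magSdLog,
    brightMagMeanLog = brightMagMeanLog,
    backgroundNoise = backgroundNoise, seed = as.integer(seed)
  )
}

## truncated log-normal sampler via inverse-CDF; lo exclusive, hi inclusive
.rtrunclnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  u <- runif(n, plo, phi)
  pmin(qlnorm(u, meanlog, sdlog), hi)
}

#' Simulate a single-cell FPKM matrix with planted ground truth
#'
#' For each gene: the expression regime (moderate or bright) and the
#' heterogeneity class (high or low) are drawn from the spec's planted
#' probabilities; the expressing-cell count N is drawn from the class
#' Gaussian, rounded and clamped to [1, nCells]; N cells are chosen uniformly
#' without replacement and given truncated log-normal FPKM magnitudes above
#' the positivity threshold; all other cells get exact zeros (or optional
#' sub-threshold noise), emulating single-cell dropout. The emitted matrix is
#' consistent with the truth table: recomputing N at threshold 3 reproduces
#' the planted N exactly. Deterministic given the spec (including its seed).
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return A \code{SummarizedExperiment} with assay \code{"fpkm"} and the
#'   truth in \code{rowData} (biotype, true_class, regime, true_N,
#'   positive_cells as a comma-joined string); the spec is kept in
#'   \code{metadata()$spec}.
#' @export
simulateMatrix <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  nc <- spec@nCells

  ## refuse class distributions that mostly miss [1, nCells]
  pOut <- function(m, s) pnorm(0.5, m, s) + (1 - pnorm(nc + 0.5, m, s))
  if (pOut(spec@nHighMean, spec@nHighSd) > 0.5 ||
      pOut(spec@nLowMean, spec@nLowSd) > 0.5)
    stop("class N distributions place more than half their mass outside [1, nCells]")

  set.seed(spec@seed)
  ng <- spec@nLnc + spec@nMrna
  biotype <- c(rep("lncRNA", spec@nLnc), rep("mRNA", spec@nMrna))
  geneId <- sprintf("%s_%05d", ifelse(biotype == "lncRNA", "LNC", "MRNA"),
                    seq_len(ng))
  cellId <- sprintf("cell_%03d", seq_len(nc))

  bright <- runif(ng) < spec@pBright
  pHigh <- ifelse(biotype == "lncRNA", spec@pHighLnc, spec@pHighMrna)
  pHigh[bright] <- pHigh[bright] * spec@brightHighScale
  highClass <- runif(ng) < pHigh

  muN <- ifelse(highClass,
                ifelse(bright, spec@brightNHighMean, spec@nHighMean),
                ifelse(bright, spec@brightNLowMean, spec@nLowMean))
  sdN <- ifelse(highClass,
                ifelse(bright, spec@brightNHighSd, spec@nHighSd),
                ifelse(bright, spec@brightNLowSd, spec@nLowSd))
  N <- pmin(pmax(as.integer(round(rnorm(ng, muN, sdN))), 1L), nc)

  thr <- 3
  mat <- matrix(0, nrow = ng, ncol = nc, dimnames = list(geneId, cellId))
  posCells <- character(ng)
  for (i in seq_len(ng)) {
    cells <- sample.int(nc, N[i])
    if (bright[i]) {
      mag <- .rtrunclnorm(N[i], spec@brightMagMeanLog, spec@magSdLog,
                          thr + 0.01, 300)
      ## the regime is defined by the maximum: force the top cell above 30
      if (max(mag) <= 30) mag[which.max(mag)] <- runif(1, 30.1, 300)
    } else {
      mag <- .rtrunclnorm(N[i], spec@magMeanLog, spec@magSdLog,
                          thr + 0.01, 30)
    }
    mat[i, cells] <- mag
    posCells[i] <- paste(cellId[sort(cells)], collapse = ",")
  }
  if (spec@backgroundNoise) {
    zero <- mat == 0
    mat[zero] <- runif(sum(zero), 0, thr - 0.01)
  }

  truth <- DataFrame(
    gene_id = geneId, biotype = biotype,
    true_class = ifelse(highClass, "high", "low"),
    regime = ifelse(bright, "bright", "moderate"),
    true_N = N, positive_cells = posCells
  )
  se <- SummarizedExperiment(assays = list(fpkm = mat), rowData = truth)
  S4Vectors::metadata(se)$spec <- spec
  se
}

#' Invert FPKM into per-cell read counts
#'
#' Produces the integer count matrix whose FPKM, at the given union-exon
#' lengths and library size, rounds back to the target matrix:
#' \code{counts = round(fpkm * length * librarySize / 1e9)}. The round-trip
#' error through \code{\link{fpkmMatrix}} is bounded per entry by the
#' analytic rounding bound \code{1e9 / (2 * length * librarySize)}.
#'
#' @param targets gene-by-cell FPKM matrix or \code{SummarizedExperiment}.
#' @param lengths named vector of union-exon lengths (nt), positive, covering
#'   all genes.
#' @param librarySize total mapped reads per cell (scalar or per-cell vector).
#' @return Integer count matrix with the same dimnames.
#' @export
simulateCounts <- function(targets, lengths, librarySize) {
  m <- .asFpkmMatrix(targets)
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    stop("gene(s) missing from lengths: ", paste(missing, collapse = ", "))
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stop("gene length must be positive")
  if (length(librarySize) == 1L) librarySize <- rep(librarySize, ncol(m))
  cnt <- sweep(m * 1e-9, 1, len, "*")
  cnt <- round(sweep(cnt, 2, librarySize, "*"))
  storage.mode(cnt) <- "integer"
  cnt
}

#' Simulate a small gene annotation
#'
#' Generates random gene models for exercising the annotation module:
#' genes with 1-4 isoforms of 1-8 exons each, a mix of RefSeq coding (NM_)
#' and noncoding (NR_/XR_) accessions, lincRNA-labelled and unrecognised
#' transcripts, plus occasional same-strand overlaps between a noncoding and
#' a coding gene (read-through candidates). Deterministic given the seed.
#'
#' @param nGenes number of genes.
#' @param seed integer RNG seed.
#' @return A \linkS4class{GeneAnnotation} (biotypes unclassified).
#' @export
simulateAnnotation <- function(nGenes = 50L, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  cursorByChrom <- setNames(rep(1000L, 3), paste0("chr", 1:3))
  prevGene <- NULL
  for (g in seq_len(nGenes)) {
    chrom <- sample(names(cursorByChrom), 1L)
    strand <- sample(c("+", "-"), 1L)
    kind <- sample(c("coding", "noncoding", "lincRNA", "unknown", "mixed"),
                   1L, prob = c(0.4, 0.25, 0.15, 0.1, 0.1))
    ## occasionally park a noncoding gene on top of the previous coding gene
    readThrough <- kind %in% c("noncoding", "lincRNA") &&
      !is.null(prevGene) && prevGene$chrom == chrom && runif(1) < 0.5
    if (readThrough) {
      gStart <- prevGene$start + 50L
      strand <- prevGene$strand
    } else {
      gStart <- cursorByChrom[[chrom]]
    }
    gid <- sprintf("GENE%04d", g)
    nTx <- sample.int(4L, 1L)
    maxEnd <- gStart
    for (t in seq_len(nTx)) {
      prefix <- switch(kind,
        coding = sample(c("NM_", "XM_"), 1L),
        noncoding = sample(c("NR_", "XR_"), 1L),
        lincRNA = "TX_",
        unknown = "TX_",
        mixed = if (t == 1L) "NM_" else "NR_"
      )
      tid <- sprintf("%s%06d", prefix, g * 10L + t)
      nEx <- sample.int(8L, 1L)
      exWidth <- sample(50:300, nEx, replace = TRUE)
      ## gap after each exon keeps isoform exons disjoint and sorted
      gaps <- sample(50:500, nEx, replace = TRUE)
      exStart <- gStart + cumsum(c(0L, exWidth[-nEx] + gaps[-nEx]))
      for (e in seq_len(nEx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = exStart[e], end = exStart[e] + exWidth[e] - 1L,
          strand = strand, gene_id = gid, transcript_id = tid,
          gene_name = paste0("Gene", g),
          source_class = if (kind == "lincRNA") "lincRNA" else "simulated",
          stringsAsFactors = FALSE
        )
        maxEnd <- max(maxEnd, exStart[e] + exWidth[e] - 1L)
      }
    }
    cursorByChrom[[chrom]] <- maxEnd + sample(2000:5000, 1L)
    if (kind %in% c("coding", "mixed"))
      prevGene <- list(chrom = chrom, start = gStart, strand = strand)
  }
  ex <- do.call(rbind, rows)
  exons <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start, ex$end),
                                  strand = ex$strand)
  S4Vectors::mcols(exons)$gene_id <- ex$gene_id
  S4Vectors::mcols(exons)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(exons)$gene_name <- ex$gene_name
  S4Vectors::mcols(exons)$source_class <- ex$source_class
  .buildGeneAnnotation(exons)
}

#' Simulate a random transcript sequence
#'
#' @param length sequence length in nt.
#' @param composition named A/C/G/T frequencies.
#' @param seed integer RNG seed; \code{NULL} uses the current RNG state.
#' @return A nucleotide string.
#' @export
simulateTranscript <- function(length,
                               composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = composition[c("A", "C", "G", "T")]), collapse = "")
}

#' Write simulated truth and matrix to TSV
#'
#' Emits the FPKM matrix, the truth table and a minimal gene table (gene_id,
#' biotype) for a simulated experiment.
#'
#' @param se output of \code{\link{simulateMatrix}}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeSimulation <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    truth = file.path(dir, "truth.tsv"),
    genes = file.path(dir, "gene_table.tsv")
  )
  writeExpressionMatrix(se, paths[["matrix"]])
  truth <- as.data.frame(SummarizedExperiment::rowData(se))
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth[, c("gene_id", "biotype")], paths[["genes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
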