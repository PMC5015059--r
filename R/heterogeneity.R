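#' @include AllClasses.R AllGenerics.R mixture.R quantification.R
#' @importFrom SummarizedExperiment rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Number of expressing cells for one gene
#'
#' Counts the cells in which the gene's FPKM is strictly greater than the
#' positivity threshold (default 3 FPKM): a cell at exactly the threshold is
#' not counted.
#'
#' @param values FPKM values of one gene across cells, non-negative.
#' @param threshold FPKM positivity threshold (strict).
#' @return Integer count.
#' @examples
#' countExpressingCells(c(0, 3.0, 3.01, 24.5))  # 2
#' @export
countExpressingCells <- function(values, threshold = 3) {
  if (!length(values)) stop("cell vector must be non-empty")
  if (any(values < 0)) stop("FPKM values must be non-negative")
  sum(values > threshold)
}

#' Select genes in the moderate-expression window
#'
#' Retains genes whose maximum FPKM across cells lies in
#' \code{(windowLow, windowHigh]}: strictly above the expression threshold
#' (otherwise the gene is not expressed) and not above the upper bound in any
#' cell (a gene reaching 30.0 FPKM is kept, one reaching 30.01 is dropped,
#' under the defaults). For each retained gene the expressing-cell count N is
#' computed; every retained gene has N >= 1 by construction.
#'
#' @param mat gene-by-cell FPKM matrix (rownames = gene ids) or
#'   \code{SummarizedExperiment} with an \code{"fpkm"} assay.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame with columns gene_id, N, max_fpkm.
#' @export
selectWindow <- function(mat, config = analysisConfig()) {
  m <- .asFpkmMatrix(mat)
  if (!nrow(m) || !ncol(m)) stop("expression matrix must be non-empty")
  mx <- apply(m, 1L, max)
  keep <- mx > config@windowLow & mx <= config@windowHigh
  m <- m[keep, , drop = FALSE]
  data.frame(
    gene_id = rownames(m),
    N = as.integer(rowSums(m > config@exprThreshold)),
    max_fpkm = mx[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.flagCore <- function(m, biotype, config) {
  win <- selectWindow(m, config)
  if (!is.null(biotype)) {
    if (is.null(names(biotype))) {
      if (length(biotype) != nrow(m))
        stop("biotype must be named by gene id or have one entry per gene")
      names(biotype) <- rownames(m)
    }
    bt <- unname(biotype[win$gene_id])
  } else {
    bt <- rep(NA_character_, nrow(win))
  }
  model <- fitMixture(win$N, config)
  post <- posteriorHigh(model, win$N)
  flag <- assignFlag(post, config@posteriorCutoff)
  rec <- DataFrame(
    gene_id = win$gene_id, biotype = bt, N = win$N,
    max_fpkm = win$max_fpkm, posterior_high = post, flag = flag
  )
  new("HetResult", records = rec, model = model, config = config)
}

#' @describeIn flagHeterogeneity matrix input; \code{biotype} is a vector of
#'   per-gene labels, named by gene id (or in row order).
#' @param biotype per-gene biotype labels.
#' @param config an \linkS4class{AnalysisConfig}.
#' @export
setMethod("flagHeterogeneity", "matrix", function(x, biotype = NULL,
                                                  config = analysisConfig()) {
  .flagCore(x, biotype, config)
})

#' @describeIn flagHeterogeneity SummarizedExperiment input; biotypes are
#'   taken from \code{rowData(x)$biotype} when present.
#' @export
setMethod("flagHeterogeneity", "SummarizedExperiment",
  function(x, biotype = NULL, config = analysisConfig()) {
    m <- .asFpkmMatrix(x)
    if (is.null(biotype) && "biotype" %in% colnames(rowData(x)))
      biotype <- setNames(rowData(x)$biotype, rownames(x))
    .flagCore(m, biotype, config)
  })

#' @rdname accessors
#' @export
setMethod("records", "HetResult", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("mixtureModel", "HetResult", function(object) object@model)

#' Per-biotype H/L/U flag fractions
#'
#' Summarises a set of heterogeneity records into counts and fractions of H,
#' L and U flags per biotype, plus the combined low-or-uncertain fraction.
#' The three fractions sum to 1 within 1e-12 for each biotype.
#'
#' @param x a \linkS4class{HetResult}, or any data.frame-like with
#'   \code{biotype} and \code{flag} columns.
#' @return data.frame with one row per biotype: n, n_H, n_L, n_U, frac_H,
#'   frac_L, frac_U, frac_low_or_uncertain.
#' @export
heterogeneityFractions <- function(x) {
  if (is(x, "HetResult")) x <- x@records
  x <- as.data.frame(x)
  if (!nrow(x)) stop("no heterogeneity records to summarise")
  if (!all(c("biotype", "flag") %in% colnames(x)))
    stop("records must have biotype and flag columns")
  bt <- as.character(x$biotype)
  bt[is.na(bt)] <- "unlabelled"
  out <- lapply(split(x$flag, bt), function(fl) {
    n <- length(fl)
    cnt <- table(factor(fl, levels = c("H", "L", "U")))
    data.frame(
      n = n, n_H = cnt[["H"]], n_L = cnt[["L"]], n_U = cnt[["U"]],
      frac_H = cnt[["H"]] / n, frac_L = cnt[["L"]] / n,
      frac_U = cnt[["U"]] / n,
      frac_low_or_uncertain = (cnt[["L"]] + cnt[["U"]]) / n
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(biotype = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}
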