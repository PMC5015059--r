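#' @include AllClasses.R quantification.R
#' @importFrom stats t.test var median quantile
NULL

#' Coefficient of variation across all cells
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, computed
#' across ALL cells of the dataset, zeros included — dropout zeros are part
#' of the cell-to-cell variability being measured. For a vector with a single
#' positive value among C cells the identity \eqn{cv = \sqrt{C}} holds
#' exactly.
#'
#' @param values FPKM values of one gene across all cells (length >= 2).
#' @return Non-negative CV.
#' @examples
#' coefficientOfVariation(c(5, 0, 0))  # sqrt(3)
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("CV needs at least 2 cells")
  m <- mean(values)
  if (m <= 0)
    stop("CV undefined for mean <= 0; gene is not expressed and should be pre-filtered")
  stats::sd(values) / m
}

#' CV records for expressed genes, stratified by expression level
#'
#' Keeps genes expressed above the positivity threshold in at least one cell
#' (max FPKM > exprThreshold), assigns each the moderate stratum when its max
#' FPKM is at most \code{windowHigh} and the high stratum otherwise, and
#' computes its CV across all cells.
#'
#' @param mat gene-by-cell FPKM matrix or \code{SummarizedExperiment}.
#' @param biotype per-gene labels, named by gene id (or in row order); taken
#'   from \code{rowData} for a \code{SummarizedExperiment} when omitted.
#' @param config an \linkS4class{AnalysisConfig}; \code{exprThreshold} and
#'   \code{windowHigh} set the expression cut and the stratum boundary.
#' @return data.frame with columns gene_id, biotype, stratum, max_fpkm, cv.
#' @export
stratifyExpressedGenes <- function(mat, biotype = NULL,
                                   config = analysisConfig()) {
  if (is(mat, "SummarizedExperiment") && is.null(biotype) &&
      "biotype" %in% colnames(SummarizedExperiment::rowData(mat)))
    biotype <- setNames(SummarizedExperiment::rowData(mat)$biotype,
                        rownames(mat))
  m <- .asFpkmMatrix(mat)
  if (!nrow(m) || ncol(m) < 2L)
    stop("expression matrix must have genes and at least 2 cells")
  if (!is.null(biotype) && is.null(names(biotype))) {
    if (length(biotype) != nrow(m))
      stop("biotype must be named by gene id or have one entry per gene")
    names(biotype) <- rownames(m)
  }
  mx <- apply(m, 1L, max)
  keep <- mx > config@exprThreshold
  m <- m[keep, , drop = FALSE]
  mx <- mx[keep]
  data.frame(
    gene_id = rownames(m),
    biotype = if (is.null(biotype)) NA_character_
              else unname(biotype[rownames(m)]),
    stratum = ifelse(mx <= config@windowHigh, "moderate", "high"),
    max_fpkm = unname(mx),
    cv = apply(m, 1L, coefficientOfVariation),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Welch's two-sample t-test
#'
#' Unequal-variances t-test: \eqn{t = (\bar x - \bar y) /
#' \sqrt{s_x^2/n_x + s_y^2/n_y}} with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param x,y numeric samples, each of length >= 2, with positive variance in
#'   at least one sample.
#' @return A list with t_statistic, df, p_value, n_x, n_y, mean_x, mean_y.
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (var(x) == 0 && var(y) == 0)
    stop("degenerate comparison: both samples have zero variance")
  ht <- t.test(x, y, var.equal = FALSE)
  list(
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_x = length(x), n_y = length(y),
    mean_x = mean(x), mean_y = mean(y)
  )
}

#' All pairwise CV comparisons among biotype-by-stratum groups
#'
#' Forms the four groups (biotype x stratum) from a set of CV records and
#' runs all six pairwise Welch's t-tests, e.g. moderately expressed lncRNAs
#' vs moderately expressed mRNAs. Every group must be non-empty.
#'
#' @param cvRecords output of \code{\link{stratifyExpressedGenes}}.
#' @return data.frame with one row per pair: group_a, group_b, t, df, p,
#'   n_a, n_b, mean_a, mean_b.
#' @seealso \code{\link{cvGroupSummary}} for box-plot statistics.
#' @export
pairwiseCvComparisons <- function(cvRecords) {
  grp <- paste(cvRecords$biotype, cvRecords$stratum, sep = "-")
  expected <- as.vector(outer(unique(cvRecords$biotype),
                              c("moderate", "high"), paste, sep = "-"))
  empty <- setdiff(expected, unique(grp))
  if (length(empty))
    stop("empty biotype-stratum group(s): ", paste(empty, collapse = ", "))
  groups <- split(cvRecords$cv, grp)
  nm <- names(groups)
  pairs <- utils::combn(length(nm), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    w <- welchTest(groups[[a]], groups[[b]])
    data.frame(
      group_a = nm[a], group_b = nm[b],
      t = w$t_statistic, df = w$df, p = w$p_value,
      n_a = w$n_x, n_b = w$n_y, mean_a = w$mean_x, mean_b = w$mean_y,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Box-plot summary statistics per biotype-by-stratum group
#'
#' Median, first and third quartiles, whiskers extending to the most extreme
#' CV within 1.5 IQR of the quartiles, and the number of points outside the
#' whiskers — the statistics needed to redraw the standard CV box plots.
#'
#' @param cvRecords output of \code{\link{stratifyExpressedGenes}}.
#' @return data.frame with one row per group: group, n, q1, median, q3,
#'   whisker_lo, whisker_hi, n_outliers.
#' @export
cvGroupSummary <- function(cvRecords) {
  grp <- paste(cvRecords$biotype, cvRecords$stratum, sep = "-")
  out <- lapply(split(cvRecords$cv, grp), function(v) {
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(
      n = length(v), q1 = q[1], median = q[2], q3 = q[3],
      whisker_lo = lo, whisker_hi = hi,
      n_outliers = sum(v < lo | v > hi)
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}
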