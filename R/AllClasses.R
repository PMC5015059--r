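#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Analysis configuration
#'
#' Holds the tunable constants of the heterogeneity analysis: the FPKM
#' positivity threshold, the moderate-expression window on a gene's maximum
#' FPKM, the mixture posterior cutoff for flag assignment, and EM settings.
#' Defaults reproduce the standard analysis: a cell counts as expressing a
#' gene when its FPKM is strictly above 3; only genes whose maximum FPKM lies
#' in (3, 30] enter the mixture fit; a gene is flagged H or L only when its
#' posterior exceeds 0.99.
#'
#' @slot exprThreshold FPKM above which a cell counts as expressing (default 3).
#' @slot windowLow,windowHigh bounds on max FPKM for the mixture analysis;
#'   lower bound strict, upper bound inclusive (defaults 3 and 30).
#' @slot posteriorCutoff posterior probability above which an H or L flag is
#'   assigned (default 0.99, strict).
#' @slot emTolerance relative log-likelihood change declaring EM convergence.
#' @slot emMaxIter maximum EM iterations.
#' @slot init mean-initialisation policy, \code{"quartile"} (deterministic,
#'   default) or \code{"random"}.
#' @slot seed integer seed used only when \code{init == "random"}.
#' @export
setClass("AnalysisConfig",
  representation(
    exprThreshold = "numeric",
    windowLow = "numeric",
    windowHigh = "numeric",
    posteriorCutoff = "numeric",
    emTolerance = "numeric",
    emMaxIter = "integer",
    init = "character",
    seed = "integer"
  ),
  prototype(
    exprThreshold = 3, windowLow = 3, windowHigh = 30,
    posteriorCutoff = 0.99, emTolerance = 1e-8, emMaxIter = 1000L,
    init = "quartile", seed = 1L
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (!(object@windowLow > 0 && object@windowLow < object@windowHigh))
    msg <- c(msg, "must have 0 < windowLow < windowHigh")
  if (!(object@posteriorCutoff > 0.5 && object@posteriorCutoff < 1))
    msg <- c(msg, "posteriorCutoff must lie in (0.5, 1)")
  if (!object@init %in% c("quartile", "random"))
    msg <- c(msg, "init must be 'quartile' or 'random'")
  if (!(object@emTolerance > 0))
    msg <- c(msg, "emTolerance must be positive")
  if (object@emMaxIter < 1L)
    msg <- c(msg, "emMaxIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param exprThreshold,windowLow,windowHigh,posteriorCutoff,emTolerance
#'   numeric settings, see \linkS4class{AnalysisConfig}.
#' @param emMaxIter,seed integers.
#' @param init \code{"quartile"} or \code{"random"}.
#' @return A validated \linkS4class{AnalysisConfig}.
#' @examples
#' analysisConfig()
#' analysisConfig(windowHigh = 50)
#' @export
analysisConfig <- function(exprThreshold = 3, windowLow = 3, windowHigh = 30,
                           posteriorCutoff = 0.99, emTolerance = 1e-8,
                           emMaxIter = 1000L, init = "quartile", seed = 1L) {
  new("AnalysisConfig",
    exprThreshold = as.numeric(exprThreshold),
    windowLow = as.numeric(windowLow),
    windowHigh = as.numeric(windowHigh),
    posteriorCutoff = as.numeric(posteriorCutoff),
    emTolerance = as.numeric(emTolerance),
    emMaxIter = as.integer(emMaxIter),
    init = init, seed = as.integer(seed)
  )
}

#' Fitted two-component Gaussian mixture
#'
#' Result of \code{\link{fitMixture}}. Components are relabelled so that
#' component 1 has the smaller mean; on expressing-cell counts this is the
#' high-heterogeneity population (genes expressed in few cells).
#'
#' @slot lambda mixing weights, sum to 1.
#' @slot mu component means, ordered \code{mu[1] <= mu[2]}.
#' @slot sigma component standard deviations, both positive.
#' @slot logLik final observed-data log-likelihood.
#' @slot logLikTrace log-likelihood at each EM iteration (non-decreasing).
#' @slot nIter number of EM iterations performed.
#' @slot converged whether the relative log-likelihood change fell below the
#'   configured tolerance within the iteration budget.
#' @export
setClass("MixtureModel",
  representation(
    lambda = "numeric", mu = "numeric", sigma = "numeric",
    logLik = "numeric", logLikTrace = "numeric",
    nIter = "integer", converged = "logical"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character(0)
  if (length(object@lambda) != 2L || length(object@mu) != 2L ||
      length(object@sigma) != 2L)
    msg <- c(msg, "lambda, mu, sigma must each have length 2")
  else {
    if (abs(sum(object@lambda) - 1) > 1e-12)
      msg <- c(msg, "mixing weights must sum to 1 (within 1e-12)")
    if (any(object@sigma <= 0))
      msg <- c(msg, "component standard deviations must be positive")
    if (object@mu[1] > object@mu[2])
      msg <- c(msg, "components must be ordered mu[1] <= mu[2]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MixtureModel-class compact display of the fitted parameters.
#' @param object a \code{MixtureModel}.
#' @export
setMethod("show", "MixtureModel", function(object) {
  cat("MixtureModel (two-component Gaussian)\n")
  cat(sprintf("  component 1 (high heterogeneity): lambda = %.4f, mu = %.4f, sigma = %.4f\n",
    object@lambda[1], object@mu[1], object@sigma[1]))
  cat(sprintf("  component 2 (low heterogeneity):  lambda = %.4f, mu = %.4f, sigma = %.4f\n",
    object@lambda[2], object@mu[2], object@sigma[2]))
  cat(sprintf("  logLik = %.6f after %d iterations (%s)\n", object@logLik,
    object@nIter, if (object@converged) "converged" else "NOT converged"))
})

#' Gene annotation with union-exon models
#'
#' Container built by \code{\link{parseGtf}}: the exon-level annotation as a
#' \code{GRanges} (metadata columns \code{gene_id}, \code{transcript_id},
#' \code{source_class}) plus a per-gene table with the union-exon length (each
#' exonic base counted once across all isoforms) and, after
#' \code{\link{classifyBiotype}}, the coding/noncoding/excluded biotype with
#' an audit reason.
#'
#' @slot exons \code{GRanges} of exon records.
#' @slot genes \code{DataFrame} with columns gene_id, gene_name, chrom,
#'   strand, union_length, biotype, biotype_reason.
#' @export
setClass("GeneAnnotation",
  representation(exons = "GRanges", genes = "DataFrame")
)

setValidity("GeneAnnotation", function(object) {
  msg <- character(0)
  need <- c("gene_id", "gene_name", "chrom", "strand", "union_length",
            "biotype", "biotype_reason")
  if (!all(need %in% colnames(object@genes)))
    msg <- c(msg, paste("gene table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@genes$gene_id))
      msg <- c(msg, "gene_id values must be unique")
    if (any(object@genes$union_length <= 0))
      msg <- c(msg, "union lengths must be positive")
    bt <- object@genes$biotype
    if (!all(is.na(bt) | bt %in% c("coding", "noncoding", "excluded")))
      msg <- c(msg, "biotype must be coding, noncoding, excluded or NA")
  }
  ec <- colnames(S4Vectors::mcols(object@exons))
  if (!all(c("gene_id", "transcript_id") %in% ec))
    msg <- c(msg, "exons must carry gene_id and transcript_id")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneAnnotation-class summary display.
#' @param object a \code{GeneAnnotation}.
#' @export
setMethod("show", "GeneAnnotation", function(object) {
  ng <- nrow(object@genes)
  nt <- length(unique(S4Vectors::mcols(object@exons)$transcript_id))
  cat(sprintf("GeneAnnotation: %d genes, %d transcripts, %d exon records\n",
    ng, nt, length(object@exons)))
  bt <- object@genes$biotype
  if (!all(is.na(bt))) {
    tb <- table(factor(bt, levels = c("coding", "noncoding", "excluded")))
    cat(sprintf("  biotypes: %d coding, %d noncoding, %d excluded\n",
      tb[["coding"]], tb[["noncoding"]], tb[["excluded"]]))
  } else cat("  biotypes: not yet classified (run classifyBiotype)\n")
})

#' Heterogeneity classification result
#'
#' Result of \code{\link{flagHeterogeneity}}: one record per windowed gene
#' (expressing-cell count N, max FPKM, posterior probability of the
#' high-heterogeneity component, H/L/U flag) together with the fitted
#' \linkS4class{MixtureModel} and the \linkS4class{AnalysisConfig} used.
#'
#' @slot records \code{DataFrame} with columns gene_id, biotype, N, max_fpkm,
#'   posterior_high, flag.
#' @slot model the fitted \linkS4class{MixtureModel}.
#' @slot config the \linkS4class{AnalysisConfig} used.
#' @export
setClass("HetResult",
  representation(records = "DataFrame", model = "MixtureModel",
                 config = "AnalysisConfig")
)

setValidity("HetResult", function(object) {
  need <- c("gene_id", "biotype", "N", "max_fpkm", "posterior_high", "flag")
  if (!all(need %in% colnames(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (!all(object@records$flag %in% c("H", "L", "U")))
    return("flags must be H, L or U")
  p <- object@records$posterior_high
  if (any(p < 0 | p > 1)) return("posterior_high must lie in [0, 1]")
  TRUE
})

#' @describeIn HetResult-class summary display with per-biotype flag fractions.
#' @param object a \code{HetResult}.
#' @export
setMethod("show", "HetResult", function(object) {
  cat(sprintf("HetResult: %d genes classified\n", nrow(object@records)))
  show(object@model)
  fr <- heterogeneityFractions(object)
  for (i in seq_len(nrow(fr))) {
    cat(sprintf("  %-10s n = %4d  H %5.1f%%  L %5.1f%%  U %5.1f%%\n",
      fr$biotype[i], fr$n[i], 100 * fr$frac_H[i], 100 * fr$frac_L[i],
      100 * fr$frac_U[i]))
  }
})

#' Simulation specification
#'
#' Parameters of the synthetic single-cell FPKM generator, emulating the
#' data regime of the heterogeneity analysis: a gene-by-cell matrix with a
#' dropout-style excess of exact zeros, genes labelled lncRNA or mRNA, a
#' two-population structure in the number of expressing cells per gene, and
#' per-gene maximum expression straddling the 3 and 30 FPKM boundaries.
#' Defaults plant the study regime: 96 cells, 2000 genes per biotype, a
#' high-heterogeneity probability of 0.74 for lncRNAs and 0.35 for mRNAs
#' among moderately expressed genes.
#'
#' @slot nCells number of cells (study datasets used 36, 32, 96, 39, 57).
#' @slot nLnc,nMrna genes per biotype.
#' @slot pHighLnc,pHighMrna probability that a moderate-expression gene of
#'   that biotype belongs to the high-heterogeneity class.
#' @slot nHighMean,nHighSd,nLowMean,nLowSd Gaussian parameters, on the
#'   expressing-cell-count scale, of the high- and low-heterogeneity classes
#'   (rounded and clamped to [1, nCells]).
#' @slot pBright fraction of genes in the bright regime (max FPKM > windowHigh).
#' @slot brightHighScale multiplier applied to pHigh* for bright-regime genes
#'   (abundant genes tend to be broadly expressed).
#' @slot brightNHighMean,brightNHighSd,brightNLowMean,brightNLowSd class
#'   distributions of N for bright-regime genes, shifted towards more
#'   expressing cells than their moderate counterparts.
#' @slot magMeanLog,magSdLog log-normal location/scale of positive-cell FPKM
#'   in the moderate regime, truncated to (3, 30].
#' @slot brightMagMeanLog log-normal location for bright-regime genes,
#'   truncated to (3, 300] with the top cell forced above 30.
#' @slot backgroundNoise if TRUE, non-expressing cells get sub-threshold
#'   uniform noise in (0, 3) instead of exact zeros.
#' @slot seed integer RNG seed; the generator is deterministic given the spec.
#' @export
setClass("SimulationSpec",
  representation(
    nCells = "integer", nLnc = "integer", nMrna = "integer",
    pHighLnc = "numeric", pHighMrna = "numeric",
    nHighMean = "numeric", nHighSd = "numeric",
    nLowMean = "numeric", nLowSd = "numeric",
    pBright = "numeric", brightHighScale = "numeric",
    brightNHighMean = "numeric", brightNHighSd = "numeric",
    brightNLowMean = "numeric", brightNLowSd = "numeric",
    magMeanLog = "numeric", magSdLog = "numeric",
    brightMagMeanLog = "numeric",
    backgroundNoise = "logical", seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  if (object@nCells < 2L) msg <- c(msg, "nCells must be >= 2")
  pr <- c(object@pHighLnc, object@pHighMrna, object@pBright,
          object@brightHighScale)
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!(object@nHighMean < object@nLowMean) ||
      !(object@brightNHighMean < object@brightNLowMean))
    msg <- c(msg, "high-heterogeneity class mean N must be below the low-class mean")
  if (any(c(object@nHighSd, object@nLowSd,
            object@brightNHighSd, object@brightNLowSd) <= 0))
    msg <- c(msg, "class N standard deviations must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationSpec-class summary display.
#' @param object a \code{SimulationSpec}.
#' @export
setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d cells, %d lncRNA + %d mRNA genes, seed %d\n",
    object@nCells, object@nLnc, object@nMrna, object@seed))
  cat(sprintf("  planted P(high het): lncRNA %.2f, mRNA %.2f (x%.2f when bright)\n",
    object@pHighLnc, object@pHighMrna, object@brightHighScale))
  cat(sprintf("  N classes: high ~ N(%.1f, %.1f), low ~ N(%.1f, %.1f)\n",
    object@nHighMean, object@nHighSd, object@nLowMean, object@nLowSd))
})
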