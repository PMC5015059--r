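#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' @param object,x a package object (\linkS4class{GeneAnnotation},
#'   \linkS4class{HetResult}, \linkS4class{MixtureModel}).
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object, ...) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("geneTable", function(object, ...) standardGeneric("geneTable"))

#' @rdname accessors
#' @export
setGeneric("unionLengths", function(object, ...) standardGeneric("unionLengths"))

#' @rdname accessors
#' @export
setGeneric("biotypes", function(object, ...) standardGeneric("biotypes"))

#' @rdname accessors
#' @export
setGeneric("unionExons", function(object, ...) standardGeneric("unionExons"))

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(object, ...) standardGeneric("exonRanges"))

#' @rdname accessors
#' @export
setGeneric("records", function(object, ...) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("mixtureModel", function(object, ...) standardGeneric("mixtureModel"))

#' Classify per-gene expression heterogeneity
#'
#' Runs the heterogeneity pipeline core on a gene-by-cell FPKM matrix:
#' windowing on max FPKM, expressing-cell counts, two-component Gaussian
#' mixture EM on the pooled counts, posterior computation and H/L/U flag
#' assignment.
#'
#' @param x a numeric matrix (genes in rows, cells in columns, rownames as
#'   gene ids) or a \code{SummarizedExperiment} with an \code{"fpkm"} assay.
#' @param ... passed to methods (\code{biotype}, \code{config}).
#' @return A \linkS4class{HetResult}.
#' @export
setGeneric("flagHeterogeneity", function(x, ...) standardGeneric("flagHeterogeneity"))
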