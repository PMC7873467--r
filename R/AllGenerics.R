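#' Extract an expression matrix for one RNA class
#'
#' @param x a [PairedExpressionSet-class]
#' @param rnaClass one of \code{"mRNA"}, \code{"lncRNA"}, \code{"miRNA"}
#' @return numeric matrix, features x samples, log2 scale
#' @export
setGeneric("exprMatrix", function(x, rnaClass) standardGeneric("exprMatrix"))

#' Sample sheet accessor
#'
#' @param x a [PairedExpressionSet-class]
#' @return data.frame with columns sample_id, patient_id, condition
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' RNA classes present in an object
#'
#' @param x a [PairedExpressionSet-class]
#' @return character vector of class names
#' @export
setGeneric("rnaClasses", function(x) standardGeneric("rnaClasses"))

#' Interaction edge table accessor
#'
#' @param x a [MirnaInteractionSet-class]
#' @return data.frame with columns mirna_id, target_id, target_class
#' @export
setGeneric("interactionEdges", function(x) standardGeneric("interactionEdges"))

#' Network edge table accessor
#'
#' @param x a [CeRNANetwork-class]
#' @return data.frame of lncRNA-mRNA edges with hypergeometric evidence
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Stationary score accessor
#'
#' @param x an [RWRResult-class]
#' @return named numeric vector of stationary probabilities
#' @export
setGeneric("rwrScores", function(x) standardGeneric("rwrScores"))

#' Permutation p-value accessor
#'
#' @param x an [RWRResult-class]
#' @return named numeric vector of lncRNA permutation p-values
#' @export
setGeneric("lncrnaPvalues", function(x) standardGeneric("lncrnaPvalues"))

#' Gene set accessor
#'
#' @param x a [GeneSetCollection-class]
#' @return named list of character vectors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Planted ground-truth accessor
#'
#' @param x a [SyntheticDataset-class]
#' @return list describing the planted signal
#' @export
setGeneric("truthManifest", function(x) standardGeneric("truthManifest"))
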