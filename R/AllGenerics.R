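#' Sample group labels
#'
#' @param x a \linkS4class{CqPanel}, \linkS4class{CqMatrix} or
#'   \linkS4class{NrqReport}.
#' @return named character vector mapping sample identifier to group label.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Number of technical replicates
#'
#' @param x a \linkS4class{CqPanel}.
#' @return integer replicate count.
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' Replicate-level Cq values as a 3-d array
#'
#' @param x a \linkS4class{CqPanel}.
#' @return numeric array gene x sample x replicate, \code{NA} for
#'   non-amplified reactions.
#' @export
setGeneric("cqArray", function(x) standardGeneric("cqArray"))

#' Coerce an algorithm result to a StabilityTable
#'
#' Every stability algorithm result can be flattened to the common
#' (gene, score, rank) table used by rank aggregation.
#'
#' @param x a \linkS4class{GeNormResult}, \linkS4class{NormFinderResult},
#'   \linkS4class{BestKeeperResult}, \linkS4class{DeltaCtResult} or
#'   \linkS4class{StabilityTable}.
#' @param ... method-specific options; for \linkS4class{GeNormResult},
#'   \code{tieAverage = TRUE} gives the formally unrankable final pair the
#'   average rank 1.5 instead of ranks 1 and 2.
#' @return a \linkS4class{StabilityTable}.
#' @export
setGeneric("stabilityTable", function(x, ...) standardGeneric("stabilityTable"))

#' Gene ranking of a stability result
#'
#' @param x a stability result or \linkS4class{ComprehensiveRanking}.
#' @return character vector of genes, most stable first.
#' @export
setGeneric("geneRanking", function(x) standardGeneric("geneRanking"))

#' Write a pipeline result to a plain-text report
#'
#' Tables are written as TSV with a stable column order, nested results as
#' JSON; floating values are kept at six significant digits.
#'
#' @param obj a pipeline result object.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
setGeneric("writeReport", function(obj, path) standardGeneric("writeReport"))
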