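#' Re-exported Bioconductor accessors
#'
#' \code{assay} and \code{colData} from \pkg{SummarizedExperiment} are
#' re-exported so that panel and matrix contents are reachable without
#' attaching that package explicitly.
#'
#' @name reexports
#' @importFrom SummarizedExperiment assay
#' @export assay
#' @importFrom SummarizedExperiment colData
#' @export colData
NULL
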