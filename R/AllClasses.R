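#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CqPanel: replicate-level quantification-cycle data
#'
#' A \code{CqPanel} holds raw, replicate-level Cq values for a gene panel
#' measured across samples, together with a group label per sample.  It
#' extends \link[SummarizedExperiment]{SummarizedExperiment}: each technical
#' replicate is stored as one assay matrix (genes x samples, named
#' \code{rep1}, \code{rep2}, ...), and the group label lives in
#' \code{colData(x)$group}.  Non-amplified reactions (no Cq call) are encoded
#' as \code{NA}.
#'
#' Validity requires a complete replicate cross-product (every assay has the
#' full gene x sample dimensions), unique gene and sample identifiers,
#' exactly one group label per sample, and all non-missing Cq values finite
#' and positive.
#'
#' @seealso \code{\link{CqPanel}} (constructor), \code{\link{readCqLong}},
#'   \code{\link{aggregateReplicates}}
#' @export
setClass("CqPanel", contains = "SummarizedExperiment")

setValidity("CqPanel", function(object) {
  msgs <- character()
  if (length(assays(object)) < 1L)
    msgs <- c(msgs, "a CqPanel needs at least one replicate assay")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample identifiers must be present and unique")
  if (!"group" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain a 'group' column")
  else if (anyNA(colData(object)$group))
    msgs <- c(msgs, "every sample needs a group label")
  for (a in as.list(assays(object))) {
    v <- a[!is.na(a)]
    if (length(v) && (any(!is.finite(v)) || any(v <= 0))) {
      msgs <- c(msgs, "all non-missing Cq values must be finite and > 0")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CqMatrix: aggregated gene x sample expression values
#'
#' A complete (or, for scale \code{"cq"} straight after replicate
#' aggregation, possibly \code{NA}-flagged) gene x sample matrix carrying
#' either mean Cq values or (log) relative quantities, with the same
#' per-sample group bookkeeping as \code{\linkS4class{CqPanel}}.  The single
#' assay is named after the scale, one of \code{"cq"}, \code{"log2rq"} or
#' \code{"rq"}.
#'
#' @slot scale character scalar, the measurement scale of the assay.
#' @seealso \code{\link{CqMatrix}}, \code{\link{toLog2Rq}},
#'   \code{\link{excludeIncompleteGenes}}
#' @export
setClass("CqMatrix", contains = "SummarizedExperiment",
         representation(scale = "character"))

setValidity("CqMatrix", function(object) {
  msgs <- character()
  if (!object@scale %in% c("cq", "log2rq", "rq"))
    msgs <- c(msgs, "scale must be one of 'cq', 'log2rq', 'rq'")
  if (length(assays(object)) != 1L)
    msgs <- c(msgs, "a CqMatrix holds exactly one assay")
  if (!"group" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain a 'group' column")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene identifiers must be present and unique")
  if (object@scale != "cq" && anyNA(assay(object)))
    msgs <- c(msgs, "matrices on the log2rq/rq scales must be complete")
  if (length(msgs)) msgs else TRUE
})

#' QC report of the missing-amplification exclusion rule
#'
#' Bookkeeping produced by \code{\link{excludeIncompleteGenes}}: gene and
#' reaction counts before and after filtering, plus the per-gene missing-cell
#' table for excluded genes.  Missing reactions are counted at the replicate
#' level over the input panel.
#'
#' @slot nGenesInput,nGenesExcluded,nGenesRetained integer gene counts.
#' @slot nReactionsTotal,nReactionsMissing integer replicate-level reaction
#'   counts; \code{fractionMissing} is their ratio.
#' @slot excludedGenes data.frame with columns \code{gene},
#'   \code{missingCells}, \code{missingReactions}.
#' @export
setClass("QcReport",
         representation(nGenesInput = "integer", nGenesExcluded = "integer",
                        nGenesRetained = "integer", nReactionsTotal = "integer",
                        nReactionsMissing = "integer", fractionMissing = "numeric",
                        excludedGenes = "data.frame"))

setValidity("QcReport", function(object) {
  msgs <- character()
  if (object@nGenesInput != object@nGenesExcluded + object@nGenesRetained)
    msgs <- c(msgs, "gene counts must satisfy input = excluded + retained")
  if (object@fractionMissing < 0 || object@fractionMissing > 1)
    msgs <- c(msgs, "fractionMissing must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Per-gene stability scores from one algorithm
#'
#' The common currency of the four stability algorithms: a per-gene score
#' and rank (1 = most stable) for one method on one cohort.  Ranks are
#' positive reals to allow average ranks under ties.
#'
#' @slot method character scalar, e.g. \code{"geNorm"}.
#' @slot table data.frame with columns \code{gene}, \code{score}, \code{rank}.
#' @export
setClass("StabilityTable",
         representation(method = "character", table = "data.frame"))

setValidity("StabilityTable", function(object) {
  msgs <- character()
  if (!all(c("gene", "score", "rank") %in% colnames(object@table)))
    msgs <- c(msgs, "table needs columns gene, score, rank")
  else if (anyDuplicated(object@table$gene))
    msgs <- c(msgs, "genes must be unique")
  if (length(msgs)) msgs else TRUE
})

#' geNorm stability analysis result
#'
#' @slot ranking character, genes most-stable first (reverse elimination
#'   order; the final, formally unrankable pair ordered by final-round M).
#' @slot mTrace list, one named M-value vector per elimination round.
#' @slot finalM named numeric, each gene's M at the round it was eliminated
#'   (final round for the last pair).
#' @slot vCurve named numeric, pairwise variation V(n/n+1) for n = 2..k-1.
#' @slot mThreshold,vThreshold numeric, the M < 0.5 and V < 0.15 defaults.
#' @slot recommendedN integer, smallest n with V(n/n+1) below threshold
#'   (NA when the curve never drops below it).
#' @export
setClass("GeNormResult",
         representation(ranking = "character", mTrace = "list",
                        finalM = "numeric", vCurve = "numeric",
                        mThreshold = "numeric", vThreshold = "numeric",
                        recommendedN = "integer"))

#' NormFinder stability analysis result
#'
#' @slot stability named numeric, per-gene stability value rho (lower =
#'   more stable).
#' @slot intergroup matrix gene x group of shrunken intergroup differences
#'   (log2 units); empty for single-group analyses.
#' @slot intragroupSd matrix gene x group of corrected intragroup standard
#'   deviations (log2 units).
#' @slot gamma2 numeric, the between-group variance estimate.
#' @slot ranking character, genes by rho ascending.
#' @export
setClass("NormFinderResult",
         representation(stability = "numeric", intergroup = "matrix",
                        intragroupSd = "matrix", gamma2 = "numeric",
                        ranking = "character"))

#' BestKeeper descriptive stability result
#'
#' @slot table data.frame with per-gene \code{sdCq}, \code{cvPct},
#'   \code{r} (Pearson correlation with the BestKeeper index; NA when the
#'   gene has zero variance), \code{sdAcceptable} (classical sd <= 1 flag)
#'   and \code{rank} (by sdCq ascending, cvPct as tie-break).
#' @slot index numeric, per-sample geometric mean of candidate Cq values.
#' @export
setClass("BestKeeperResult",
         representation(table = "data.frame", index = "numeric"))

#' Comparative delta-Ct stability result
#'
#' @slot scores named numeric, per-gene mean over partner genes of the
#'   standard deviation of pairwise Cq differences (cycles).
#' @slot ranking character, genes by score ascending.
#' @export
setClass("DeltaCtResult",
         representation(scores = "numeric", ranking = "character"))

#' Comprehensive (four-method) ranking
#'
#' Geometric-mean aggregation of the geNorm, NormFinder, BestKeeper and
#' delta-Ct ranks, RefFinder style.
#'
#' @slot table data.frame with per-gene \code{rankGeNorm},
#'   \code{rankNormFinder}, \code{rankBestKeeper}, \code{rankDeltaCt},
#'   \code{geomeanRank} and final \code{position}; rows ordered by position.
#' @export
setClass("ComprehensiveRanking", representation(table = "data.frame"))

setValidity("ComprehensiveRanking", function(object) {
  need <- c("gene", "rankGeNorm", "rankNormFinder", "rankBestKeeper",
            "rankDeltaCt", "geomeanRank", "position")
  if (!all(need %in% colnames(object@table)))
    paste("table needs columns", paste(need, collapse = ", "))
  else TRUE
})

#' Normalized relative quantities and group comparison
#'
#' Output of \code{\link{evaluateNormalization}}: per-sample normalization
#' factors from a chosen reference-gene set, NRQ values for the target
#' genes, and the two-group Mann-Whitney comparison per target.
#'
#' @slot rgSet character, the reference genes used.
#' @slot nf named numeric, per-sample normalization factor (geometric mean
#'   of the reference genes' relative quantities).
#' @slot rq,nrq matrices target gene x sample of relative and normalized
#'   relative quantities.
#' @slot comparison data.frame with per-target group medians, fold change,
#'   Mann-Whitney U, two-sided p and significance stars (empty until
#'   \code{\link{compareGroups}} is applied).
#' @slot groups named character, sample -> group label.
#' @export
setClass("NrqReport",
         representation(rgSet = "character", nf = "numeric", rq = "matrix",
                        nrq = "matrix", comparison = "data.frame",
                        groups = "character"))
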