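#' Aggregate technical replicates to a gene x sample Cq matrix
#'
#' Each cell becomes the arithmetic mean of its non-missing replicate Cq
#' values (no outlier rejection).  A cell with no successful replicate at
#' all is flagged non-amplified and left \code{NA} in the matrix.
#'
#' @param panel a \linkS4class{CqPanel}.
#' @return list with elements \code{matrix} (a \linkS4class{CqMatrix} on
#'   the \code{"cq"} scale, \code{NA} where non-amplified) and
#'   \code{nonAmplified} (logical gene x sample matrix flagging cells whose
#'   replicates all failed).
#' @examples
#' p <- simulateCqPanel(nGenes = 4, groupSizes = c(a = 3, b = 3), seed = 1)
#' agg <- aggregateReplicates(p$panel)
#' @export
aggregateReplicates <- function(panel) {
  stopifnot(is(panel, "CqPanel"))
  arr <- cqArray(panel)
  means <- apply(arr, c(1L, 2L), function(v) mean(v, na.rm = TRUE))
  flags <- apply(arr, c(1L, 2L), function(v) all(is.na(v)))
  means[flags] <- NA_real_
  list(matrix = CqMatrix(means, sampleGroups(panel), scale = "cq"),
       nonAmplified = flags)
}

#' Apply the missing-amplification exclusion rule
#'
#' High-throughput stability algorithms require a complete Cq matrix, so a
#' gene for which any sample yields no amplification has to be dropped
#' before reference-gene selection.  In the default \code{"cell"} mode a
#' gene is excluded when at least one gene x sample cell has \emph{all}
#' replicates missing; the stricter \code{"replicate"} mode excludes on a
#' single missing replicate.  Replicate-level missing reactions are counted
#' over the input panel in either mode.
#'
#' @param panel a \linkS4class{CqPanel}.
#' @param mode \code{"cell"} (default) or \code{"replicate"}.
#' @param cqCeiling optional Cq ceiling; aggregated cells above it are
#'   treated as non-amplified.  Off (\code{NULL}) by default.
#' @return list with elements \code{matrix} (complete \linkS4class{CqMatrix}
#'   of the retained genes) and \code{report} (a \linkS4class{QcReport}).
#' @examples
#' p <- simulateCqPanel(nGenes = 6, groupSizes = c(a = 4, b = 4),
#'                      dropout = list(genes = "gene01", nMissing = 3),
#'                      seed = 7)
#' qc <- excludeIncompleteGenes(p$panel)
#' qc$report
#' @export
excludeIncompleteGenes <- function(panel, mode = c("cell", "replicate"),
                                   cqCeiling = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "CqPanel"))
  arr <- cqArray(panel)
  agg <- aggregateReplicates(panel)
  mat <- assay(agg$matrix)
  flags <- agg$nonAmplified
  if (!is.null(cqCeiling)) flags <- flags | (!is.na(mat) & mat > cqCeiling)

  nMissRep <- apply(arr, 1L, function(g) sum(is.na(g)))
  drop <- if (mode == "cell") rowSums(flags) > 0L else nMissRep > 0L

  nGenes <- nrow(panel)
  nTotal <- nGenes * ncol(panel) * nReplicates(panel)
  nMissing <- sum(is.na(arr))
  excluded <- data.frame(gene = rownames(panel)[drop],
                         missingCells = rowSums(flags)[drop],
                         missingReactions = nMissRep[drop],
                         row.names = NULL)
  report <- new("QcReport",
                nGenesInput = nGenes, nGenesExcluded = sum(drop),
                nGenesRetained = sum(!drop),
                nReactionsTotal = as.integer(nTotal),
                nReactionsMissing = as.integer(nMissing),
                fractionMissing = nMissing / nTotal,
                excludedGenes = excluded)
  if (all(drop)) stop("no genes retained")
  keep <- mat[!drop, , drop = FALSE]
  list(matrix = CqMatrix(keep, sampleGroups(panel), scale = "cq"),
       report = report)
}

setMethod("show", "QcReport", function(object) {
  cat("QC report (missing-amplification exclusion)\n")
  cat(sprintf("  genes: %d in, %d excluded, %d retained\n",
              object@nGenesInput, object@nGenesExcluded,
              object@nGenesRetained))
  cat(sprintf("  reactions: %d of %d missing (%.2f%%)\n",
              object@nReactionsMissing, object@nReactionsTotal,
              100 * object@fractionMissing))
})
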