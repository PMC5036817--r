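#' Comprehensive ranking across the four stability algorithms
#'
#' Aggregates the geNorm, NormFinder, BestKeeper and delta-Ct rankings of
#' one gene panel into a comprehensive ranking by the geometric mean of
#' the four per-gene ranks, the aggregation used by RefFinder.  The final
#' order is geometric mean ascending, ties broken by the best single-method
#' rank and then by input order.
#'
#' @param genorm,normfinder,bestkeeper,deltact results for the same gene
#'   set: either the algorithm result objects or
#'   \linkS4class{StabilityTable}s.
#' @param genormTieAverage passed to the geNorm
#'   \code{\link{stabilityTable}} coercion: give the final, formally
#'   unrankable pair the average rank 1.5 instead of ranks 1 and 2.
#' @return a \linkS4class{ComprehensiveRanking}.
#' @examples
#' p <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 6, b = 6), seed = 4)
#' mat <- excludeIncompleteGenes(p$panel)$matrix
#' cr <- comprehensiveRanking(geNorm(mat), normFinder(mat),
#'                            bestKeeper(mat), deltaCt(mat))
#' geneRanking(cr)
#' @export
comprehensiveRanking <- function(genorm, normfinder, bestkeeper, deltact,
                                 genormTieAverage = FALSE) {
  tabs <- list(
    geNorm = if (is(genorm, "GeNormResult"))
      stabilityTable(genorm, tieAverage = genormTieAverage)
    else stabilityTable(genorm),
    NormFinder = stabilityTable(normfinder),
    BestKeeper = stabilityTable(bestkeeper),
    deltaCt = stabilityTable(deltact))

  genes <- tabs[[1L]]@table$gene
  for (nm in names(tabs)[-1L]) {
    other <- tabs[[nm]]@table$gene
    if (!setequal(genes, other)) {
      diff <- c(setdiff(genes, other), setdiff(other, genes))
      stop("gene sets differ between rankings; symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  ranks <- vapply(tabs, function(tb) {
    tb@table$rank[match(genes, tb@table$gene)]
  }, numeric(length(genes)))
  if (length(genes) == 1L) ranks <- matrix(ranks, nrow = 1L)
  geomean <- exp(rowMeans(log(ranks)))
  best <- apply(ranks, 1L, min)
  ord <- order(geomean, best, seq_along(genes))
  position <- integer(length(genes)); position[ord] <- seq_along(ord)
  tab <- data.frame(gene = genes,
                    rankGeNorm = ranks[, "geNorm"],
                    rankNormFinder = ranks[, "NormFinder"],
                    rankBestKeeper = ranks[, "BestKeeper"],
                    rankDeltaCt = ranks[, "deltaCt"],
                    geomeanRank = geomean,
                    position = position, row.names = NULL)
  tab <- tab[order(tab$position), ]
  rownames(tab) <- NULL
  new("ComprehensiveRanking", table = tab)
}

#' @describeIn geneRanking comprehensive ranking (geometric-mean order)
#' @export
setMethod("geneRanking", "ComprehensiveRanking", function(x) {
  x@table$gene[order(x@table$position)]
})

#' @describeIn stabilityTable comprehensive: score is the geometric-mean
#'   rank.
#' @export
setMethod("stabilityTable", "ComprehensiveRanking", function(x) {
  tab <- x@table[order(x@table$position), ]
  new("StabilityTable", method = "comprehensive",
      table = data.frame(gene = tab$gene, score = tab$geomeanRank,
                         rank = as.numeric(tab$position), row.names = NULL))
})

setMethod("show", "ComprehensiveRanking", function(object) {
  cat(sprintf("Comprehensive ranking over %d genes\n", nrow(object@table)))
  print(utils::head(object@table, 5), row.names = FALSE)
})

#' Consensus top-n genes across rankings
#'
#' Intersection of the top-n gene lists of two or more rankings — e.g. the
#' genes that every algorithm, or every cohort, places among its ten most
#' stable candidates.
#'
#' @param rankings list (length >= 2) of \linkS4class{StabilityTable},
#'   algorithm results or \linkS4class{ComprehensiveRanking}s over a
#'   common gene set.
#' @param n number of top genes per ranking, between 1 and the panel size.
#' @return character vector of genes in every ranking's top n, ordered as
#'   in the first ranking.
#' @examples
#' p <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 6, b = 6), seed = 5)
#' mat <- excludeIncompleteGenes(p$panel)$matrix
#' consensusTop(list(geNorm(mat), normFinder(mat), deltaCt(mat)), n = 4)
#' @export
consensusTop <- function(rankings, n = 10L) {
  if (length(rankings) < 2L) stop("need at least 2 rankings")
  tops <- lapply(rankings, function(r) geneRanking(r))
  k <- length(tops[[1L]])
  if (n < 1L || n > k) stop("n must lie between 1 and the panel size (", k, ")")
  heads <- lapply(tops, utils::head, n)
  out <- heads[[1L]]
  for (h in heads[-1L]) out <- out[out %in% h]
  out
}
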