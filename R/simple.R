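#' BestKeeper descriptive stability statistics
#'
#' Operates on raw Cq values (deliberately: unlike the log-ratio methods,
#' its per-gene standard deviation is sensitive to sample loading).  The
#' BestKeeper index is the per-sample geometric mean of all candidate
#' genes' Cq; each gene is described by its Cq standard deviation (cycles),
#' coefficient of variation (percent of the mean Cq) and Pearson
#' correlation with the index.  Genes are ranked by standard deviation
#' ascending, coefficient of variation breaking ties; the classical
#' sd <= 1 acceptability flag is reported but never removes genes.
#'
#' @param mat a complete \linkS4class{CqMatrix} on the \code{"cq"} scale
#'   with >= 2 samples.
#' @return a \linkS4class{BestKeeperResult}.
#' @examples
#' m <- CqMatrix(matrix(c(20, 21, 22, 23, 25, 25, 25, 25), 2, 4,
#'                      byrow = TRUE,
#'                      dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
#'               groups = rep("a", 4), scale = "cq")
#' bestKeeper(m)@table
#' @export
bestKeeper <- function(mat) {
  stopifnot(is(mat, "CqMatrix"))
  if (cqScale(mat) != "cq") stop("BestKeeper operates on raw Cq values")
  X <- assay(mat)
  if (anyNA(X)) stop("Cq matrix must be complete; run QC filtering first")
  if (ncol(X) < 2L) stop("need at least 2 samples")

  index <- exp(colMeans(log(X)))
  sdCq <- apply(X, 1L, stats::sd)
  cvPct <- 100 * sdCq / rowMeans(X)
  r <- vapply(seq_len(nrow(X)), function(i) {
    if (sdCq[i] == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(X[i, ], index)
  }, 0)
  ord <- order(sdCq, cvPct, seq_along(sdCq))
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  tab <- data.frame(gene = rownames(X), sdCq = sdCq, cvPct = cvPct, r = r,
                    sdAcceptable = sdCq <= 1, rank = as.numeric(rank),
                    row.names = NULL)
  new("BestKeeperResult", table = tab,
      index = stats::setNames(index, colnames(X)))
}

#' @describeIn geneRanking BestKeeper ranking (smallest Cq sd first)
#' @export
setMethod("geneRanking", "BestKeeperResult", function(x) {
  x@table$gene[order(x@table$rank)]
})

#' @describeIn stabilityTable BestKeeper: score is the raw-Cq standard
#'   deviation.
#' @export
setMethod("stabilityTable", "BestKeeperResult", function(x) {
  tab <- x@table[order(x@table$rank), ]
  new("StabilityTable", method = "BestKeeper",
      table = data.frame(gene = tab$gene, score = tab$sdCq,
                         rank = tab$rank, row.names = NULL))
})

setMethod("show", "BestKeeperResult", function(object) {
  cat(sprintf("BestKeeper result over %d genes, %d samples\n",
              nrow(object@table), length(object@index)))
  tab <- object@table[order(object@table$rank), ]
  top <- utils::head(tab, 3)
  cat("  most stable:",
      paste(sprintf("%s (sd %.3f)", top$gene, top$sdCq), collapse = ", "),
      "\n")
})

#' Comparative delta-Ct stability scores
#'
#' Scores each gene by the mean, over all partner genes, of the standard
#' deviation across samples of the pairwise Cq difference.  Because a Cq
#' difference is a log2 expression ratio, this score is algebraically the
#' geNorm M-value computed on the full panel with base-2 efficiency, and
#' like it is invariant to per-sample loading offsets.
#'
#' @param mat a complete \linkS4class{CqMatrix} on the \code{"cq"} scale
#'   with >= 2 genes and >= 2 samples.
#' @return a \linkS4class{DeltaCtResult}.
#' @export
deltaCt <- function(mat) {
  stopifnot(is(mat, "CqMatrix"))
  if (cqScale(mat) != "cq") stop("the delta-Ct method operates on Cq values")
  X <- assay(mat)
  if (anyNA(X)) stop("Cq matrix must be complete; run QC filtering first")
  if (nrow(X) < 2L) stop("need at least 2 genes")
  if (ncol(X) < 2L) stop("need at least 2 samples")
  V <- .pairSdMatrix(X)
  scores <- rowSums(V) / (nrow(X) - 1L)
  names(scores) <- rownames(X)
  new("DeltaCtResult", scores = scores,
      ranking = names(scores)[order(scores)])
}

#' @describeIn geneRanking delta-Ct ranking (smallest mean pair sd first)
#' @export
setMethod("geneRanking", "DeltaCtResult", function(x) x@ranking)

#' @describeIn stabilityTable delta-Ct: score is the mean pairwise sd in
#'   cycles.
#' @export
setMethod("stabilityTable", "DeltaCtResult", function(x) {
  new("StabilityTable", method = "deltaCt",
      table = data.frame(gene = x@ranking,
                         score = unname(x@scores[x@ranking]),
                         rank = as.numeric(seq_along(x@ranking))))
})

setMethod("show", "DeltaCtResult", function(object) {
  cat(sprintf("delta-Ct result over %d genes\n", length(object@scores)))
  top <- utils::head(object@ranking, 3)
  cat("  most stable:",
      paste(sprintf("%s (%.3f)", top, object@scores[top]), collapse = ", "),
      "\n")
})

#' @describeIn geneRanking of an already-flattened stability table
#' @export
setMethod("geneRanking", "StabilityTable", function(x) {
  x@table$gene[order(x@table$rank)]
})

#' @describeIn stabilityTable identity on a StabilityTable
#' @export
setMethod("stabilityTable", "StabilityTable", function(x) x)

setMethod("show", "StabilityTable", function(object) {
  cat(sprintf("StabilityTable [%s], %d genes\n", object@method,
              nrow(object@table)))
  print(utils::head(object@table[order(object@table$rank), ], 5),
        row.names = FALSE)
})
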