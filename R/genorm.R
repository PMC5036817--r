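#' Pairwise variation between two genes
#'
#' The building block of the geNorm M-value: the sample standard deviation
#' (n - 1 denominator), across samples, of the difference of two genes'
#' log2 expression values.  Two genes whose log ratio is constant across
#' samples have pairwise variation 0.
#'
#' @param x,y numeric vectors of log2 expression, equal length >= 2,
#'   complete.
#' @return non-negative scalar.
#' @examples
#' pairwiseVariation(c(0, 1, 2, 3), c(0, 0, 0, 0))  # sd(0:3) = 1.29099
#' @export
pairwiseVariation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) stop("inputs must be complete")
  stats::sd(x - y)
}

# k x k matrix of pairwise variations from a genes x samples log2 matrix,
# via the covariance identity var(x - y) = var x + var y - 2 cov(x, y).
.pairSdMatrix <- function(X) {
  C <- stats::cov(t(X))
  v <- diag(C)
  V2 <- outer(v, v, "+") - 2 * C
  V <- sqrt(pmax(V2, 0))
  diag(V) <- 0
  V
}

#' geNorm M-values for a gene subset
#'
#' The M-value of a gene is the arithmetic mean of its pairwise variation
#' with every other gene in the subset; lower M means more stable.
#'
#' @param mat a \linkS4class{CqMatrix} (\code{"log2rq"}, or \code{"cq"}
#'   which is converted internally with base-2 efficiency).
#' @param genes subset of genes to analyse (default all), length >= 2.
#' @return named numeric vector of M-values.
#' @export
mValues <- function(mat, genes = rownames(mat)) {
  X <- assay(.asLog2(mat))
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes")
  absent <- setdiff(genes, rownames(X))
  if (length(absent)) stop("unknown gene(s): ", paste(absent, collapse = ", "))
  V <- .pairSdMatrix(X[genes, , drop = FALSE])
  rowSums(V) / (length(genes) - 1L)
}

# M-values from a precomputed pairwise-variation matrix restricted to 'keep'
.mFromV <- function(V, keep) {
  rowSums(V[keep, keep, drop = FALSE]) / (length(keep) - 1L)
}

#' geNorm stability ranking with iterative elimination and V-curve
#'
#' Repeatedly removes the gene with the highest M-value and recomputes M
#' for the remainder until two genes are left.  The ranking is the reverse
#' elimination order; geNorm itself cannot rank the final pair, which is
#' ordered here by final-round M (ascending, then input order) so that
#' downstream rank aggregation has a total order.  The pairwise-variation
#' curve V(n/n+1) compares normalization factors (per-sample mean log2rq of
#' the top-n genes, by the final ranking) of consecutive n; the smallest n
#' with V below \code{vThreshold} is the recommended number of reference
#' genes.
#'
#' Ties in M during elimination are broken by removing the gene later in
#' input order.
#'
#' @param mat a \linkS4class{CqMatrix} with >= 3 genes and >= 2 samples.
#' @param mThreshold stability threshold reported with the result
#'   (M < 0.5 conventionally marks acceptable reference genes).
#' @param vThreshold pairwise-variation threshold below which adding a
#'   further reference gene is considered unnecessary (0.15).
#' @return a \linkS4class{GeNormResult}.
#' @examples
#' p <- simulateCqPanel(nGenes = 6, groupSizes = c(a = 5, b = 5), seed = 2)
#' gn <- geNorm(excludeIncompleteGenes(p$panel)$matrix)
#' geneRanking(gn)
#' @export
geNorm <- function(mat, mThreshold = 0.5, vThreshold = 0.15) {
  L <- .asLog2(mat)
  X <- assay(L)
  k <- nrow(X)
  if (k < 3L) stop("geNorm elimination needs >= 3 genes; use mValues()")
  if (ncol(X) < 2L) stop("need at least 2 samples")

  V <- .pairSdMatrix(X)
  genes <- rownames(X)
  keep <- genes
  eliminated <- character()
  mTrace <- list()
  finalM <- stats::setNames(numeric(k), genes)
  round <- 0L
  while (length(keep) > 2L) {
    round <- round + 1L
    M <- .mFromV(V, keep)
    mTrace[[round]] <- M
    worst <- keep[max(which(M == max(M)))]  # tie: later in input order
    finalM[worst] <- M[worst]
    eliminated <- c(eliminated, worst)
    keep <- setdiff(keep, worst)
  }
  M <- .mFromV(V, keep)
  mTrace[[round + 1L]] <- M
  finalM[keep] <- M
  pair <- keep[order(M, match(keep, genes))]
  ranking <- c(pair, rev(eliminated))

  vCurve <- numeric(0)
  if (k >= 3L) {
    nf <- vapply(2:k, function(n) colMeans(X[ranking[1:n], , drop = FALSE]),
                 numeric(ncol(X)))  # columns: n = 2..k
    v <- vapply(seq_len(k - 2L), function(i) stats::sd(nf[, i] - nf[, i + 1L]),
                0)
    vCurve <- stats::setNames(v, paste0("V", 2:(k - 1L), "/", 3:k))
  }
  below <- which(vCurve < vThreshold)
  recommendedN <- if (length(below)) as.integer(below[1L] + 1L) else NA_integer_

  new("GeNormResult", ranking = ranking, mTrace = mTrace, finalM = finalM,
      vCurve = vCurve, mThreshold = mThreshold, vThreshold = vThreshold,
      recommendedN = recommendedN)
}

#' @describeIn geneRanking geNorm ranking (most stable first)
#' @export
setMethod("geneRanking", "GeNormResult", function(x) x@ranking)

#' @describeIn stabilityTable geNorm: score is the M-value at elimination
#'   (final-round M for the last pair); ranks follow the elimination order,
#'   optionally averaging the final pair with \code{tieAverage = TRUE}.
#' @export
setMethod("stabilityTable", "GeNormResult", function(x, tieAverage = FALSE) {
  k <- length(x@ranking)
  rank <- as.numeric(seq_len(k))
  if (tieAverage && k >= 2L) rank[1:2] <- 1.5
  new("StabilityTable", method = "geNorm",
      table = data.frame(gene = x@ranking,
                         score = unname(x@finalM[x@ranking]),
                         rank = rank))
})

setMethod("show", "GeNormResult", function(object) {
  k <- length(object@ranking)
  cat(sprintf("geNorm result over %d genes\n", k))
  cat("  most stable:", paste(utils::head(object@ranking, 3), collapse = ", "),
      "...\n")
  cat(sprintf("  genes with M < %.2f: %d\n", object@mThreshold,
              sum(object@finalM < object@mThreshold)))
  cat(sprintf("  recommended number of reference genes: %s (V < %.2f)\n",
              ifelse(is.na(object@recommendedN), "none",
                     object@recommendedN), object@vThreshold))
})
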