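#' NormFinder model-based stability values
#'
#' Decomposes each gene's log2 expression into sample loading, a group
#' (intergroup) effect and residual (intragroup) noise, and scores each
#' gene by combining its shrunken intergroup difference with the standard
#' error of its intragroup variation.  Lower stability values indicate
#' more stably expressed genes.
#'
#' The computation: (1) per-sample centring across genes removes loading;
#' (2) group means of the centred values, minus the sample-size-weighted
#' gene mean, give raw intergroup differences d; (3) within-group variances
#' are bias-corrected for the centring step,
#' \code{sigma2 = max(eps, (v - vbar/(k-1)) * k/(k-2))} with
#' \code{eps = 1e-12}; (4) a between-group variance \code{gamma2} is
#' estimated from the spread of the d's in excess of their sampling
#' variance; (5) d is shrunk by \code{gamma2 / (gamma2 + sigma2/n)};
#' (6) the stability value is the mean over groups of
#' \code{|d_shrunk| + sqrt(sigma2/n)}.  With a single group the stability
#' value reduces to the corrected intragroup standard deviation.
#'
#' @param mat a \linkS4class{CqMatrix} (\code{"log2rq"}, or \code{"cq"}
#'   converted internally) with >= 3 genes; every group needs >= 2 samples.
#' @param useGroups if \code{FALSE}, ignore the group labels and score by
#'   intragroup variation only (single-group mode).
#' @param weighted if \code{TRUE} (default) the across-group gene mean is
#'   weighted by group size, which keeps the weighted intergroup
#'   differences summing to zero under unbalanced cohorts.
#' @return a \linkS4class{NormFinderResult}.
#' @examples
#' p <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 6, b = 6), seed = 3)
#' nf <- normFinder(excludeIncompleteGenes(p$panel)$matrix)
#' geneRanking(nf)
#' @export
normFinder <- function(mat, useGroups = TRUE, weighted = TRUE) {
  L <- .asLog2(mat)
  X <- assay(L)
  k <- nrow(X)
  if (k < 3L) stop("NormFinder needs >= 3 genes")
  grp <- if (useGroups) sampleGroups(L) else
    stats::setNames(rep("all", ncol(X)), colnames(X))
  glev <- unique(unname(grp))
  G <- length(glev)
  ng <- vapply(glev, function(g) sum(grp == g), 0L)
  if (any(ng < 2L))
    stop("every group needs >= 2 samples; offending group(s): ",
         paste(glev[ng < 2L], collapse = ", "))
  eps <- 1e-12

  z <- sweep(X, 2L, colMeans(X))  # remove per-sample loading exactly

  zbar <- vapply(glev, function(g) rowMeans(z[, grp == g, drop = FALSE]),
                 numeric(k))                       # k x G
  zi <- if (weighted) as.vector(zbar %*% ng) / sum(ng) else rowMeans(zbar)
  d <- zbar - zi                                   # k x G

  v <- vapply(glev, function(g)
    apply(z[, grp == g, drop = FALSE], 1L, stats::var), numeric(k))
  vbarg <- colMeans(v)
  sigma2 <- pmax(sweep(v, 2L, vbarg / (k - 1L)) * k / (k - 2L), eps)

  sig2n <- sweep(sigma2, 2L, ng, "/")              # sigma2_ig / n_g
  if (G >= 2L) {
    gamma2 <- max(0, sum(d^2) / (k * (G - 1L)) - mean(sig2n))
    dShrunk <- d * gamma2 / (gamma2 + sig2n)
    rho <- rowMeans(abs(dShrunk) + sqrt(sig2n))
  } else {
    gamma2 <- 0
    dShrunk <- d * 0
    rho <- sqrt(sigma2[, 1L])
  }
  names(rho) <- rownames(X)
  dimnames(d) <- dimnames(dShrunk) <- dimnames(sigma2) <-
    list(rownames(X), glev)

  ranking <- names(rho)[order(rho)]  # stable under ties: input order
  new("NormFinderResult", stability = rho,
      intergroup = if (G >= 2L) dShrunk else matrix(numeric(0), 0, 0),
      intragroupSd = sqrt(sigma2), gamma2 = gamma2, ranking = ranking)
}

#' @describeIn geneRanking NormFinder ranking (lowest stability value first)
#' @export
setMethod("geneRanking", "NormFinderResult", function(x) x@ranking)

#' @describeIn stabilityTable NormFinder: score is the stability value rho.
#' @export
setMethod("stabilityTable", "NormFinderResult", function(x) {
  new("StabilityTable", method = "NormFinder",
      table = data.frame(gene = x@ranking,
                         score = unname(x@stability[x@ranking]),
                         rank = as.numeric(seq_along(x@ranking))))
})

setMethod("show", "NormFinderResult", function(object) {
  cat(sprintf("NormFinder result over %d genes (%d group%s)\n",
              length(object@stability),
              max(1L, ncol(object@intragroupSd)),
              ifelse(ncol(object@intragroupSd) == 1L, "", "s")))
  top <- utils::head(object@ranking, 3)
  cat("  most stable:", paste(sprintf("%s (%.3f)", top,
                                      object@stability[top]),
                              collapse = ", "), "\n")
  cat(sprintf("  between-group variance estimate: %.4g\n", object@gamma2))
})
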