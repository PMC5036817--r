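#' Mann-Whitney U test (two-sided)
#'
#' Reports the smaller of the two U statistics (midranks under ties) and a
#' two-sided p-value: exact by enumeration when the combined sample size
#' is at most 16 and there are no ties, otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with elements \code{U}, \code{p} and \code{exact}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  uA <- unname(wt$statistic)
  u <- min(uA, length(x) * length(y) - uA)
  list(U = u, p = unname(wt$p.value), exact = exact)
}

#' Normalize target genes with a chosen reference-gene set
#'
#' Computes the per-sample normalization factor NF (geometric mean of the
#' reference genes' relative quantities) and the normalized relative
#' quantity NRQ = RQ/NF for each target gene.  With mean-anchored RQ the
#' geometric mean of NF across samples is 1.
#'
#' @param mat a complete \linkS4class{CqMatrix} (\code{"cq"} is converted
#'   to mean-anchored log2 relative quantities internally).
#' @param rgSet non-empty character vector of reference genes; an RG that
#'   is not in the matrix (e.g. removed by QC) is an error.
#' @param targets character vector of target genes (default: all genes not
#'   in \code{rgSet}).
#' @return a \linkS4class{NrqReport} (comparison table empty until
#'   \code{\link{compareGroups}}).
#' @examples
#' p <- simulateCqPanel(nGenes = 6, groupSizes = c(a = 5, b = 5), seed = 6)
#' mat <- excludeIncompleteGenes(p$panel)$matrix
#' rep <- normalizeToReference(mat, rgSet = rownames(mat)[1:2],
#'                             targets = rownames(mat)[3])
#' @export
normalizeToReference <- function(mat, rgSet, targets = NULL) {
  if (!length(rgSet)) stop("rgSet must be non-empty")
  L <- .asLog2(mat)
  rq <- rqValues(L)
  absent <- setdiff(rgSet, rownames(rq))
  if (length(absent))
    stop("reference gene(s) not in the retained matrix (excluded by QC?): ",
         paste(absent, collapse = ", "))
  if (is.null(targets)) targets <- setdiff(rownames(rq), rgSet)
  absentT <- setdiff(targets, rownames(rq))
  if (length(absentT))
    stop("target gene(s) not in the retained matrix: ",
         paste(absentT, collapse = ", "))
  nf <- exp(colMeans(log(rq[rgSet, , drop = FALSE])))
  nrq <- sweep(rq[targets, , drop = FALSE], 2L, nf, "/")
  new("NrqReport", rgSet = rgSet, nf = nf,
      rq = rq[targets, , drop = FALSE], nrq = nrq,
      comparison = data.frame(), groups = sampleGroups(L))
}

#' Two-group comparison of normalized relative quantities
#'
#' For each target gene, compares NRQ between the two groups with the
#' Mann-Whitney test, and summarizes the effect as the ratio of group
#' medians (second group over first).  Significance stars: \code{**} for
#' p below the stricter level, \code{*} for p below the looser one.
#' No multiple-testing adjustment is applied by default.
#'
#' @param report a \linkS4class{NrqReport}.
#' @param groupOrder optional length-2 character: reference group first,
#'   test group second (default: sorted unique labels).
#' @param alpha significance levels, stricter first.
#' @param bonferroni apply a Bonferroni correction over the target genes
#'   before annotating significance.
#' @param useMean summarize fold change with group means instead of
#'   medians.
#' @return the report with its \code{comparison} table filled in
#'   (columns: gene, medianA, medianB, foldChange, U, p, signif).
#' @export
compareGroups <- function(report, groupOrder = NULL, alpha = c(0.01, 0.05),
                          bonferroni = FALSE, useMean = FALSE) {
  stopifnot(is(report, "NrqReport"))
  grp <- report@groups
  labs <- if (is.null(groupOrder)) sort(unique(unname(grp))) else groupOrder
  if (length(labs) != 2L)
    stop("exactly two groups are required; found: ",
         paste(sort(unique(unname(grp))), collapse = ", "))
  a <- names(grp)[grp == labs[1L]]
  b <- names(grp)[grp == labs[2L]]
  if (!length(a) || !length(b))
    stop("group '", labs[which(!c(length(a), length(b)))[1L]],
         "' has no samples")
  alpha <- sort(alpha)
  centre <- if (useMean) mean else stats::median

  rows <- lapply(rownames(report@nrq), function(g) {
    va <- report@nrq[g, a]; vb <- report@nrq[g, b]
    mw <- mannWhitneyU(va, vb)
    data.frame(gene = g, medianA = centre(va), medianB = centre(vb),
               foldChange = centre(vb) / centre(va), U = mw$U, p = mw$p)
  })
  cmp <- do.call(rbind, rows)
  pAdj <- if (bonferroni) pmin(1, cmp$p * nrow(cmp)) else cmp$p
  cmp$signif <- ifelse(pAdj < alpha[1L], "**",
                       ifelse(pAdj < alpha[2L], "*", ""))
  names(cmp)[names(cmp) == "medianA"] <- paste0("median_", labs[1L])
  names(cmp)[names(cmp) == "medianB"] <- paste0("median_", labs[2L])
  report@comparison <- cmp
  report
}

#' One-call normalization evaluation
#'
#' Convenience wrapper: \code{\link{normalizeToReference}} followed by
#' \code{\link{compareGroups}}.
#'
#' @inheritParams normalizeToReference
#' @inheritParams compareGroups
#' @return a \linkS4class{NrqReport} with the comparison table filled.
#' @export
evaluateNormalization <- function(mat, rgSet, targets = NULL,
                                  groupOrder = NULL, alpha = c(0.01, 0.05),
                                  bonferroni = FALSE, useMean = FALSE) {
  compareGroups(normalizeToReference(mat, rgSet, targets),
                groupOrder = groupOrder, alpha = alpha,
                bonferroni = bonferroni, useMean = useMean)
}

#' @describeIn sampleGroups group labels carried by an NRQ report
#' @export
setMethod("sampleGroups", "NrqReport", function(x) x@groups)

setMethod("show", "NrqReport", function(object) {
  cat(sprintf("NRQ report: %d target gene(s) normalized to {%s}\n",
              nrow(object@nrq), paste(object@rgSet, collapse = ", ")))
  if (nrow(object@comparison)) {
    print(object@comparison, row.names = FALSE, digits = 4)
  } else {
    cat("  (no group comparison yet; see compareGroups())\n")
  }
})
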