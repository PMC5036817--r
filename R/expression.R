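#' Convert aggregated Cq to log2 relative quantities
#'
#' Relative quantities express each gene's level relative to an anchor:
#' \code{log2rq(g, s) = log2(base) * (anchorCq(g) - Cq(g, s))}, where the
#' anchor is the per-gene mean Cq (default; gives geometric-mean-centred
#' RQ, the qBase convention) or the per-gene minimum (RQ relative to the
#' most-expressed sample).  A single amplification factor per cycle is
#' assumed for all assays, \code{base = 2} by default, appropriate when
#' the instrument's Cq calls are already efficiency-corrected.
#'
#' The choice of anchor shifts each gene's log2rq by a constant only, so
#' every log-ratio-based stability statistic is unaffected by it.
#'
#' @param mat a \linkS4class{CqMatrix} on the \code{"cq"} scale, complete.
#' @param base amplification factor per cycle, > 1.
#' @param anchor \code{"mean"} or \code{"min"}.
#' @return a \linkS4class{CqMatrix} on the \code{"log2rq"} scale.
#' @examples
#' m <- CqMatrix(matrix(c(20, 22, 24, 24), 2, 2,
#'                      dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'               groups = c("a", "b"), scale = "cq")
#' assay(toLog2Rq(m))
#' @export
toLog2Rq <- function(mat, base = 2, anchor = c("mean", "min")) {
  anchor <- match.arg(anchor)
  stopifnot(is(mat, "CqMatrix"), cqScale(mat) == "cq", base > 1)
  x <- assay(mat)
  if (anyNA(x)) stop("Cq matrix must be complete; run QC filtering first")
  a <- if (anchor == "mean") rowMeans(x) else apply(x, 1L, min)
  l2 <- log2(base) * (a - x)
  CqMatrix(l2, sampleGroups(mat), scale = "log2rq")
}

#' Relative quantities from a log2rq matrix
#'
#' @param mat a \linkS4class{CqMatrix} on the \code{"log2rq"} scale.
#' @return numeric gene x sample matrix of RQ values (\code{2^log2rq}).
#' @export
rqValues <- function(mat) {
  stopifnot(is(mat, "CqMatrix"), cqScale(mat) == "log2rq")
  2^assay(mat)
}

# Stability algorithms work on the log2 scale; Cq is itself a (negated)
# log2 abundance, so accept either and convert mean-anchored when needed.
.asLog2 <- function(mat) {
  if (cqScale(mat) == "log2rq") mat
  else if (cqScale(mat) == "cq") toLog2Rq(mat)
  else stop("expected a matrix on the 'cq' or 'log2rq' scale")
}
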