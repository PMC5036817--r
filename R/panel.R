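#' Construct a CqPanel from a replicate-level Cq array
#'
#' @param cq numeric array gene x sample x replicate (dimnames on the first
#'   two margins are the gene and sample identifiers), with \code{NA} for
#'   non-amplified reactions.
#' @param groups named character vector mapping every sample to its group
#'   label, or an unnamed vector in sample order.
#' @return a \linkS4class{CqPanel}.
#' @examples
#' cq <- array(rnorm(2 * 3 * 2, 25, 1), dim = c(2, 3, 2),
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"), NULL))
#' CqPanel(cq, groups = c(s1 = "control", s2 = "control", s3 = "infected"))
#' @export
CqPanel <- function(cq, groups) {
  stopifnot(is.array(cq), length(dim(cq)) == 3L)
  genes <- dimnames(cq)[[1L]]
  samples <- dimnames(cq)[[2L]]
  if (is.null(genes) || is.null(samples))
    stop("cq array needs gene and sample dimnames")
  if (is.null(names(groups))) {
    if (length(groups) != length(samples))
      stop("unnamed 'groups' must have one label per sample")
    names(groups) <- samples
  }
  missing_meta <- setdiff(samples, names(groups))
  if (length(missing_meta))
    stop("no group label for sample(s): ", paste(missing_meta, collapse = ", "))
  nrep <- dim(cq)[3L]
  reps <- lapply(seq_len(nrep), function(r) {
    m <- cq[, , r, drop = FALSE]
    dim(m) <- dim(cq)[1:2]
    dimnames(m) <- list(genes, samples)
    m
  })
  names(reps) <- paste0("rep", seq_len(nrep))
  se <- SummarizedExperiment(
    assays = reps,
    colData = DataFrame(group = unname(as.character(groups[samples])),
                        row.names = samples))
  new("CqPanel", se)
}

#' @describeIn sampleGroups group labels of a replicate-level panel
#' @export
setMethod("sampleGroups", "CqPanel", function(x) {
  stats::setNames(as.character(colData(x)$group), colnames(x))
})

#' @describeIn sampleGroups group labels of an aggregated matrix
#' @export
setMethod("sampleGroups", "CqMatrix", function(x) {
  stats::setNames(as.character(colData(x)$group), colnames(x))
})

#' @describeIn nReplicates replicate count of a panel
#' @export
setMethod("nReplicates", "CqPanel", function(x) length(assays(x)))

#' @describeIn cqArray replicate-level values of a panel
#' @export
setMethod("cqArray", "CqPanel", function(x) {
  reps <- as.list(assays(x))
  arr <- array(NA_real_, dim = c(nrow(x), ncol(x), length(reps)),
               dimnames = list(rownames(x), colnames(x),
                               paste0("rep", seq_along(reps))))
  for (r in seq_along(reps)) arr[, , r] <- as.matrix(reps[[r]])
  arr
})

#' Restrict a panel or matrix to samples in given groups
#'
#' Cohort selection for per-cohort stability analyses: keeps the samples
#' whose group label is in \code{labels}.
#'
#' @param x a \linkS4class{CqPanel} or \linkS4class{CqMatrix}.
#' @param labels character, the group labels to retain.
#' @return an object of the same class with the matching samples.
#' @export
subsetByGroup <- function(x, labels) {
  g <- sampleGroups(x)
  absent <- setdiff(labels, unique(g))
  if (length(absent))
    stop("group label(s) not present: ", paste(absent, collapse = ", "))
  x[, g %in% labels]
}

#' Construct a CqMatrix
#'
#' @param values numeric gene x sample matrix with dimnames.
#' @param groups named character vector (sample -> group) or unnamed vector
#'   in column order.
#' @param scale one of \code{"cq"}, \code{"log2rq"}, \code{"rq"}.
#' @return a \linkS4class{CqMatrix}.
#' @export
CqMatrix <- function(values, groups, scale = c("cq", "log2rq", "rq")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values))
  samples <- colnames(values)
  if (is.null(rownames(values)) || is.null(samples))
    stop("values needs gene and sample dimnames")
  if (is.null(names(groups))) {
    if (length(groups) != length(samples))
      stop("unnamed 'groups' must have one label per sample")
    names(groups) <- samples
  }
  if (length(setdiff(samples, names(groups))))
    stop("missing group label for some samples")
  a <- stats::setNames(list(values), scale)
  se <- SummarizedExperiment(
    assays = a,
    colData = DataFrame(group = unname(as.character(groups[samples])),
                        row.names = samples))
  new("CqMatrix", se, scale = scale)
}

#' Measurement scale of a CqMatrix
#' @param x a \linkS4class{CqMatrix}.
#' @return character scalar.
#' @export
cqScale <- function(x) x@scale

setMethod("show", "CqPanel", function(object) {
  g <- table(sampleGroups(object))
  cat(sprintf("CqPanel: %d genes x %d samples x %d replicates\n",
              nrow(object), ncol(object), nReplicates(object)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(g), as.integer(g)),
                       collapse = ", "), "\n")
  nmiss <- sum(vapply(as.list(assays(object)), function(a) sum(is.na(a)), 0))
  cat(sprintf("non-amplified reactions: %d of %d\n", nmiss,
              nrow(object) * ncol(object) * nReplicates(object)))
})

setMethod("show", "CqMatrix", function(object) {
  cat(sprintf("CqMatrix [%s]: %d genes x %d samples", cqScale(object),
              nrow(object), ncol(object)))
  nmiss <- sum(is.na(assay(object)))
  if (nmiss) cat(sprintf(" (%d non-amplified cells)", nmiss))
  cat("\n")
})
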