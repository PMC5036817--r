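#' Simulate a replicate-level Cq panel with known ground truth
#'
#' Generates Cq values under the additive model on the cycle (log2) scale
#' that the stability algorithms assume:
#' \deqn{Cq(g,s,r) = B_g + L_s + \Delta_g [group(s) = B] + \epsilon_{gs} +
#'   \tau_{gsr}}
#' with per-gene baseline \eqn{B_g}, per-sample loading offset
#' \eqn{L_s \sim N(0, loadingSd)}, a group shift \eqn{\Delta_g} applied to
#' every group after the first (a negative shift means up-regulation),
#' biological noise \eqn{\epsilon \sim N(0, \sigma_g)} and technical
#' replicate noise \eqn{\tau \sim N(0, techSd)}.  Optionally, replicate
#' level dropout (non-amplification) is planted in a subset of genes, with
#' the guarantee that every affected gene contains at least one fully
#' missing gene x sample cell, so the missing-amplification exclusion rule
#' removes exactly the affected genes.
#'
#' Gene parameters are either supplied as \code{geneParams} or drawn from
#' the defaults: baseline Cq uniform on \code{baselineRange}; the first
#' \code{nStable} genes get biological sd uniform on \code{stableSdRange}
#' and zero group shift (designed-stable), the rest uniform on
#' \code{unstableSdRange} with group shifts from \code{shiftRange}.
#'
#' @param nGenes number of genes (ignored when \code{geneParams} is given).
#' @param geneParams optional data.frame with columns \code{gene},
#'   \code{baselineCq}, \code{bioSd}, \code{groupShift}.
#' @param groupSizes named integer vector, group label -> number of
#'   samples (default the two-cohort design \code{c(control = 23,
#'   infected = 24)}).
#' @param nReplicates technical replicates per reaction (default 3).
#' @param nStable number of designed-stable genes under default parameters
#'   (default half the panel).
#' @param baselineRange,stableSdRange,unstableSdRange,shiftRange ranges
#'   (cycles) for the default gene-parameter draws; \code{shiftRange} is
#'   the group-shift magnitude range for non-stable genes, applied with
#'   random sign, and defaults to no shift.
#' @param loadingSd per-sample loading offset sd (cycles, default 0.5).
#' @param techSd technical replicate sd (cycles, default 0.1).
#' @param dropout \code{NULL} or a list: \code{genes} (affected genes) or
#'   \code{nGenesAffected}; \code{nMissing} (replicate-level missing count
#'   per affected gene, recycled) or \code{totalMissing} (split as evenly
#'   as possible); \code{placement} \code{"detection"} (default: dropout
#'   concentrates in the highest-Cq genes/cells, mimicking detection-limit
#'   censoring) or \code{"uniform"} (random cells).  Each per-gene count
#'   must lie between \code{nReplicates} (to allow the guaranteed fully
#'   missing cell) and the gene's total reaction count.
#' @param seed integer seed; identical config + seed gives an identical
#'   panel.
#' @return list with \code{panel} (a \linkS4class{CqPanel}) and
#'   \code{truth} (gene parameters, loading offsets, group labels and the
#'   dropout placement).
#' @examples
#' sim <- simulateCqPanel(nGenes = 10, groupSizes = c(a = 6, b = 6),
#'                        seed = 11)
#' sim$panel
#' @export
simulateCqPanel <- function(nGenes = NULL, geneParams = NULL,
                            groupSizes = c(control = 23, infected = 24),
                            nReplicates = 3L, nStable = NULL,
                            baselineRange = c(18, 32),
                            stableSdRange = c(0.1, 0.25),
                            unstableSdRange = c(0.5, 2.0),
                            shiftRange = c(0, 0),
                            loadingSd = 0.5, techSd = 0.1,
                            dropout = NULL, seed = 1L) {
  stopifnot(loadingSd >= 0, techSd >= 0, nReplicates >= 1L,
            all(groupSizes >= 1L), !is.null(names(groupSizes)))
  set.seed(as.integer(seed))

  if (is.null(geneParams)) {
    if (is.null(nGenes)) stop("supply nGenes or geneParams")
    if (is.null(nStable)) nStable <- floor(nGenes / 2)
    stopifnot(nStable >= 0, nStable <= nGenes)
    nUn <- nGenes - nStable
    geneParams <- data.frame(
      gene = sprintf("gene%02d", seq_len(nGenes)),
      baselineCq = stats::runif(nGenes, baselineRange[1L], baselineRange[2L]),
      bioSd = c(stats::runif(nStable, stableSdRange[1L], stableSdRange[2L]),
                stats::runif(nUn, unstableSdRange[1L], unstableSdRange[2L])),
      groupShift = c(rep(0, nStable),
                     stats::runif(nUn, shiftRange[1L], shiftRange[2L]) *
                       sample(c(-1, 1), nUn, replace = TRUE)),
      stable = rep(c(TRUE, FALSE), c(nStable, nUn)))
  } else {
    need <- c("gene", "baselineCq", "bioSd", "groupShift")
    if (!all(need %in% colnames(geneParams)))
      stop("geneParams needs columns ", paste(need, collapse = ", "))
    if (anyDuplicated(geneParams$gene)) stop("duplicate gene names")
    if (any(geneParams$bioSd < 0)) stop("bioSd must be >= 0")
  }
  genes <- geneParams$gene
  nG <- length(genes)

  labels <- rep(names(groupSizes), groupSizes)
  samples <- sprintf("%s_%02d", labels,
                     unlist(lapply(groupSizes, seq_len), use.names = FALSE))
  nS <- length(samples)
  groups <- stats::setNames(labels, samples)
  inShifted <- as.numeric(labels != names(groupSizes)[1L])

  loading <- stats::rnorm(nS, 0, loadingSd)
  eps <- matrix(stats::rnorm(nG * nS), nG, nS) * geneParams$bioSd
  mu <- outer(geneParams$baselineCq, loading, "+") +
    outer(geneParams$groupShift, inShifted) + eps
  arr <- array(NA_real_, dim = c(nG, nS, nReplicates),
               dimnames = list(genes, samples, NULL))
  for (r in seq_len(nReplicates))
    arr[, , r] <- mu + matrix(stats::rnorm(nG * nS, 0, techSd), nG, nS)

  dropPlacement <- NULL
  if (!is.null(dropout)) {
    placement <- if (is.null(dropout$placement)) "detection"
                 else match.arg(dropout$placement, c("detection", "uniform"))
    affected <- dropout$genes
    if (is.null(affected)) {
      nA <- dropout$nGenesAffected
      if (is.null(nA)) stop("dropout needs 'genes' or 'nGenesAffected'")
      if (nA > nG) stop("more affected genes than genes in the panel")
      affected <- if (placement == "detection")
        genes[order(-geneParams$baselineCq)][seq_len(nA)]
      else sample(genes, nA)
    }
    if (length(setdiff(affected, genes)))
      stop("dropout genes not in the panel: ",
           paste(setdiff(affected, genes), collapse = ", "))
    counts <- dropout$nMissing
    if (is.null(counts)) {
      tot <- dropout$totalMissing
      if (is.null(tot)) stop("dropout needs 'nMissing' or 'totalMissing'")
      nA <- length(affected)
      base <- tot %/% nA; extra <- tot %% nA
      counts <- rep(base, nA) + rep(c(1L, 0L), c(extra, nA - extra))
    } else {
      counts <- rep(counts, length.out = length(affected))
    }
    maxPer <- nS * nReplicates
    if (any(counts < nReplicates) || any(counts > maxPer))
      stop(sprintf(paste("infeasible dropout: per-gene missing counts must",
                         "lie in [%d, %d]"), nReplicates, maxPer))
    dropPlacement <- vector("list", length(affected))
    names(dropPlacement) <- affected
    for (j in seq_along(affected)) {
      g <- affected[j]
      cellMeans <- rowMeans(matrix(arr[match(g, genes), , ], nS, nReplicates))
      cellOrder <- if (placement == "detection")
        order(-cellMeans) else sample(nS)
      m <- counts[j]
      slots <- matrix(NA_integer_, nrow = 0L, ncol = 2L)
      for (s in cellOrder) {
        take <- min(nReplicates, m - nrow(slots))
        if (take <= 0L) break
        slots <- rbind(slots, cbind(rep(s, take), seq_len(take)))
      }
      arr[cbind(match(g, genes), slots[, 1L], slots[, 2L])] <- NA_real_
      dropPlacement[[j]] <- data.frame(sample = samples[slots[, 1L]],
                                       replicate = slots[, 2L])
    }
  }

  panel <- CqPanel(arr, groups = groups)
  truth <- list(genes = geneParams,
                loading = stats::setNames(loading, samples),
                groups = groups, loadingSd = loadingSd, techSd = techSd,
                nReplicates = nReplicates, dropout = dropPlacement,
                seed = as.integer(seed))
  list(panel = panel, truth = truth)
}

#' Deterministic study-scale Cq fixture
#'
#' A fixed-seed panel emulating a high-throughput TaqMan OpenArray screen
#' of mouse spleen samples: 112 assays x 47 samples (23 control + 24
#' infected) x 3 replicates = 15792 reactions.  Exactly 1516 replicate
#' level reactions are non-amplified, concentrated in the 41
#' highest-baseline (lowest-expression) filler genes — each of which
#' contains at least one fully missing gene x sample cell — so the
#' missing-amplification exclusion rule retains exactly the 71 complete
#' genes.
#'
#' The named genes carry designed behaviour: a designed-stable block
#' (biological sd 0.1-0.25 cycles, no group effect) that includes
#' \emph{Il2rg} and \emph{Itgb2}; six classical reference-gene candidates
#' (\emph{Hprt}, \emph{Ubc}, \emph{B2m}, \emph{Pgk1}, \emph{Polr2a},
#' \emph{Tbp}) with mixed, mostly mediocre stability; and the cytokine
#' targets \emph{Cxcl10}, \emph{Ifng} and \emph{Tnf} with planted
#' up-regulation in the infected group (negative Cq shifts of 2.5, 2 and
#' 1.5 cycles).  All values are synthetic; the panel reproduces the
#' study design's bookkeeping, not its measured data.
#'
#' @return list with \code{panel} and \code{truth}, as
#'   \code{\link{simulateCqPanel}}.
#' @examples
#' fx <- studyScalePanel()
#' excludeIncompleteGenes(fx$panel)$report
#' @export
studyScalePanel <- function() {
  stableBlock <- data.frame(
    gene = c("Il2rg", "Itgb2", "Il10ra", "Stat6", "Myd88",
             "Il10rb", "Il6st", "Tgfbr1", "Stat4", "Il18bp"),
    bioSd = c(0.10, 0.12, 0.15, 0.16, 0.18, 0.19, 0.21, 0.22, 0.24, 0.25),
    groupShift = 0, stable = TRUE)
  classical <- data.frame(
    gene = c("Hprt", "Ubc", "B2m", "Pgk1", "Polr2a", "Tbp"),
    bioSd = c(0.30, 0.60, 1.00, 0.55, 1.20, 0.90),
    groupShift = c(0, 0, 0.5, 0, 0.4, 0.3), stable = FALSE)
  targets <- data.frame(
    gene = c("Cxcl10", "Ifng", "Tnf"),
    bioSd = c(0.6, 0.7, 0.6),
    groupShift = c(-2.5, -2.0, -1.5), stable = FALSE)

  seed <- 20160926L
  set.seed(seed)
  nFill <- 112L - nrow(stableBlock) - nrow(classical) - nrow(targets)
  fillers <- data.frame(
    gene = sprintf("Assay%03d", seq_len(nFill)),
    bioSd = stats::runif(nFill, 0.5, 2.0),
    groupShift = ifelse(stats::runif(nFill) < 0.2,
                        stats::runif(nFill, 0.3, 1.5) *
                          sample(c(-1, 1), nFill, replace = TRUE), 0),
    stable = FALSE)
  gp <- rbind(stableBlock, classical, targets, fillers)
  # named genes express well (low-mid Cq) and are never hit by dropout;
  # fillers span the full range, the high-Cq tail takes the dropout
  nNamed <- nrow(gp) - nFill
  gp$baselineCq <- c(stats::runif(nNamed, 19, 26),
                     stats::runif(nFill, 18, 32))
  gp <- gp[, c("gene", "baselineCq", "bioSd", "groupShift", "stable")]

  dropGenes <- fillers$gene[order(-gp$baselineCq[match(fillers$gene,
                                                       gp$gene)])][1:41]
  simulateCqPanel(geneParams = gp,
                  groupSizes = c(control = 23, infected = 24),
                  nReplicates = 3L, loadingSd = 0.5, techSd = 0.1,
                  dropout = list(genes = dropGenes, totalMissing = 1516L,
                                 placement = "detection"),
                  seed = seed)
}
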