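#' Run the full reference-gene stability pipeline
#'
#' Orchestrates the whole analysis on a replicate-level panel: QC
#' filtering, the four stability algorithms and their comprehensive
#' aggregation per cohort, the top-n consensus across geNorm, NormFinder
#' and the comprehensive ranking, and — when reference-gene sets are
#' supplied — NRQ evaluation of target genes with a two-group comparison.
#' All reports are written as TSV/JSON files under \code{outDir}, one
#' subdirectory per cohort, plus a manifest recording the package version,
#' a hash of the configuration and the seed, so a run is reproducible from
#' its manifest.
#'
#' @param panel a \linkS4class{CqPanel}.
#' @param outDir output directory (created if needed).
#' @param cohorts named list of group-label vectors defining the cohorts;
#'   the default analyses each group separately plus all samples combined.
#' @param rgSets named list of reference-gene sets to evaluate (e.g.
#'   \code{list(selected = c("Il2rg", "Itgb2"), classical = c("Polr2a",
#'   "Tbp"))}); evaluation runs on the combined cohort.
#' @param targets target genes for the NRQ evaluation.
#' @param qcMode exclusion mode, see \code{\link{excludeIncompleteGenes}}.
#' @param topN size of the top lists intersected for the consensus set.
#' @param mThreshold,vThreshold geNorm thresholds.
#' @param alpha significance levels for the group comparison.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given the panel).
#' @param verbose print one progress line per stage.
#' @return invisibly, a nested list of all in-memory results (per cohort:
#'   \code{qc}, \code{genorm}, \code{normfinder}, \code{bestkeeper},
#'   \code{deltact}, \code{comprehensive}, \code{consensus}; plus
#'   \code{evaluation} per reference-gene set and \code{manifest}).
#' @examples
#' \donttest{
#' fx <- studyScalePanel()
#' res <- runStabilityPipeline(fx$panel, outDir = tempfile("run"),
#'                             rgSets = list(selected = c("Il2rg", "Itgb2")),
#'                             targets = c("Cxcl10", "Ifng", "Tnf"))
#' }
#' @export
runStabilityPipeline <- function(panel, outDir,
                                 cohorts = NULL,
                                 rgSets = NULL,
                                 targets = NULL,
                                 qcMode = c("cell", "replicate"),
                                 topN = 10L,
                                 mThreshold = 0.5, vThreshold = 0.15,
                                 alpha = c(0.01, 0.05),
                                 seed = 1L, verbose = FALSE) {
  qcMode <- match.arg(qcMode)
  stopifnot(is(panel, "CqPanel"))
  labels <- unique(unname(sampleGroups(panel)))
  if (is.null(cohorts)) {
    cohorts <- c(stats::setNames(as.list(labels), labels),
                 list(combined = labels))
  }
  bad <- setdiff(unique(unlist(cohorts)), labels)
  if (length(bad))
    stop("cohort label(s) absent from the panel: ",
         paste(bad, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  results <- list()
  for (co in names(cohorts)) {
    sub <- subsetByGroup(panel, cohorts[[co]])
    codir <- file.path(outDir, co)
    dir.create(codir, showWarnings = FALSE)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("cohort '%s', stage '%s': %s", co, what,
                     conditionMessage(e)), call. = FALSE))
    }
    qc <- stage("qc", excludeIncompleteGenes(sub, mode = qcMode))
    say("[%s] qc: %d/%d genes retained, %d samples", co,
        qc$report@nGenesRetained, qc$report@nGenesInput, ncol(sub))
    writeReport(qc$report, file.path(codir, "qc_report.json"))
    mat <- qc$matrix

    gn <- stage("genorm", geNorm(mat, mThreshold, vThreshold))
    multigroup <- length(unique(sampleGroups(mat))) >= 2L
    nf <- stage("normfinder", normFinder(mat, useGroups = multigroup))
    bk <- stage("bestkeeper", bestKeeper(mat))
    dc <- stage("deltact", deltaCt(mat))
    cr <- stage("aggregate", comprehensiveRanking(gn, nf, bk, dc))
    say("[%s] stability: top gene %s (comprehensive)", co,
        geneRanking(cr)[1L])

    writeReport(gn, file.path(codir, "genorm.json"))
    writeReport(stabilityTable(gn), file.path(codir, "genorm_ranking.tsv"))
    writeReport(nf, file.path(codir, "normfinder.json"))
    writeReport(stabilityTable(nf), file.path(codir, "normfinder_ranking.tsv"))
    writeReport(bk, file.path(codir, "bestkeeper.tsv"))
    writeReport(dc, file.path(codir, "deltact_ranking.tsv"))
    writeReport(cr, file.path(codir, "comprehensive.tsv"))

    cons <- consensusTop(list(gn, nf, cr), n = min(topN, nrow(mat)))
    writeLines(cons, file.path(codir, sprintf("consensus_top%d.txt", topN)))
    results[[co]] <- list(qc = qc$report, matrix = mat, genorm = gn,
                          normfinder = nf, bestkeeper = bk, deltact = dc,
                          comprehensive = cr, consensus = cons)
  }

  if (!is.null(rgSets)) {
    full <- excludeIncompleteGenes(panel, mode = qcMode)$matrix
    ev <- list()
    for (nm in names(rgSets)) {
      rep <- evaluateNormalization(full, rgSets[[nm]], targets,
                                   alpha = alpha)
      writeReport(rep, file.path(outDir,
                                 sprintf("evaluation_%s.json", nm)))
      say("evaluation [%s]: %d target(s), RG = {%s}", nm,
          nrow(rep@nrq), paste(rgSets[[nm]], collapse = ", "))
      ev[[nm]] <- rep
    }
    results$evaluation <- ev
  }

  config <- list(cohorts = cohorts, rgSets = rgSets, targets = targets,
                 qcMode = qcMode, topN = topN, mThreshold = mThreshold,
                 vThreshold = vThreshold, alpha = alpha, seed = seed)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "qpcrStability",
    version = as.character(utils::packageVersion("qpcrStability")),
    config_md5 = unname(tools::md5sum(cfgPath)),
    seed = seed,
    panel = list(genes = nrow(panel), samples = ncol(panel),
                 replicates = nReplicates(panel)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
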