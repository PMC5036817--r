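test_that("identical config and seed give identical panels", {
  a <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 5, b = 5),
                       dropout = list(genes = "gene08", nMissing = 4),
                       seed = 60)
  b <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 5, b = 5),
                       dropout = list(genes = "gene08", nMissing = 4),
                       seed = 60)
  expect_identical(cqArray(a$panel), cqArray(b$panel))
  expect_identical(a$truth$genes, b$truth$genes)
  c <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 5, b = 5), seed = 61)
  expect_false(identical(cqArray(a$panel)[1, 1, 1], cqArray(c$panel)[1, 1, 1]))
})

test_that("the noise-free limit is recomputable from the ground truth", {
  gp <- data.frame(gene = c("g1", "g2", "g3"),
                   baselineCq = c(20, 25, 30),
                   bioSd = 0, groupShift = c(0, 1, -2))
  sim <- simulateCqPanel(geneParams = gp, groupSizes = c(a = 3, b = 3),
                         loadingSd = 0, techSd = 0, seed = 62)
  arr <- cqArray(sim$panel)
  tr <- sim$truth
  for (g in gp$gene) for (s in names(tr$groups)) {
    expected <- gp$baselineCq[gp$gene == g] +
      gp$groupShift[gp$gene == g] * (tr$groups[[s]] == "b")
    expect_equal(unname(arr[g, s, ]), rep(expected, 3))
  }
  # with no group effects either, downstream statistics hit their minima
  gp0 <- transform(gp, groupShift = 0)
  sim0 <- simulateCqPanel(geneParams = gp0, groupSizes = c(a = 3, b = 3),
                          loadingSd = 0, techSd = 0, seed = 62)
  mat <- excludeIncompleteGenes(sim0$panel)$matrix
  expect_equal(unname(deltaCt(mat)@scores), rep(0, 3), tolerance = 1e-12)
  expect_equal(bestKeeper(mat)@table$sdCq, rep(0, 3), tolerance = 1e-12)
})

test_that("planted dropout counts are exact and QC reproduces them", {
  sim <- simulateCqPanel(nGenes = 10, groupSizes = c(a = 6, b = 6),
                         dropout = list(genes = c("gene07", "gene09"),
                                        nMissing = c(7, 4)),
                         seed = 63)
  arr <- cqArray(sim$panel)
  expect_equal(sum(is.na(arr)), 11L)
  expect_equal(sum(is.na(arr["gene07", , ])), 7L)
  expect_equal(sum(is.na(arr["gene09", , ])), 4L)
  # each affected gene has at least one fully missing cell
  for (g in c("gene07", "gene09"))
    expect_true(any(apply(is.na(arr[g, , ]), 1, all)))
  qc <- excludeIncompleteGenes(sim$panel)
  expect_setequal(qc$report@excludedGenes$gene, c("gene07", "gene09"))
  expect_equal(qc$report@nReactionsMissing, 11L)
})

test_that("infeasible dropout specifications are rejected", {
  expect_error(simulateCqPanel(nGenes = 4, groupSizes = c(a = 3, b = 3),
                               dropout = list(genes = "gene01",
                                              nMissing = 2),
                               seed = 1),
               "infeasible")
  expect_error(simulateCqPanel(nGenes = 4, groupSizes = c(a = 3, b = 3),
                               dropout = list(genes = "gene01",
                                              nMissing = 100),
                               seed = 1),
               "infeasible")
  expect_error(simulateCqPanel(nGenes = 4, groupSizes = c(a = 3, b = 3),
                               dropout = list(genes = "nope", nMissing = 3),
                               seed = 1),
               "not in the panel")
})

test_that("designed-stable genes are recovered by every ranking", {
  hits <- 0L
  nRuns <- 20L
  for (r in seq_len(nRuns)) {
    sim <- simulateCqPanel(nGenes = 12, nStable = 4,
                           groupSizes = c(control = 24, infected = 24),
                           seed = 600 + r)
    mat <- excludeIncompleteGenes(sim$panel)$matrix
    stable <- sim$truth$genes$gene[sim$truth$genes$stable]
    cr <- comprehensiveRanking(geNorm(mat), normFinder(mat),
                               bestKeeper(mat), deltaCt(mat))
    if (setequal(utils::head(geneRanking(cr), 4), stable)) hits <- hits + 1L
  }
  expect_gte(hits, nRuns - 1L)
})

test_that("the study-scale fixture has the designed bookkeeping", {
  fx <- studyScalePanel()
  p <- fx$panel
  expect_equal(dim(p), c(112L, 47L))
  expect_equal(nReplicates(p), 3L)
  expect_equal(as.integer(table(sampleGroups(p))[c("control", "infected")]),
               c(23L, 24L))
  arr <- cqArray(p)
  expect_equal(length(arr), 15792L)
  expect_equal(sum(is.na(arr)), 1516L)
  missPerGene <- apply(arr, 1, function(g) sum(is.na(g)))
  expect_equal(sum(missPerGene > 0), 41L)
  # affected genes all carry a fully missing cell; named genes are untouched
  for (g in names(which(missPerGene > 0)))
    expect_true(any(apply(is.na(arr[g, , ]), 1, all)))
  named <- c("Il2rg", "Itgb2", "Hprt", "Ubc", "B2m", "Pgk1", "Polr2a",
             "Tbp", "Cxcl10", "Ifng", "Tnf")
  expect_equal(unname(missPerGene[named]), rep(0L, length(named)))
  # deterministic: a second call is identical
  expect_identical(arr, cqArray(studyScalePanel()$panel))
})
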