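test_that("replicate aggregation averages available values and flags dead cells", {
  arr <- array(NA_real_, dim = c(2, 2, 3),
               dimnames = list(c("g1", "g2"), c("s1", "s2"), NULL))
  arr["g1", "s1", ] <- c(20.0, 20.2, NA)
  arr["g1", "s2", ] <- c(21.0, 21.3, 21.2)
  arr["g2", "s1", ] <- c(30, 30, 30)
  # g2/s2 left fully missing
  p <- CqPanel(arr, groups = c(s1 = "a", s2 = "a"))
  agg <- aggregateReplicates(p)
  m <- assay(agg$matrix)
  expect_equal(m["g1", "s1"], 20.1)
  expect_equal(m["g1", "s2"], mean(c(21.0, 21.3, 21.2)))
  expect_false(agg$nonAmplified["g1", "s1"])
  expect_true(agg$nonAmplified["g2", "s2"])
  expect_true(is.na(m["g2", "s2"]))
})

test_that("exclusion removes exactly the genes with a dead cell", {
  sim <- simulateCqPanel(nGenes = 3, groupSizes = c(a = 4, b = 4),
                         dropout = list(genes = "gene02", nMissing = 3),
                         seed = 21)
  qc <- excludeIncompleteGenes(sim$panel)
  expect_equal(sort(rownames(qc$matrix)), c("gene01", "gene03"))
  rep <- qc$report
  expect_equal(rep@nGenesInput, 3L)
  expect_equal(rep@nGenesExcluded, 1L)
  expect_equal(rep@nGenesRetained, 2L)
  expect_equal(rep@excludedGenes$gene, "gene02")
  expect_equal(rep@nReactionsTotal, 3L * 8L * 3L)
  expect_equal(rep@nReactionsMissing, 3L)
  expect_false(anyNA(assay(qc$matrix)))
})

test_that("clean panels pass through untouched", {
  sim <- simulateCqPanel(nGenes = 4, groupSizes = c(a = 3, b = 3), seed = 2)
  qc <- excludeIncompleteGenes(sim$panel)
  expect_equal(qc$report@nGenesExcluded, 0L)
  expect_equal(qc$report@fractionMissing, 0)
  expect_equal(nrow(qc$matrix), 4L)
})

test_that("replicate mode is stricter than cell mode", {
  # one missing replicate but no dead cell: kept by cell mode only
  arr <- array(25, dim = c(2, 2, 3),
               dimnames = list(c("g1", "g2"), c("s1", "s2"), NULL))
  arr["g1", "s1", 1] <- NA
  p <- CqPanel(arr, groups = c(s1 = "a", s2 = "a"))
  expect_equal(excludeIncompleteGenes(p, "cell")$report@nGenesExcluded, 0L)
  qcr <- excludeIncompleteGenes(p, "replicate")
  expect_equal(qcr$report@excludedGenes$gene, "g1")
})

test_that("exclusion is idempotent and counts match a brute-force tally", {
  sim <- simulateCqPanel(nGenes = 8, groupSizes = c(a = 5, b = 5),
                         dropout = list(genes = c("gene06", "gene07"),
                                        nMissing = c(5, 3)),
                         seed = 33)
  qc <- excludeIncompleteGenes(sim$panel)
  expect_equal(qc$report@nReactionsMissing, sum(is.na(cqArray(sim$panel))))

  # rebuild a panel from the retained matrix (1 replicate) and re-filter
  vals <- assay(qc$matrix)
  arr <- array(vals, dim = c(dim(vals), 1L),
               dimnames = c(dimnames(vals), list(NULL)))
  again <- excludeIncompleteGenes(CqPanel(arr, sampleGroups(qc$matrix)))
  expect_equal(rownames(again$matrix), rownames(qc$matrix))
  expect_equal(again$report@nGenesExcluded, 0L)
})

test_that("QC counts are invariant to gene and sample permutations", {
  sim <- simulateCqPanel(nGenes = 6, groupSizes = c(a = 4, b = 4),
                         dropout = list(genes = "gene05", nMissing = 6),
                         seed = 8)
  qc1 <- excludeIncompleteGenes(sim$panel)$report
  set.seed(1)
  perm <- sim$panel[sample(nrow(sim$panel)), sample(ncol(sim$panel))]
  qc2 <- excludeIncompleteGenes(perm)$report
  for (slot in c("nGenesExcluded", "nGenesRetained", "nReactionsMissing",
                 "nReactionsTotal"))
    expect_equal(methods::slot(qc1, slot), methods::slot(qc2, slot))
})

test_that("filtering everything is an error", {
  arr <- array(NA_real_, dim = c(2, 2, 2),
               dimnames = list(c("g1", "g2"), c("s1", "s2"), NULL))
  arr["g1", "s1", ] <- c(20, 20); arr["g2", "s1", ] <- c(22, 22)
  p <- CqPanel(arr, groups = c(s1 = "a", s2 = "a"))
  expect_error(excludeIncompleteGenes(p), "no genes retained")
})

test_that("optional Cq ceiling treats late cells as non-amplified", {
  arr <- array(25, dim = c(2, 2, 2),
               dimnames = list(c("g1", "g2"), c("s1", "s2"), NULL))
  arr["g2", "s2", ] <- c(38, 39)
  p <- CqPanel(arr, groups = c(s1 = "a", s2 = "a"))
  expect_equal(excludeIncompleteGenes(p)$report@nGenesExcluded, 0L)
  qc <- excludeIncompleteGenes(p, cqCeiling = 35)
  expect_equal(qc$report@excludedGenes$gene, "g2")
})
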