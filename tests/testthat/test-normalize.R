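test_that("normalization factors are geometric means of RG relative quantities", {
  vals <- matrix(c(20, 21,   # rg1
                   22, 21,   # rg2
                   24, 23),  # target
                 3, 2, byrow = TRUE,
                 dimnames = list(c("rg1", "rg2", "t"), c("s1", "s2")))
  mat <- CqMatrix(vals, groups = c("a", "b"), scale = "cq")
  rep <- normalizeToReference(mat, c("rg1", "rg2"), "t")
  rq <- rqValues(toLog2Rq(mat))
  expect_equal(unname(rep@nf),
               unname(sqrt(rq["rg1", ] * rq["rg2", ])), tolerance = 1e-12)
  expect_equal(unname(rep@nrq["t", ]),
               unname(rq["t", ] / rep@nf), tolerance = 1e-12)

  # two RGs with RQ 1 and 4 in a sample give NF 2 there
  l2 <- matrix(c(0, 0, 2, -2, 1, 1), 3, 2, byrow = TRUE,
               dimnames = list(c("rg1", "rg2", "t"), c("s1", "s2")))
  m2 <- CqMatrix(l2, groups = c("a", "b"), scale = "log2rq")
  rep2 <- normalizeToReference(m2, c("rg1", "rg2"), "t")
  expect_equal(unname(rep2@nf[["s1"]]), 2)
})

test_that("self-normalization gives NRQ identically 1", {
  mat <- randomCqMatrix(3, 6, seed = 50)
  rep <- normalizeToReference(mat, "g1", "g1")
  expect_equal(unname(rep@nrq["g1", ]), rep(1, 6), tolerance = 1e-12)
})

test_that("mean-anchored NF has geometric mean 1 across samples", {
  mat <- randomCqMatrix(6, 10, seed = 51)
  rep <- normalizeToReference(mat, c("g1", "g2", "g3"))
  expect_equal(exp(mean(log(rep@nf))), 1, tolerance = 1e-9)
})

test_that("a QC-excluded reference gene is reported by name", {
  mat <- randomCqMatrix(3, 5, seed = 52)
  expect_error(normalizeToReference(mat, c("g1", "ghost")),
               "excluded by QC.*ghost")
  expect_error(normalizeToReference(mat, character(0)), "non-empty")
})

test_that("Mann-Whitney agrees with exhaustive enumeration on small groups", {
  cases <- list(
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1, 5, 9), y = c(2, 3, 11)),
    list(x = c(0.3, 2.2), y = c(1.1, 4.4, 0.9, 3.3)),
    list(x = c(7, 1, 3, 5), y = c(2, 4, 6)))
  for (cs in cases) {
    got <- mannWhitneyU(cs$x, cs$y)
    ora <- enumMannWhitney(cs$x, cs$y)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
    expect_true(got$exact)
  }
  # the canonical fully separated case
  got <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)
})

test_that("Mann-Whitney is symmetric and null on identical groups", {
  x <- c(1.2, 3.4, 2.2, 5.5); y <- c(0.7, 4.1, 2.9)
  a <- mannWhitneyU(x, y); b <- mannWhitneyU(y, x)
  expect_equal(a$U, b$U)
  expect_equal(a$p, b$p)
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.9)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("large or tied samples fall back to the corrected normal approximation", {
  set.seed(53)
  x <- rnorm(20); y <- rnorm(20, 1)
  got <- mannWhitneyU(x, y)
  expect_false(got$exact)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$p, unname(ref$p.value))
})

test_that("a planted group shift is detected with the right direction", {
  gp <- data.frame(gene = c("rg1", "rg2", "t"),
                   baselineCq = c(22, 24, 26),
                   bioSd = c(0.15, 0.15, 0.3),
                   groupShift = c(0, 0, -2))  # t up-regulated in group b
  sim <- simulateCqPanel(geneParams = gp, groupSizes = c(a = 20, b = 20),
                         seed = 54)
  mat <- excludeIncompleteGenes(sim$panel)$matrix
  rep <- evaluateNormalization(mat, c("rg1", "rg2"), "t")
  cmp <- rep@comparison
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$foldChange, 1)
  expect_equal(cmp$signif, "**")
})

test_that("identical groups give fold change 1", {
  vals <- matrix(rep(c(20, 24, 26), 4), 3, 4,
                 dimnames = list(c("rg1", "rg2", "t"), paste0("s", 1:4)))
  mat <- CqMatrix(vals, groups = c("a", "a", "b", "b"), scale = "cq")
  rep <- evaluateNormalization(mat, c("rg1", "rg2"), "t")
  expect_equal(rep@comparison$foldChange, 1)
})

test_that("p-values are invariant to rescaling every sample's NF", {
  mat <- randomCqMatrix(5, 12, seed = 55)
  rep <- normalizeToReference(mat, c("g1", "g2"), c("g4", "g5"))
  scaled <- rep
  scaled@nf <- rep@nf * 3.7
  scaled@nrq <- rep@nrq / 3.7
  a <- compareGroups(rep); b <- compareGroups(scaled)
  expect_equal(a@comparison$p, b@comparison$p)
  expect_equal(a@comparison$U, b@comparison$U)
})

test_that("reference genes carrying a group effect bias target fold changes", {
  # RGs shifted down (up-regulated) in group b drag target NRQ down
  gp <- data.frame(gene = c("rgBias1", "rgBias2", "rgGood1", "rgGood2", "t"),
                   baselineCq = c(22, 23, 24, 25, 26),
                   bioSd = rep(0.15, 5),
                   groupShift = c(-1.5, -1.5, 0, 0, 0))  # t itself is null
  sim <- simulateCqPanel(geneParams = gp, groupSizes = c(a = 20, b = 20),
                         seed = 56)
  mat <- excludeIncompleteGenes(sim$panel)$matrix
  good <- evaluateNormalization(mat, c("rgGood1", "rgGood2"), "t")
  bias <- evaluateNormalization(mat, c("rgBias1", "rgBias2"), "t")
  expect_lt(bias@comparison$foldChange, good@comparison$foldChange)
  expect_lt(bias@comparison$foldChange, 1)  # pushed opposite to the RG shift
})

test_that("exactly two groups are required for comparison", {
  vals <- matrix(rnorm(9, 25), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  mat <- CqMatrix(vals, groups = c("a", "b", "c"), scale = "cq")
  rep <- normalizeToReference(mat, "g1", "g2")
  expect_error(compareGroups(rep), "exactly two groups")
})
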