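mkTable <- function(genes, ranks, method = "m") {
  new("StabilityTable", method = method,
      table = data.frame(gene = genes, score = ranks, rank = ranks))
}

test_that("geometric-mean aggregation matches direct arithmetic", {
  genes <- c("a", "b", "c")
  cr <- comprehensiveRanking(mkTable(genes, c(2, 1, 3)),
                             mkTable(genes, c(1, 2, 3)),
                             mkTable(genes, c(3, 1, 2)),
                             mkTable(genes, c(2, 1, 3)))
  tab <- cr@table
  expect_equal(tab$geomeanRank[tab$gene == "a"], 12^(1/4))  # 1.8612
  expect_equal(tab$geomeanRank[tab$gene == "b"], 2^(1/4))
  # unanimity: rank 1 everywhere gives geomean 1 and position 1
  cr1 <- comprehensiveRanking(mkTable(genes, 1:3), mkTable(genes, 1:3),
                              mkTable(genes, 1:3), mkTable(genes, 1:3))
  expect_equal(cr1@table$geomeanRank[cr1@table$gene == "a"], 1)
  expect_equal(geneRanking(cr1), genes)
})

test_that("aggregation is symmetric in the order of the four tables", {
  mat <- randomCqMatrix(6, 9, seed = 40)
  gn <- stabilityTable(geNorm(mat)); nf <- stabilityTable(normFinder(mat))
  bk <- stabilityTable(bestKeeper(mat)); dc <- stabilityTable(deltaCt(mat))
  a <- comprehensiveRanking(gn, nf, bk, dc)
  b <- comprehensiveRanking(dc, bk, nf, gn)
  # geomean and position are permutation-invariant; column roles track inputs
  ta <- a@table[order(a@table$gene), ]
  tb <- b@table[order(b@table$gene), ]
  expect_equal(ta$geomeanRank, tb$geomeanRank)
  expect_equal(ta$position, tb$position)
})

test_that("mismatched gene sets are reported with their difference", {
  g1 <- mkTable(c("a", "b", "c"), 1:3)
  g2 <- mkTable(c("a", "b", "d"), 1:3)
  expect_error(comprehensiveRanking(g1, g2, g1, g1),
               "symmetric difference.*c.*d")
})

test_that("improving one method's rank never worsens the geometric mean", {
  genes <- letters[1:5]
  set.seed(41)
  for (rep in 1:10) {
    ranks <- replicate(4, sample(1:5), simplify = FALSE)
    cr <- comprehensiveRanking(mkTable(genes, ranks[[1]]),
                               mkTable(genes, ranks[[2]]),
                               mkTable(genes, ranks[[3]]),
                               mkTable(genes, ranks[[4]]))
    g <- sample(genes, 1)
    i <- match(g, genes)
    if (ranks[[1]][i] == 1) next
    better <- ranks[[1]]
    # swap g one step up in method 1
    j <- which(better == better[i] - 1)
    better[j] <- better[i]; better[i] <- better[i] - 1
    cr2 <- comprehensiveRanking(mkTable(genes, better),
                                mkTable(genes, ranks[[2]]),
                                mkTable(genes, ranks[[3]]),
                                mkTable(genes, ranks[[4]]))
    gm1 <- cr@table$geomeanRank[cr@table$gene == g]
    gm2 <- cr2@table$geomeanRank[cr2@table$gene == g]
    expect_lte(gm2, gm1)
  }
})

test_that("the geNorm final pair can enter aggregation as tied 1.5 ranks", {
  mat <- randomCqMatrix(5, 8, seed = 42)
  gn <- geNorm(mat)
  st <- stabilityTable(gn, tieAverage = TRUE)
  expect_equal(st@table$rank[1:2], c(1.5, 1.5))
  cr <- comprehensiveRanking(gn, normFinder(mat), bestKeeper(mat),
                             deltaCt(mat), genormTieAverage = TRUE)
  expect_setequal(cr@table$rankGeNorm[cr@table$gene %in% geneRanking(gn)[1:2]],
                  c(1.5, 1.5))
})

test_that("consensus is the intersection of top-n lists", {
  r1 <- mkTable(letters[1:6], 1:6)
  r2 <- mkTable(letters[1:6], c(2, 1, 4, 3, 6, 5))
  expect_setequal(consensusTop(list(r1, r1), 3), c("a", "b", "c"))
  expect_setequal(consensusTop(list(r1, r2), 2), c("a", "b"))
  # disjoint tops give the empty set
  r3 <- mkTable(letters[1:6], 6:1)
  expect_length(consensusTop(list(r1, r3), 3), 0L)
  # n = k returns everything
  expect_setequal(consensusTop(list(r1, r3), 6), letters[1:6])
  expect_error(consensusTop(list(r1, r3), 0), "between 1")
  expect_error(consensusTop(list(r1), 3), "at least 2")
})

test_that("a planted common top gene survives the consensus of three rankings", {
  set.seed(43)
  genes <- sprintf("g%d", 1:10)
  mk <- function() {
    rest <- sample(genes[-1])
    mkTable(c("g1", rest), 1:10)
  }
  cons <- consensusTop(list(mk(), mk(), mk()), 4)
  expect_true("g1" %in% cons)
})
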