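# fixture builders used across the suite

makeCqMatrix <- function(values, groups = NULL, scale = "cq") {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (is.null(groups)) groups <- rep("a", ncol(values))
  CqMatrix(values, groups = groups, scale = scale)
}

# complete random Cq-scale matrix, two balanced groups
randomCqMatrix <- function(k, n, seed, groupLabels = c("a", "b")) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(k * n, 25, 2), k, n)
  groups <- rep(groupLabels, length.out = n)
  makeCqMatrix(vals, groups = groups)
}

# naive geNorm machinery, loops and sd() only: the brute-force oracle
naiveM <- function(X, genes = rownames(X)) {
  sapply(genes, function(j) {
    others <- setdiff(genes, j)
    mean(sapply(others, function(k) stats::sd(X[j, ] - X[k, ])))
  })
}

naiveEliminationOrder <- function(X) {
  keep <- rownames(X)
  out <- character()
  while (length(keep) > 2L) {
    M <- naiveM(X, keep)
    worst <- keep[max(which(M == max(M)))]
    out <- c(out, worst)
    keep <- setdiff(keep, worst)
  }
  M <- naiveM(X, keep)
  # most stable first: final pair by M ascending, then reverse eliminations
  c(keep[order(M, match(keep, rownames(X)))], rev(out))
}

# sign-balanced group shifts: the across-gene mean shift is exactly zero,
# so per-sample centring cannot convert a global shift into apparent
# per-gene (in)stability
balancedShifts <- function(k, maxShift = 2) {
  mags <- stats::runif(k %/% 2, 0, maxShift)
  shifts <- c(mags, -mags, if (k %% 2) 0)
  sample(shifts)
}

# exhaustive Mann-Whitney: all C(n1+n2, n1) group assignments
enumMannWhitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  uOf <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  uObs <- uOf(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2L, uOf)
  pLow <- mean(all_u <= uObs)
  pHigh <- mean(all_u >= uObs)
  list(U = min(uObs, n1 * length(y) - uObs),
       p = min(1, 2 * min(pLow, pHigh)))
}

writeLongFixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("sample,group,gene,replicate,cq", lines), path)
  path
}
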