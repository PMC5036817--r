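.MISSING_SENTINELS <- c("", "na", "nan", "undetermined")

.parseCqColumn <- function(cqText, sentinels) {
  cqText <- trimws(cqText)
  miss <- is.na(cqText) | tolower(cqText) %in% tolower(sentinels)
  val <- suppressWarnings(as.numeric(cqText))
  bad <- which(!miss & is.na(val))
  list(value = ifelse(miss, NA_real_, val), bad = bad)
}

#' Read a long-format Cq panel
#'
#' Reads a comma-separated file with columns \code{sample}, \code{group},
#' \code{gene}, \code{replicate}, \code{cq} into a replicate-level
#' \linkS4class{CqPanel}.  Missing reactions may be encoded as an empty
#' field or a sentinel ("NA", "NaN" or the instrument convention
#' "Undetermined", case-insensitive); rows absent from the file are filled
#' in as missing.  The replicate count is the maximum 1-based replicate
#' index observed.
#'
#' @param path path to the CSV file.
#' @param sentinels character values (besides an empty field) treated as
#'   a missing Cq, case-insensitively.
#' @return a \linkS4class{CqPanel}.
#' @seealso \code{\link{writeCqLong}}, \code{\link{readCqWide}}
#' @export
readCqLong <- function(path, sentinels = c("NA", "NaN", "Undetermined")) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample", "group", "gene", "replicate", "cq")
  absent <- setdiff(need, colnames(d))
  if (length(absent))
    stop("missing column(s): ", paste(absent, collapse = ", "))
  d$replicate <- as.integer(d$replicate)
  if (anyNA(d$replicate) || any(d$replicate < 1L))
    stop("replicate indices must be positive integers")

  key <- paste(d$gene, d$sample, d$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate row for (gene=%s, sample=%s, replicate=%d)",
                 d$gene[dup[1L]], d$sample[dup[1L]], d$replicate[dup[1L]]))

  grp <- unique(d[, c("sample", "group")])
  conflict <- grp$sample[duplicated(grp$sample)]
  if (length(conflict))
    stop("conflicting group labels for sample(s): ",
         paste(unique(conflict), collapse = ", "))

  parsed <- .parseCqColumn(d$cq, sentinels)
  if (length(parsed$bad))
    stop(sprintf("non-numeric cq value '%s' at line %d",
                 d$cq[parsed$bad[1L]], parsed$bad[1L] + 1L))

  # sorted identifiers make parsing independent of row order
  genes <- sort(unique(d$gene))
  samples <- sort(unique(d$sample))
  nrep <- max(d$replicate)
  arr <- array(NA_real_, dim = c(length(genes), length(samples), nrep),
               dimnames = list(genes, samples, NULL))
  arr[cbind(match(d$gene, genes), match(d$sample, samples), d$replicate)] <-
    parsed$value
  CqPanel(arr, groups = stats::setNames(grp$group, grp$sample))
}

#' Write a CqPanel in long format
#'
#' Inverse of \code{\link{readCqLong}}: one row per (sample, gene,
#' replicate) with missing reactions written as \code{NA}.
#'
#' @param panel a \linkS4class{CqPanel}.
#' @param path output CSV path.
#' @param digits significant digits for Cq values.
#' @return invisibly, \code{path}.
#' @export
writeCqLong <- function(panel, path, digits = 6L) {
  arr <- cqArray(panel)
  grp <- sampleGroups(panel)
  long <- expand.grid(replicate = seq_len(dim(arr)[3L]),
                      sample = colnames(panel), gene = rownames(panel),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$group <- unname(grp[long$sample])
  long$cq <- arr[cbind(match(long$gene, rownames(panel)),
                       match(long$sample, colnames(panel)), long$replicate)]
  long$cq <- ifelse(is.na(long$cq), "NA",
                    formatC(signif(long$cq, digits), digits = digits,
                            format = "fg", flag = "-"))
  utils::write.csv(long[, c("sample", "group", "gene", "replicate", "cq")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide-format Cq panel plus sample metadata
#'
#' The wide file's first column is \code{gene}; the remaining headers
#' encode sample and replicate as \code{"<sample>.<rep>"}.  Group labels
#' come from a separate two-column (sample, group) metadata CSV.
#'
#' @param path path to the wide CSV.
#' @param metaPath path to the metadata CSV.
#' @param sentinels as in \code{\link{readCqLong}}.
#' @return a \linkS4class{CqPanel}.
#' @export
readCqWide <- function(path, metaPath,
                       sentinels = c("NA", "NaN", "Undetermined")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(metaPath)) stop("file not found: ", metaPath)
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (colnames(d)[1L] != "gene") stop("first column must be 'gene'")
  if (anyDuplicated(d$gene))
    stop("duplicate gene row(s): ",
         paste(unique(d$gene[duplicated(d$gene)]), collapse = ", "))
  heads <- colnames(d)[-1L]
  m <- regmatches(heads, regexec("^(.*)\\.([0-9]+)$", heads))
  bad <- heads[vapply(m, length, 0L) != 3L]
  if (length(bad))
    stop("header(s) not parseable as <sample>.<rep>: ",
         paste(bad, collapse = ", "))
  sam <- vapply(m, `[`, "", 2L)
  rep <- as.integer(vapply(m, `[`, "", 3L))

  meta <- utils::read.csv(metaPath, colClasses = "character")
  if (!all(c("sample", "group") %in% colnames(meta)))
    stop("metadata needs columns sample, group")
  absent <- setdiff(unique(sam), meta$sample)
  if (length(absent))
    stop("sample(s) absent from metadata: ", paste(absent, collapse = ", "))

  genes <- sort(d$gene)
  samples <- sort(unique(sam))
  arr <- array(NA_real_, dim = c(length(genes), length(samples), max(rep)),
               dimnames = list(genes, samples, NULL))
  for (j in seq_along(heads)) {
    parsed <- .parseCqColumn(d[[j + 1L]], sentinels)
    if (length(parsed$bad))
      stop(sprintf("non-numeric cq value '%s' in column '%s'",
                   d[[j + 1L]][parsed$bad[1L]], heads[j]))
    arr[match(d$gene, genes), match(sam[j], samples), rep[j]] <- parsed$value
  }
  CqPanel(arr, groups = stats::setNames(meta$group, meta$sample))
}

.sig <- function(x, digits = 6L) {
  if (is.numeric(x)) signif(x, digits) else x
}

.writeTsv <- function(df, path, digits = 6L) {
  df[] <- lapply(df, .sig, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn writeReport TSV with columns gene, score, rank.
#' @export
setMethod("writeReport", "StabilityTable", function(obj, path) {
  .writeTsv(obj@table[, c("gene", "score", "rank")], path)
})

#' @describeIn writeReport TSV of the four component ranks, the geometric
#'   mean and the final position.
#' @export
setMethod("writeReport", "ComprehensiveRanking", function(obj, path) {
  .writeTsv(obj@table, path)
})

#' @describeIn writeReport JSON with the elimination order, per-round M
#'   trace, V curve and thresholds.
#' @export
setMethod("writeReport", "GeNormResult", function(obj, path) {
  out <- list(ranking = obj@ranking,
              m_trace = lapply(obj@mTrace, function(v) as.list(.sig(v))),
              final_m = as.list(.sig(obj@finalM)),
              v_curve = as.list(.sig(obj@vCurve)),
              m_threshold = obj@mThreshold, v_threshold = obj@vThreshold,
              recommended_n = obj@recommendedN)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
})

#' @describeIn writeReport JSON with stability values, shrunken intergroup
#'   differences, intragroup sds and the between-group variance.
#' @export
setMethod("writeReport", "NormFinderResult", function(obj, path) {
  out <- list(stability = as.list(.sig(obj@stability)),
              ranking = obj@ranking,
              intergroup = as.data.frame(.sig(obj@intergroup)),
              intragroup_sd = as.data.frame(.sig(obj@intragroupSd)),
              gamma2 = .sig(obj@gamma2))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
})

#' @describeIn writeReport TSV of the per-gene descriptive statistics.
#' @export
setMethod("writeReport", "BestKeeperResult", function(obj, path) {
  .writeTsv(obj@table, path)
})

#' @describeIn writeReport TSV with columns gene, score, rank.
#' @export
setMethod("writeReport", "DeltaCtResult", function(obj, path) {
  writeReport(stabilityTable(obj), path)
})

#' @describeIn writeReport JSON of the QC counts plus the excluded-genes
#'   table.
#' @export
setMethod("writeReport", "QcReport", function(obj, path) {
  out <- list(n_genes_input = obj@nGenesInput,
              n_genes_excluded = obj@nGenesExcluded,
              n_genes_retained = obj@nGenesRetained,
              n_reactions_total = obj@nReactionsTotal,
              n_reactions_missing = obj@nReactionsMissing,
              fraction_missing = .sig(obj@fractionMissing),
              excluded_genes = obj@excludedGenes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
})

#' @describeIn writeReport JSON with the reference-gene set, NF and NRQ
#'   values and the group-comparison table.
#' @export
setMethod("writeReport", "NrqReport", function(obj, path) {
  out <- list(rg_set = obj@rgSet,
              nf = as.list(.sig(obj@nf)),
              nrq = as.data.frame(.sig(obj@nrq)),
              comparison = obj@comparison)
  out$comparison[] <- lapply(out$comparison, .sig)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
})
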