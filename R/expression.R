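#' Housekeeping-normalized target-gene expression
#'
#' For each replicate column, divides the target gene's TPM by the
#' geometric mean of the TPM of exactly four housekeeping genes (by
#' default the denominator genes used for FAP: PSMB2, PSMB5, HPRT1,
#' GAPDH), then collapses replicate columns of the same sample with the
#' median (configurable to the mean). The ratio is invariant to rescaling
#' a replicate column, so samples quantified on different scales remain
#' comparable. A missing housekeeping gene is an error, never a
#' three-gene fallback: silently changing the denominator would corrupt
#' cross-sample comparability.
#'
#' @param exprs numeric matrix of TPM values, genes in rows (rownames are
#'   gene identifiers), replicate columns; or a path to a TSV with gene
#'   identifiers in the first column.
#' @param targetGene gene identifier to normalize (e.g. `"FAP"`).
#' @param housekeeping character vector of exactly 4 housekeeping gene
#'   identifiers; every value used must be > 0.
#' @param sampleMap optional data.frame with columns `column` and `sample`
#'   mapping replicate columns to samples; by default each column is its
#'   own sample.
#' @param aggregate how replicate values are collapsed per sample,
#'   `"median"` (default) or `"mean"`.
#' @return named numeric vector of normalized values, one per sample.
#' @examples
#' m <- rbind(FAP = c(8, 6), PSMB2 = c(2, 1), PSMB5 = c(2, 2),
#'            HPRT1 = c(2, 4), GAPDH = c(2, 8))
#' colnames(m) <- c("s1", "s2")
#' normalizeTarget(m, "FAP") # s1: 4, s2: 6/64^0.25
#' @export
normalizeTarget <- function(exprs, targetGene = "FAP",
                            housekeeping = c("PSMB2", "PSMB5", "HPRT1", "GAPDH"),
                            sampleMap = NULL,
                            aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.character(exprs) && length(exprs) == 1L)
    exprs <- readExpressionTsv(exprs)
  stopifnot(is.matrix(exprs), is.numeric(exprs))
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("normalizeTarget: expression matrix needs gene rownames and column names")
  if (anyDuplicated(rownames(exprs)))
    stop("normalizeTarget: duplicated gene identifiers")
  if (anyDuplicated(colnames(exprs)))
    stop("normalizeTarget: duplicated column identifiers")
  if (any(exprs < 0, na.rm = TRUE))
    stop("normalizeTarget: negative TPM values")
  if (length(housekeeping) != 4L)
    stop("normalizeTarget: exactly 4 housekeeping genes are required, got ",
         length(housekeeping))
  missingGenes <- setdiff(c(targetGene, housekeeping), rownames(exprs))
  if (length(missingGenes))
    stop("normalizeTarget: gene(s) absent from the table: ",
         paste(missingGenes, collapse = ", "))
  hk <- exprs[housekeeping, , drop = FALSE]
  badIdx <- which(hk <= 0 | !is.finite(hk), arr.ind = TRUE)
  if (nrow(badIdx))
    stop("normalizeTarget: non-positive housekeeping TPM for gene ",
         housekeeping[badIdx[1L, 1L]], " in column ",
         colnames(exprs)[badIdx[1L, 2L]])
  perRep <- exprs[targetGene, ] / apply(hk, 2L, geometricMean)

  if (is.null(sampleMap))
    sampleMap <- data.frame(column = colnames(exprs),
                            sample = colnames(exprs),
                            stringsAsFactors = FALSE)
  stopifnot(all(c("column", "sample") %in% names(sampleMap)))
  unknown <- setdiff(sampleMap$column, colnames(exprs))
  if (length(unknown))
    stop("normalizeTarget: sampleMap names unknown column(s): ",
         paste(unknown, collapse = ", "))
  agg <- if (aggregate == "median") median else mean
  vals <- tapply(perRep[sampleMap$column], sampleMap$sample, agg)
  out <- as.numeric(vals)
  names(out) <- names(vals)
  out[base::order(names(out))]
}

readExpressionTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Classify samples as FAP-positive / negative / indeterminate
#'
#' Anchored grouping of samples by normalized target expression: samples
#' strictly below the negative anchor's value (a cell line known to be
#' FAP-negative, A549 in the original design) are `negative`, samples at
#' or above the positive anchor's value (the lowest clearly FAP-positive
#' sample, transverse colon in the original design) are `positive`, and
#' samples strictly between the anchors are `indeterminate`. Each anchor
#' itself belongs to its own group. Classification depends only on the
#' ordering of the values, so any strictly monotone transform of the
#' normalized scale leaves the labels unchanged.
#'
#' @param normalized named numeric vector from [normalizeTarget()].
#' @param negativeAnchor,positiveAnchor sample names present in
#'   `normalized`; the negative anchor's value must not exceed the
#'   positive anchor's.
#' @return a `data.frame` (one row per sample, sorted by decreasing
#'   normalized value, ties broken by sample id) with columns `sample`,
#'   `normalized_expr`, `status`, `source`.
#' @export
classifySamples <- function(normalized, negativeAnchor, positiveAnchor) {
  stopifnot(is.numeric(normalized), !is.null(names(normalized)))
  if (!negativeAnchor %in% names(normalized))
    stop("classifySamples: negative anchor '", negativeAnchor,
         "' not among samples")
  if (!positiveAnchor %in% names(normalized))
    stop("classifySamples: positive anchor '", positiveAnchor,
         "' not among samples")
  if (any(!is.finite(normalized)))
    stop("classifySamples: non-finite normalized values")
  lo <- normalized[[negativeAnchor]]
  hi <- normalized[[positiveAnchor]]
  if (lo > hi)
    stop("classifySamples: anchors inverted (negative anchor ", lo,
         " > positive anchor ", hi, ")")
  status <- ifelse(normalized < lo, "negative",
                   ifelse(normalized >= hi, "positive", "indeterminate"))
  status[names(normalized) == negativeAnchor] <- "negative"
  status[names(normalized) == positiveAnchor] <- "positive"
  out <- data.frame(
    sample = names(normalized),
    normalized_expr = as.numeric(normalized),
    status = unname(status),
    source = "expression",
    stringsAsFactors = FALSE)
  out <- out[base::order(-out$normalized_expr, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Append externally justified status labels
#'
#' Adds samples whose FAP status comes from outside the expression table
#' (prior measurements, literature), with provenance recorded in `source`.
#' Expression-derived labels are never overwritten: an override for an
#' already classified sample is an error.
#'
#' @param statuses a status `data.frame` from [classifySamples()].
#' @param overrides data.frame with columns `sample`, `status` (one of
#'   positive/negative/indeterminate) and `source`.
#' @return the combined status table; externally added samples carry
#'   `normalized_expr = NA`.
#' @export
appendExternalLabels <- function(statuses, overrides) {
  stopifnot(is.data.frame(statuses))
  if (is.null(overrides) || !nrow(overrides)) return(statuses)
  stopifnot(all(c("sample", "status", "source") %in% names(overrides)))
  badStatus <- setdiff(overrides$status,
                       c("positive", "negative", "indeterminate"))
  if (length(badStatus))
    stop("appendExternalLabels: unknown status value(s): ",
         paste(badStatus, collapse = ", "))
  clash <- intersect(overrides$sample, statuses$sample)
  if (length(clash))
    stop("appendExternalLabels: sample(s) already classified from expression: ",
         paste(clash, collapse = ", "))
  extra <- data.frame(
    sample = overrides$sample,
    normalized_expr = NA_real_,
    status = overrides$status,
    source = overrides$source,
    stringsAsFactors = FALSE)
  out <- rbind(statuses, extra)
  rownames(out) <- NULL
  out
}
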