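#' Map TF binding events onto named elements
#'
#' Assigns every transcription-factor ChIP-seq binding event to each
#' studied element (promoter regions R1-R4, enhancers E1/E2, ...) that its
#' cluster overlaps by at least one base; an event spanning several
#' elements is listed under all of them. No score threshold is applied: a
#' factor "binds" an element if at least one of its clusters overlaps it
#' in at least one cell type.
#'
#' @param elements a named `GRanges` (unique names = element ids).
#' @param events either a `GRanges` with metadata columns `tf` and `cell`,
#'   or a data.frame with columns `tf`, `cell`, `chrom`, `start`, `end`
#'   (0-based half-open, BED convention).
#' @return a `data.frame` with one row per (element, event) overlap:
#'   columns `element`, `tf`, `cell`, `chrom`, `start`, `end` (BED
#'   convention), sorted deterministically.
#' @export
mapTfEvents <- function(elements, events) {
  stopifnot(is(elements, "GRanges"))
  ids <- names(elements)
  if (is.null(ids) || anyDuplicated(ids))
    stop("mapTfEvents: elements must carry unique names")
  if (is.data.frame(events)) {
    stopifnot(all(c("tf", "cell", "chrom", "start", "end") %in% names(events)))
    gr <- GRanges(events$chrom, IRanges(events$start + 1L, events$end))
    S4Vectors::mcols(gr)$tf <- as.character(events$tf)
    S4Vectors::mcols(gr)$cell <- as.character(events$cell)
    events <- gr
  }
  stopifnot(is(events, "GRanges"))
  mc <- S4Vectors::mcols(events)
  if (is.null(mc$tf) || is.null(mc$cell))
    stop("mapTfEvents: events need 'tf' and 'cell' metadata columns")
  if (any(!nzchar(mc$tf)) || any(!nzchar(mc$cell)))
    stop("mapTfEvents: empty tf or cell labels")
  hits <- findOverlaps(elements, events, ignore.strand = TRUE)
  ev <- events[subjectHits(hits)]
  out <- data.frame(
    element = ids[queryHits(hits)],
    tf = S4Vectors::mcols(ev)$tf,
    cell = S4Vectors::mcols(ev)$cell,
    chrom = as.character(seqnames(ev)),
    start = start(ev) - 1L,
    end = end(ev),
    stringsAsFactors = FALSE)
  out <- out[base::order(out$element, out$tf, out$cell, out$chrom,
                         out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition TFs by promoter-only / both / enhancer-only binding
#'
#' Splits the factors with at least one mapped binding event into three
#' disjoint sets according to which element groups they touch: only
#' promoter elements, only enhancers, or both. The three sets always sum
#' to the total number of bound factors.
#'
#' @param mapped output of [mapTfEvents()].
#' @param promoterIds,enhancerIds disjoint element-id sets that together
#'   cover every element id occurring in `mapped`.
#' @return a list with sorted character vectors `promoter_only`, `both`,
#'   `enhancer_only`, and `per_element` (element id -> sorted TF names).
#' @export
partitionTfs <- function(mapped, promoterIds, enhancerIds) {
  stopifnot(is.data.frame(mapped))
  if (length(intersect(promoterIds, enhancerIds)))
    stop("partitionTfs: promoter and enhancer id sets overlap")
  stray <- setdiff(unique(mapped$element), c(promoterIds, enhancerIds))
  if (length(stray))
    stop("partitionTfs: element id(s) in neither group: ",
         paste(stray, collapse = ", "))
  perElement <- lapply(split(mapped$tf, mapped$element),
                       function(x) base::sort(unique(x)))
  tfs <- base::sort(unique(mapped$tf))
  inProm <- vapply(tfs, function(tf)
    any(mapped$element[mapped$tf == tf] %in% promoterIds), TRUE)
  inEnh <- vapply(tfs, function(tf)
    any(mapped$element[mapped$tf == tf] %in% enhancerIds), TRUE)
  list(
    promoter_only = tfs[inProm & !inEnh],
    both = tfs[inProm & inEnh],
    enhancer_only = tfs[!inProm & inEnh],
    per_element = perElement)
}

#' Venn counts of a TF partition
#'
#' @param partition output of [partitionTfs()].
#' @return named integer vector `(promoter_only, both, enhancer_only)`;
#'   the sum is the total number of bound TFs.
#' @export
tfVennCounts <- function(partition) {
  c(promoter_only = length(partition$promoter_only),
    both = length(partition$both),
    enhancer_only = length(partition$enhancer_only))
}

#' Stratify TF binding events by cell FAP status
#'
#' Counts mapped binding events per (TF, element group, cell status).
#' Cells without a status entry are kept visible in an `unclassified`
#' stratum rather than dropped, so no event disappears from the totals.
#'
#' @param mapped output of [mapTfEvents()].
#' @param statuses status `data.frame` from [classifySamples()] /
#'   [appendExternalLabels()].
#' @param promoterIds,enhancerIds element-id groups as in
#'   [partitionTfs()].
#' @return a `data.frame` with columns `tf`, `element_group`
#'   (promoter/enhancer), `status` (positive/negative/indeterminate/
#'   unclassified) and `n` (event count); `sum(n)` equals `nrow(mapped)`.
#' @export
stratifyByStatus <- function(mapped, statuses, promoterIds, enhancerIds) {
  stopifnot(is.data.frame(mapped))
  if (!nrow(mapped)) {
    return(data.frame(tf = character(), element_group = character(),
                      status = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  stray <- setdiff(unique(mapped$element), c(promoterIds, enhancerIds))
  if (length(stray))
    stop("stratifyByStatus: element id(s) in neither group: ",
         paste(stray, collapse = ", "))
  lookup <- setNames(statuses$status, statuses$sample)
  status <- unname(lookup[mapped$cell])
  status[is.na(status)] <- "unclassified"
  group <- ifelse(mapped$element %in% promoterIds, "promoter", "enhancer")
  tab <- stats::aggregate(
    list(n = rep(1L, nrow(mapped))),
    by = list(tf = mapped$tf, element_group = group, status = status),
    FUN = sum)
  tab <- tab[base::order(tab$tf, tab$element_group, tab$status), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
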