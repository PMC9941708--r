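#' Call consensus candidate elements from FAP-positive peak sets
#'
#' Operationalizes "regions of greatest H3K27ac overlap": the coverage
#' stack over the positive-line peak sets is thresholded at
#' `ceiling(minSupportFraction * n_positive)` supporting lines, gaps up to
#' `mergeGap` bp between above-threshold pieces are closed, and regions
#' narrower than `minWidth` bp are discarded. Each candidate's `support` is
#' the maximum stack depth inside it. The default threshold of 0.75
#' tolerates peak dropout in a minority of lines (enhancers need not be
#' detected in every FAP-positive line).
#'
#' @param positiveSets list of >= 2 [PeakSet-class] / `GRanges`, one per
#'   FAP-positive cell line.
#' @param config a [ScreenConfig-class].
#' @return a `GRanges` of candidates sorted by (`support` desc, width desc,
#'   coordinate), with metadata columns `support`, `positive_total`, and
#'   placeholder columns `negative_hits`, `dnase_overlap`,
#'   `tf_cluster_count`, `elem_class` (`NA` until the later stages fill
#'   them).
#' @seealso [filterByNegatives()], [annotateCandidates()],
#'   [classifyProximity()], [runScreen()]
#' @export
callConsensus <- function(positiveSets, config = ScreenConfig()) {
  if (!is.list(positiveSets) || length(positiveSets) < 2L)
    stop("callConsensus: consensus undefined for fewer than 2 positive peak sets")
  k <- length(positiveSets)
  minDepth <- ceiling(config@minSupportFraction * k)
  stack <- coverageStack(positiveSets)
  core <- stack[S4Vectors::mcols(stack)$depth >= minDepth]
  regions <- reduce(core, min.gapwidth = config@mergeGap + 1L,
                    ignore.strand = TRUE)
  regions <- regions[width(regions) >= config@minWidth]
  support <- integer(length(regions))
  if (length(regions)) {
    hits <- findOverlaps(regions, stack)
    depth <- S4Vectors::mcols(stack)$depth[subjectHits(hits)]
    support <- as.integer(tapply(depth, factor(queryHits(hits),
                                               levels = seq_along(regions)),
                                 max))
  }
  S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
    support = support,
    positive_total = rep(k, length(regions)),
    negative_hits = rep(NA_integer_, length(regions)),
    dnase_overlap = rep(NA, length(regions)),
    tf_cluster_count = rep(NA_integer_, length(regions)),
    elem_class = rep(NA_character_, length(regions))
  )
  orderCandidates(regions)
}

# support desc, width desc, then leftmost coordinate: deterministic ranking
orderCandidates <- function(cand) {
  o <- base::order(-S4Vectors::mcols(cand)$support, -width(cand),
                   as.character(seqnames(cand)), start(cand), end(cand))
  cand[o]
}

#' Drop candidates seen in FAP-negative lines
#'
#' Computes `negative_hits` (number of negative peak sets overlapping each
#' candidate by >= 1 bp, regardless of overlap length) and removes
#' candidates exceeding `maxNegativeHits`. With the default of 0 this is
#' the strict reading of "absent in FAP-negative cell lines".
#'
#' @param candidates output of [callConsensus()].
#' @param negativeSets list of [PeakSet-class] / `GRanges`, one per
#'   FAP-negative line.
#' @param config a [ScreenConfig-class].
#' @return the surviving candidates, otherwise unchanged, with
#'   `negative_hits` filled.
#' @export
filterByNegatives <- function(candidates, negativeSets,
                              config = ScreenConfig()) {
  stopifnot(is(candidates, "GRanges"))
  grs <- lapply(negativeSets, function(x)
    if (is(x, "PeakSet")) peakRanges(x) else x)
  hits <- rep(0L, length(candidates))
  for (gr in grs)
    hits <- hits + as.integer(overlapsAny(candidates, gr, ignore.strand = TRUE))
  S4Vectors::mcols(candidates)$negative_hits <- hits
  candidates[hits <= config@maxNegativeHits]
}

#' Annotate candidates with DNase and TF-cluster overlap
#'
#' Fills `dnase_overlap` (any overlap with the DNase hypersensitivity
#' track) and `tf_cluster_count` (number of distinct transcription-factor
#' names among overlapping clusters; the TF name is BED column 4 of the
#' cluster track). Candidate coordinates are untouched.
#'
#' @param candidates a `GRanges` of candidates.
#' @param dnase DNase clusters as [PeakSet-class] / `GRanges`.
#' @param tfClusters TF clusters as [PeakSet-class] / `GRanges` with a
#'   `name` metadata column holding the factor name (read with
#'   `readBed(..., mergeOverlapping = FALSE)` to keep names).
#' @return `candidates` with the two annotation columns filled.
#' @export
annotateCandidates <- function(candidates, dnase, tfClusters) {
  stopifnot(is(candidates, "GRanges"))
  if (is(dnase, "PeakSet")) dnase <- peakRanges(dnase)
  if (is(tfClusters, "PeakSet")) tfClusters <- peakRanges(tfClusters)
  S4Vectors::mcols(candidates)$dnase_overlap <-
    overlapsAny(candidates, dnase, ignore.strand = TRUE)
  tfName <- S4Vectors::mcols(tfClusters)$name
  if (is.null(tfName))
    stop("annotateCandidates: TF cluster track has no 'name' column")
  hits <- findOverlaps(candidates, tfClusters, ignore.strand = TRUE)
  nTf <- integer(length(candidates))
  if (length(hits)) {
    byCand <- split(tfName[subjectHits(hits)],
                    factor(queryHits(hits), levels = seq_along(candidates)))
    nTf <- vapply(byCand, function(x) length(unique(x)), 1L)
  }
  S4Vectors::mcols(candidates)$tf_cluster_count <- as.integer(nTf)
  candidates
}

#' Classify candidates as promoter-proximal or distal
#'
#' A candidate is `proximal` when its distance to the configured
#' transcription start site is at most `proximalWindow` bp (default 3 kb,
#' the conventional promoter territory upstream of the start codon), else
#' `distal`. Regions containing the TSS have distance 0 and are always
#' proximal.
#'
#' @param candidates a `GRanges` of candidates.
#' @param config a [ScreenConfig-class] with `tss` set.
#' @return `candidates` with `elem_class` filled.
#' @export
classifyProximity <- function(candidates, config) {
  stopifnot(is(candidates, "GRanges"))
  if (is.null(config@tss))
    stop("classifyProximity: config@tss is not set")
  d <- distance(candidates, rep(config@tss, length(candidates)),
                ignore.strand = TRUE)
  S4Vectors::mcols(candidates)$elem_class <-
    ifelse(d <= config@proximalWindow, "proximal", "distal")
  candidates
}

#' Run the whole enhancer screen from a file manifest
#'
#' Composes [readBed()], [callConsensus()], [filterByNegatives()],
#' [annotateCandidates()] and [classifyProximity()] and writes the
#' candidate BED (score column = support) plus a JSON report with
#' per-stage counts. Deterministic given the same inputs.
#'
#' @param manifest either a named list or the path to a JSON file with
#'   entries `positive` (character vector of BED paths, >= 2), `negative`
#'   (BED paths, may be empty), and optionally `dnase` and `tf_clusters`
#'   (single BED paths).
#' @param config a [ScreenConfig-class] with `tss` set if proximity
#'   classification is wanted.
#' @param outDir if non-`NULL`, directory where `candidates.bed` and
#'   `screen_report.json` are written.
#' @return a list with `candidates` (`GRanges`), `counts` (per-stage
#'   integer counts) and `files` (paths written, or `NULL`).
#' @export
runScreen <- function(manifest, config = ScreenConfig(), outDir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest))
      stop("runScreen: manifest file not found: ", manifest)
    manifest <- read_json(manifest, simplifyVector = TRUE)
  }
  stopifnot(is.list(manifest))
  needFiles <- function(entry) {
    paths <- manifest[[entry]]
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("runScreen: manifest entry '", entry, "' names missing file(s): ",
           paste(missing, collapse = ", "))
    paths
  }
  posPaths <- needFiles("positive")
  posSets <- lapply(posPaths, readBed, mark = "H3K27ac")
  negSets <- list()
  if (!is.null(manifest$negative) && length(manifest$negative))
    negSets <- lapply(needFiles("negative"), readBed, mark = "H3K27ac")

  cand <- callConsensus(posSets, config)
  counts <- c(positive_sets = length(posSets),
              negative_sets = length(negSets),
              consensus = length(cand))
  cand <- filterByNegatives(cand, negSets, config)
  counts["after_negative_filter"] <- length(cand)
  if (!is.null(manifest$dnase) || !is.null(manifest$tf_clusters)) {
    dnase <- if (!is.null(manifest$dnase))
      readBed(needFiles("dnase"), mark = "DNase") else GRanges()
    tf <- if (!is.null(manifest$tf_clusters)) {
      ps <- readBed(needFiles("tf_clusters"), mergeOverlapping = FALSE,
                    mark = "TF")
      peakRanges(ps)
    } else {
      g <- GRanges(); S4Vectors::mcols(g)$name <- character(); g
    }
    cand <- annotateCandidates(cand, dnase, tf)
  }
  if (!is.null(config@tss))
    cand <- classifyProximity(cand, config)
  counts["final"] <- length(cand)

  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    bedPath <- file.path(outDir, "candidates.bed")
    out <- cand
    ids <- sprintf("cand_%03d", seq_along(out))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      name = ids, score = S4Vectors::mcols(cand)$support)
    writeBed(out, bedPath)
    jsonPath <- file.path(outDir, "screen_report.json")
    report <- list(
      config = list(
        min_support_fraction = config@minSupportFraction,
        max_negative_hits = config@maxNegativeHits,
        proximal_window = config@proximalWindow,
        min_width = config@minWidth,
        merge_gap = config@mergeGap),
      counts = as.list(counts),
      candidates = candidatesAsData(cand, ids))
    write_json(report, jsonPath, auto_unbox = TRUE, pretty = TRUE,
               digits = NA)
    files <- c(bed = bedPath, json = jsonPath)
  }
  list(candidates = cand, counts = counts, files = files)
}

candidatesAsData <- function(cand, ids = sprintf("cand_%03d", seq_along(cand))) {
  df <- data.frame(
    id = ids,
    chrom = as.character(seqnames(cand)),
    start = start(cand) - 1L, # BED convention in the report
    end = end(cand),
    stringsAsFactors = FALSE)
  cbind(df, as.data.frame(S4Vectors::mcols(cand)))
}
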