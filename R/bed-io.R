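#' Read a BED file into a PeakSet
#'
#' Strict BED3/BED6 reader. Coordinates on disk are 0-based half-open (BED
#' convention) and are converted to the 1-based closed convention of
#' [GenomicRanges::GRanges] on the way in; all interval arithmetic in the
#' package happens on `GRanges`, and [writeBed()] converts back. Malformed
#' lines are an error naming the line number — they are never silently
#' dropped. The TF-cluster dialect (factor name in column 4) is read the
#' same way, with the name landing in the `name` metadata column.
#'
#' @param path path to a BED file. Lines starting with `#`, `track` or
#'   `browser` are ignored.
#' @param mergeOverlapping union overlapping/adjacent intervals (default
#'   `TRUE`). Use `FALSE` for tracks whose rows carry identities, e.g.
#'   named TF clusters. The pre-merge interval count is retained either
#'   way (see [preMergeCount()]).
#' @param sampleId,mark labels stored on the returned [PeakSet-class];
#'   `sampleId` defaults to the file name without extension.
#' @return a [PeakSet-class].
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr2\t100\t200\tpk1\t5", "chr2\t150\t250\tpk2\t7"), bed)
#' ps <- readBed(bed, sampleId = "HUVEC", mark = "H3K27ac")
#' length(ps)          # 1 after merging
#' preMergeCount(ps)   # 2
#' @export
readBed <- function(path, mergeOverlapping = TRUE,
                    sampleId = sub("\\.[^.]*$", "", basename(path)),
                    mark = NA_character_) {
  if (!file.exists(path)) stop("readBed: file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    ps <- PeakSet(GRanges(), sampleId = sampleId, mark = mark,
                  merge = FALSE, preMergeCount = 0L)
    return(ps)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("readBed: line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  startTxt <- vapply(fields, `[[`, "", 2L)
  endTxt <- vapply(fields, `[[`, "", 3L)
  start0 <- suppressWarnings(as.integer(startTxt))
  end0 <- suppressWarnings(as.integer(endTxt))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("readBed: line ", idx[bad[1L]], ": start/end not integer ('",
         startTxt[bad[1L]], "', '", endTxt[bad[1L]], "')")
  bad <- which(start0 < 0L)
  if (length(bad))
    stop("readBed: line ", idx[bad[1L]], ": negative start ", start0[bad[1L]])
  bad <- which(end0 <= start0)
  if (length(bad))
    stop("readBed: line ", idx[bad[1L]], ": end (", end0[bad[1L]],
         ") must be > start (", start0[bad[1L]], ")")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (any(nf >= 4L)) {
    nm <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
    S4Vectors::mcols(gr)$name <- nm
  }
  if (any(nf >= 5L)) {
    sc <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")
    sc[sc == "."] <- NA_character_
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(sc))
  }
  PeakSet(gr, sampleId = sampleId, mark = mark,
          merge = mergeOverlapping, preMergeCount = length(gr))
}

#' Write intervals as BED
#'
#' Writes a `GRanges` or [PeakSet-class] as BED, converting back to 0-based
#' half-open coordinates. A `name` metadata column becomes BED column 4 and
#' `score` column 5 (missing values written as `.`).
#'
#' @param x a `GRanges` or `PeakSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  if (is(x, "PeakSet")) x <- peakRanges(x)
  stopifnot(is(x, "GRanges"))
  mc <- S4Vectors::mcols(x)
  cols <- list(
    chrom = as.character(seqnames(x)),
    start = format(start(x) - 1L, scientific = FALSE, trim = TRUE),
    end = format(end(x), scientific = FALSE, trim = TRUE)
  )
  hasScore <- "score" %in% colnames(mc)
  hasName <- "name" %in% colnames(mc)
  if (hasName || hasScore) {
    nm <- if (hasName) as.character(mc$name) else rep(".", length(x))
    nm[is.na(nm)] <- "."
    cols$name <- nm
  }
  if (hasScore) {
    sc <- as.character(mc$score)
    sc[is.na(sc)] <- "."
    cols$score <- sc
  }
  writeLines(do.call(paste, c(unname(cols), sep = "\t")), path)
  invisible(path)
}
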