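# Per-base brute-force oracle on a small toy chromosome: interval sets are
# expanded to base-membership masks, so merge / intersect / coverage can be
# checked base-for-base against naive set arithmetic.

library(GenomicRanges)

grToMask <- function(gr, L) {
  m <- logical(L)
  for (i in seq_along(gr))
    m[start(gr)[i]:end(gr)[i]] <- TRUE
  m
}

maskToGr <- function(m, chrom = "toy") {
  r <- rle(m)
  if (!any(r$values)) return(GRanges())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  GRanges(chrom, IRanges(starts[r$values], ends[r$values]))
}

# coordinate triple comparison, ignoring seqinfo bookkeeping
rangesDf <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr))
}

depthVector <- function(grs, L) {
  Reduce(`+`, lapply(grs, function(g)
    as.integer(grToMask(mergeIntervals(g), L))))
}

randomToyGr <- function(nMax = 10L, L = 10000L, chrom = "toy") {
  n <- sample.int(nMax, 1L)
  s <- sample.int(L - 300L, n, replace = TRUE)
  w <- sample.int(250L, n, replace = TRUE)
  GRanges(chrom, IRanges(s, pmin(s + w, L)))
}

writeBedLines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
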