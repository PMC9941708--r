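toyTss <- GRanges("chr2", IRanges(50001, 50001))
toyCfg <- ScreenConfig(tss = toyTss)

test_that("callConsensus recovers a fully supported planted element", {
  sim <- simulatePeakLandscape(defaultPlanted(), decoyRate = 0, seed = 11)
  cand <- callConsensus(sim$positive, toyCfg)
  e1 <- GRanges("chr2", IRanges(20001, 20800))
  hit <- cand[overlapsAny(cand, e1)]
  expect_equal(length(hit), 1L)
  expect_equal(S4Vectors::mcols(hit)$support, 9L)
  expect_equal(S4Vectors::mcols(hit)$positive_total, 9L)
})

test_that("support below the consensus threshold is not called", {
  planted <- defaultPlanted()
  planted <- planted[planted$name == "E1", ]
  planted$support <- 3L
  sim <- simulatePeakLandscape(planted, decoyRate = 0, seed = 3)
  cand <- callConsensus(sim$positive, toyCfg) # needs ceil(0.75*9) = 7
  expect_equal(length(cand), 0L)
})

test_that("threshold 1.0 on identical sets returns the common set", {
  gr <- GRanges("chr2", IRanges(c(1001, 5001), c(2000, 6000)))
  sets <- rep(list(PeakSet(gr, sampleId = "x", mark = "H3K27ac")), 4L)
  cfg <- ScreenConfig(minSupportFraction = 1, mergeGap = 0, minWidth = 0)
  cand <- callConsensus(sets, cfg)
  expect_equal(rangesDf(sort(cand)), rangesDf(gr))
  expect_equal(S4Vectors::mcols(cand)$support, c(4L, 4L))
})

test_that("consensus needs at least two positive sets", {
  gr <- GRanges("chr2", IRanges(1, 100))
  expect_error(callConsensus(list(gr)), "fewer than 2")
})

test_that("filterByNegatives drops candidates seen in negative lines", {
  cand <- GRanges("chr2", IRanges(c(1001, 9001), c(2000, 9500)))
  S4Vectors::mcols(cand)$support <- c(9L, 9L)
  S4Vectors::mcols(cand)$negative_hits <- NA_integer_
  negs <- list(GRanges("chr2", IRanges(1500, 1600)),
               GRanges("chr2", IRanges(1001, 1100)),
               GRanges("chr2", IRanges(30001, 30100)))
  kept <- filterByNegatives(cand, negs, ScreenConfig(maxNegativeHits = 0))
  expect_equal(start(kept), 9001L)
  expect_equal(S4Vectors::mcols(kept)$negative_hits, 0L)
  # max_negative_hits = number of negative lines: identity
  all3 <- filterByNegatives(cand, negs, ScreenConfig(maxNegativeHits = 3))
  expect_equal(length(all3), 2L)
  expect_equal(S4Vectors::mcols(all3)$negative_hits, c(2L, 0L))
})

test_that("planted clean enhancer survives, planted shared decoy is removed", {
  sim <- simulatePeakLandscape(defaultPlanted(), seed = 21)
  cand <- callConsensus(sim$positive, toyCfg)
  kept <- filterByNegatives(cand, sim$negative, toyCfg)
  e1 <- GRanges("chr2", IRanges(20001, 20800))
  e2 <- GRanges("chr2", IRanges(62001, 63000))
  shared <- GRanges("chr2", IRanges(80001, 80900))
  expect_true(overlapsAny(e1, kept))
  expect_true(overlapsAny(e2, kept))
  expect_true(overlapsAny(shared, cand))  # called before the filter...
  expect_false(overlapsAny(shared, kept)) # ...removed by it
})

test_that("annotation counts distinct TFs and flags DNase overlap", {
  cand <- GRanges("chr2", IRanges(c(1001, 8001), c(2000, 9000)))
  dnase <- GRanges("chr2", IRanges(1500, 1600))
  tf <- GRanges("chr2", IRanges(c(1001, 1101, 1201, 1301, 1401, 1501),
                                width = 50))
  S4Vectors::mcols(tf)$name <- c("STAT3", "FOS", "JUND", "CEBPB", "EP300",
                                 "STAT3") # STAT3 twice -> 5 distinct
  ann <- annotateCandidates(cand, dnase, tf)
  expect_equal(S4Vectors::mcols(ann)$dnase_overlap, c(TRUE, FALSE))
  expect_equal(S4Vectors::mcols(ann)$tf_cluster_count, c(5L, 0L))
})

test_that("annotation matches a brute-force overlap count on random input", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      cand <- randomToyGr(5, L = 10000, chrom = "chr2")
      tf <- randomToyGr(20, L = 10000, chrom = "chr2")
      S4Vectors::mcols(tf)$name <- sample(LETTERS[1:6], length(tf),
                                          replace = TRUE)
      dnase <- randomToyGr(5, L = 10000, chrom = "chr2")
      ann <- annotateCandidates(cand, dnase, tf)
      for (i in seq_along(cand)) {
        ov <- vapply(seq_along(tf), function(j)
          start(tf)[j] <= end(cand)[i] && end(tf)[j] >= start(cand)[i], TRUE)
        expect_equal(S4Vectors::mcols(ann)$tf_cluster_count[i],
                     length(unique(S4Vectors::mcols(tf)$name[ov])))
        expect_equal(S4Vectors::mcols(ann)$dnase_overlap[i],
                     any(vapply(seq_along(dnase), function(j)
                       start(dnase)[j] <= end(cand)[i] &&
                         end(dnase)[j] >= start(cand)[i], TRUE)))
      }
    }
  })
})

test_that("proximity classification uses distance to the TSS", {
  cfg <- ScreenConfig(tss = GRanges("chr2", IRanges(50001, 50001)),
                      proximalWindow = 3000)
  cand <- GRanges("chr2", IRanges(c(48800, 60001, 49901), # 1 kb, 10 kb, spanning
                                  c(49000, 60500, 50200)))
  S4Vectors::mcols(cand)$elem_class <- NA_character_
  cls <- classifyProximity(cand, cfg)
  expect_equal(S4Vectors::mcols(cls)$elem_class,
               c("proximal", "distal", "proximal"))
})

test_that("screen thresholds are monotone", {
  sim <- simulatePeakLandscape(defaultPlanted(), seed = 5)
  fracs <- c(0.5, 0.75, 0.9, 1)
  called <- lapply(fracs, function(f)
    callConsensus(sim$positive, ScreenConfig(minSupportFraction = f)))
  for (i in seq_len(length(fracs) - 1L)) {
    # every region called at the stricter threshold is covered at the looser
    expect_true(all(overlapsAny(called[[i + 1L]], called[[i]])))
    expect_lte(length(called[[i + 1L]]), length(called[[i]]))
  }
  cand <- called[[2L]]
  survivors <- vapply(0:3, function(m)
    length(filterByNegatives(cand, sim$negative,
                             ScreenConfig(maxNegativeHits = m))), 1L)
  expect_true(all(diff(survivors) >= 0))
})

test_that("runScreen composes the stages and round-trips its BED output", {
  dir <- tempfile()
  sim <- simulatePeakLandscape(defaultPlanted(), seed = 13, dir = dir)
  manifest <- list(
    positive = grep("pos_", sim$files, value = TRUE),
    negative = grep("neg_", sim$files, value = TRUE))
  out <- tempfile()
  res <- runScreen(manifest, toyCfg, outDir = out)
  expect_true(length(res$candidates) >= 2L)
  expect_true(all(c("positive_sets", "consensus", "after_negative_filter",
                    "final") %in% names(res$counts)))
  expect_true(all(S4Vectors::mcols(res$candidates)$negative_hits == 0L))
  # BED output re-read reproduces candidate coordinates exactly
  back <- peakRanges(readBed(res$files[["bed"]], mergeOverlapping = FALSE))
  expect_equal(start(back), start(sort(res$candidates)))
  expect_equal(end(back), end(sort(res$candidates)))
  expect_true(file.exists(res$files[["json"]]))
  bad <- manifest
  bad$positive <- c(bad$positive, file.path(dir, "nonexistent.bed"))
  expect_error(runScreen(bad, toyCfg), "positive.*missing file")
})
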