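tfElements <- function() {
  gr <- GRanges("chr2", IRanges(c(1000, 2000, 3000, 4000, 20000, 62000),
                                width = 500))
  names(gr) <- c("R1", "R2", "R3", "R4", "E1", "E2")
  gr
}
promIds <- c("R1", "R2", "R3", "R4")
enhIds <- c("E1", "E2")

eventsFor <- function(tf, elements, cell = "SJSA-1") {
  el <- tfElements()[elements]
  data.frame(tf = tf, cell = cell,
             chrom = "chr2", start = start(el) + 9L, end = start(el) + 59L,
             stringsAsFactors = FALSE)
}

test_that("events map to every element they overlap", {
  el <- tfElements()
  ev <- data.frame(tf = c("SPAN", "OUT"), cell = "c1", chrom = "chr2",
                   start = c(1400, 9000), end = c(2100, 9100))
  mapped <- mapTfEvents(el, ev)
  # the spanning event hits R1 and R2; the distant one is unassigned
  expect_equal(base::sort(mapped$element), c("R1", "R2"))
  expect_equal(unique(mapped$tf), "SPAN")
})

test_that("event mapping matches brute-force pairwise overlap", {
  withr::with_seed(31, {
    el <- randomToyGr(6, L = 10000, chrom = "chr2")
    names(el) <- paste0("el", seq_along(el))
    n <- 30
    s <- sample.int(9900, n)
    ev <- data.frame(tf = sample(c("A", "B", "C"), n, replace = TRUE),
                     cell = sample(c("c1", "c2"), n, replace = TRUE),
                     chrom = "chr2", start = s, end = s + 80)
    mapped <- mapTfEvents(el, ev)
    brute <- 0L
    for (i in seq_along(el)) for (j in seq_len(n)) {
      # event BED [start,end) vs element 1-based [start(el), end(el)]
      if (ev$start[j] < end(el)[i] && ev$end[j] > start(el)[i] - 1L)
        brute <- brute + 1L
    }
    expect_equal(nrow(mapped), brute)
  })
})

test_that("a planted 9/8/6 roster partitions exactly", {
  promOnly <- paste0("P", 1:9)
  bothTf <- paste0("B", 1:8)
  enhOnly <- paste0("Q", 1:6)
  ev <- rbind(
    do.call(rbind, lapply(promOnly, eventsFor, elements = c("R2", "R3"))),
    do.call(rbind, lapply(bothTf, eventsFor, elements = c("R2", "E2"))),
    do.call(rbind, lapply(enhOnly, eventsFor, elements = c("E1", "E2"))))
  mapped <- mapTfEvents(tfElements(), ev)
  part <- partitionTfs(mapped, promIds, enhIds)
  expect_equal(tfVennCounts(part),
               c(promoter_only = 9L, both = 8L, enhancer_only = 6L))
  expect_setequal(part$promoter_only, promOnly)
  expect_setequal(part$both, bothTf)
  expect_setequal(part$enhancer_only, enhOnly)
  # the three sets are disjoint and exhaust the bound TFs
  expect_equal(length(intersect(part$promoter_only, part$both)), 0L)
  expect_equal(length(intersect(part$both, part$enhancer_only)), 0L)
  expect_setequal(c(part$promoter_only, part$both, part$enhancer_only),
                  unique(mapped$tf))
})

test_that("partition is idempotent under event duplication and moves one TF at a time", {
  ev <- rbind(eventsFor("X", "R2"), eventsFor("Y", c("R3", "E1")))
  mapped <- mapTfEvents(tfElements(), ev)
  part <- partitionTfs(mapped, promIds, enhIds)
  expect_equal(part$promoter_only, "X")
  expect_equal(part$both, "Y")
  dup <- partitionTfs(rbind(mapped, mapped), promIds, enhIds)
  expect_equal(tfVennCounts(dup), tfVennCounts(part))
  # adding an enhancer event for X moves it to both, leaves Y alone
  ev2 <- rbind(ev, eventsFor("X", "E2"))
  part2 <- partitionTfs(mapTfEvents(tfElements(), ev2), promIds, enhIds)
  expect_setequal(part2$both, c("X", "Y"))
  expect_equal(length(part2$promoter_only), 0L)
  expect_error(partitionTfs(mapped, c("R1", "R2"), "E1"), "neither group")
})

test_that("stratification keeps totals and reports unclassified cells", {
  ev <- rbind(eventsFor("X", "R2", cell = "pos1"),
              eventsFor("X", "E2", cell = "pos1"),
              eventsFor("Y", "E1", cell = "neg1"),
              eventsFor("Y", "E2", cell = "mystery"))
  mapped <- mapTfEvents(tfElements(), ev)
  statuses <- data.frame(sample = c("pos1", "neg1"),
                         status = c("positive", "negative"),
                         source = "expression")
  tab <- stratifyByStatus(mapped, statuses, promIds, enhIds)
  expect_equal(sum(tab$n), nrow(mapped))
  expect_equal(tab$n[tab$tf == "Y" & tab$status == "unclassified"], 1L)
  expect_false(any(tab$status == "negative" & tab$tf == "X"))
  # all-positive events leave no negative stratum
  onlyPos <- mapTfEvents(tfElements(), eventsFor("Z", "R2", cell = "pos1"))
  tabPos <- stratifyByStatus(onlyPos, statuses, promIds, enhIds)
  expect_false("negative" %in% tabPos$status)
  # empty events give an empty table
  empty <- stratifyByStatus(mapped[0, ], statuses, promIds, enhIds)
  expect_equal(nrow(empty), 0L)
})

test_that("a planted positive-cell fraction is recovered within binomial error", {
  withr::with_seed(99, {
    n <- 400
    cells <- ifelse(runif(n) < 0.8, "pos1", "neg1")
    ev <- do.call(rbind, lapply(seq_len(n), function(i)
      eventsFor(sample(c("A", "B"), 1), sample(c("R2", "E1", "E2"), 1),
                cell = cells[i])))
    mapped <- mapTfEvents(tfElements(), ev)
    statuses <- data.frame(sample = c("pos1", "neg1"),
                           status = c("positive", "negative"),
                           source = "expression")
    tab <- stratifyByStatus(mapped, statuses, promIds, enhIds)
    fracPos <- sum(tab$n[tab$status == "positive"]) / sum(tab$n)
    expect_lt(abs(fracPos - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  })
})
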