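wellRow <- function(construct, experiment, replicate, firefly, renilla,
                    cell = "SJSA-1") {
  data.frame(construct = construct, cell_line = cell,
             experiment = experiment, replicate = replicate,
             firefly = firefly, renilla = renilla, stringsAsFactors = FALSE)
}

test_that("well normalization is firefly over renilla", {
  w <- rbind(wellRow("a", 1, 1, 5000, 1000),
             wellRow("a", 1, 2, 0, 800),
             wellRow("a", 1, 3, 750, 750))
  out <- normalizeWells(w)
  expect_equal(out$activity, c(5, 0, 1))
  bad <- wellRow("a", 1, 1, 10, 0)
  expect_error(normalizeWells(bad), "renilla")
  expect_error(normalizeWells(wellRow("a", 1, 1, -1, 10)), "firefly")
})

test_that("background subtraction is per experiment with a floor at zero", {
  w <- rbind(wellRow("promoterless", 1, 1, 500, 1000),   # bg 0.5
             wellRow("test", 1, 1, 5000, 1000),          # 5.0 -> 4.5
             wellRow("weak", 1, 1, 100, 1000),           # 0.1 -> 0
             wellRow("promoterless", 2, 1, 0, 1000),     # bg 0
             wellRow("test", 2, 1, 3000, 1000))          # identity
  out <- backgroundCorrect(normalizeWells(w))
  expect_equal(out$corrected[out$construct == "test"], c(4.5, 3))
  expect_equal(out$corrected[out$construct == "weak"], 0)
  noBg <- wellRow("test", 3, 1, 10, 10)
  expect_error(backgroundCorrect(normalizeWells(rbind(w, noBg))),
               "promoterless")
})

test_that("fold enhancement is a per-experiment ratio of means", {
  w <- rbind(wellRow("promoterless", 1:3, 1, 0, 1000),
             wellRow("ref", 1:3, 1, c(1000, 2000, 4000), 1000),
             wellRow("ref", 1:3, 2, c(1000, 2000, 4000), 1000),
             wellRow("test", 1:3, 1, c(2000, 4000, 8000), 1000))
  w <- backgroundCorrect(normalizeWells(w))
  fe <- foldEnhancement(w, "test", "ref", "SJSA-1")
  expect_equal(fe$fold, 2)          # twice the reference in every experiment
  expect_equal(unname(fe$per_experiment), c(2, 2, 2))
  self <- foldEnhancement(w, "ref", "ref", "SJSA-1")
  expect_identical(self$fold, 1)    # exactly 1, reference against itself
  zero <- rbind(wellRow("promoterless", 1:2, 1, 1000, 1000),
                wellRow("ref", 1:2, 1, 1000, 1000),
                wellRow("test", 1:2, 1, 2000, 1000))
  zero <- backgroundCorrect(normalizeWells(zero))
  expect_error(foldEnhancement(zero, "test", "ref", "SJSA-1"), "fold undefined")
})

test_that("one-tailed tests behave at the degenerate and extreme ends", {
  expect_equal(oneTailedTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p_value,
               0.5) # t = 0 under the symmetric null
  big <- oneTailedTest(c(101, 102, 103), c(1, 2, 3), paired = TRUE)
  expect_lt(big$p_value, 1e-6)
  expect_equal(big$test, "paired one-tailed t-test")
  welch <- oneTailedTest(c(10, 11, 12, 13), c(1, 2.5), paired = FALSE)
  expect_equal(welch$test, "Welch one-tailed t-test")
  expect_lt(welch$p_value, 0.05)
  expect_error(oneTailedTest(1, c(1, 2)), "at least 2")
  expect_error(oneTailedTest(c(1, 2, 3), c(1, 2), paired = TRUE), "matched")
})

test_that("both tests hold their type-I error under a lognormal null", {
  withr::with_seed(1234, {
    nrep <- 2000
    rejPaired <- rejWelch <- logical(nrep)
    for (i in seq_len(nrep)) {
      a <- rlnorm(3, 0, 0.3)
      b <- rlnorm(3, 0, 0.3)
      rejPaired[i] <- oneTailedTest(a, b, paired = TRUE)$p_value <= 0.05
      rejWelch[i] <- oneTailedTest(a, b, paired = FALSE)$p_value <= 0.05
    }
    expect_gt(mean(rejPaired), 0.03)
    expect_lt(mean(rejPaired), 0.07)
    expect_gt(mean(rejWelch), 0.03)
    expect_lt(mean(rejWelch), 0.07)
  })
})

test_that("summaries are scale-invariant in the expected ways", {
  sim <- simulateLuciferase(luciferaseEffects("SJSA-1"), seed = 2)
  base <- summarizeAssay(sim$wells)
  both <- sim$wells
  both$firefly <- both$firefly * 7
  both$renilla <- both$renilla * 7
  expect_equal(summarizeAssay(both), base)
  fOnly <- sim$wells
  fOnly$firefly <- fOnly$firefly * 7
  scaled <- summarizeAssay(fOnly)
  expect_equal(scaled$fold_vs_reference, base$fold_vs_reference)
  expect_equal(scaled$mean_relative_activity,
               base$mean_relative_activity * 7)
})

test_that("planted folds are recovered within 15% at assay-like noise", {
  eff <- luciferaseEffects("SJSA-1")
  want <- setNames(eff$fold, eff$construct)
  constructs <- c("pFAP_S+E1_up", "pFAP_S+E2_up", "pFAP_S+E1_down",
                  "pFAP_S+E2_down", "E2_prom")
  folds <- sapply(1:40, function(s) {
    sim <- simulateLuciferase(eff, seed = s)
    su <- summarizeAssay(sim$wells)
    setNames(su$fold_vs_reference, su$construct)[constructs]
  })
  med <- apply(folds, 1, median)
  expect_true(all(abs(med / want[constructs] - 1) < 0.15))
})

test_that("the optional BH adjustment adds a column without changing p-values", {
  sim <- simulateLuciferase(luciferaseEffects("SJSA-1"), seed = 4)
  plain <- summarizeAssay(sim$wells)
  adj <- summarizeAssay(sim$wells, adjust = "BH")
  expect_false("p_adjusted" %in% names(plain))
  expect_equal(adj$p_value, plain$p_value)
  expect_true(all(adj$p_adjusted >= adj$p_value, na.rm = TRUE))
})
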