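#' Packaged dual-luciferase effect tables
#'
#' Per-cell-line tables of construct effects, expressed as fold activity
#' relative to the short FAP promoter `pFAP_S` (whose activity is 1 by
#' definition; the promoterless background construct has fold 0). Rows
#' with `anchored = TRUE` carry effect sizes reported for that cell line
#' (ranges reported as "two-to three-fold" are encoded at their midpoint
#' 2.5); rows with `anchored = FALSE` are plausible fill-in values for
#' constructs whose activity was described only qualitatively, so the
#' simulated assay plates carry a full construct panel.
#'
#' Construct id grammar: `pFAP_S` / `pFAP_L` bare promoters,
#' `<promoter>+<element>_up` / `_down` for an enhancer cloned upstream of
#' the promoter or downstream of the luciferase gene, `<element>_prom` for
#' an enhancer placed alone at the promoter position, and `promoterless`.
#'
#' @param cellLine one of `"SJSA-1"`, `"SJCRH30"` (FAP-positive),
#'   `"PANC-1"`, `"MIA PaCa-2"` (FAP-negative).
#' @return a `data.frame` with columns `construct`, `promoter`, `enhancer`,
#'   `position`, `fold`, `anchored`.
#' @examples
#' luciferaseEffects("SJSA-1")
#' @export
luciferaseEffects <- function(cellLine = c("SJSA-1", "SJCRH30",
                                           "PANC-1", "MIA PaCa-2")) {
  cellLine <- match.arg(cellLine)
  row <- function(construct, promoter, enhancer, position, fold, anchored)
    data.frame(construct = construct, promoter = promoter,
               enhancer = enhancer, position = position, fold = fold,
               anchored = anchored, stringsAsFactors = FALSE)
  common <- rbind(
    row("promoterless", "none", "none", "none", 0, TRUE),
    row("pFAP_S", "pFAP_S", "none", "none", 1, TRUE))
  per <- switch(cellLine,
    "SJSA-1" = rbind(
      row("pFAP_S+E1_up",   "pFAP_S", "E1", "upstream",   18,   TRUE),
      row("pFAP_S+E2_up",   "pFAP_S", "E2", "upstream",   41,   TRUE),
      row("pFAP_S+E1_down", "pFAP_S", "E1", "downstream", 3.5,  TRUE),
      row("pFAP_S+E2_down", "pFAP_S", "E2", "downstream", 6.7,  TRUE),
      row("E1_prom", "none", "E1", "promoter_position",   5,    FALSE),
      row("E2_prom", "none", "E2", "promoter_position",   50.6, TRUE),
      row("pFAP_L", "pFAP_L", "none", "none",             4,    FALSE),
      row("pFAP_L+E1_up",   "pFAP_L", "E1", "upstream",   10,   FALSE),
      row("pFAP_L+E2_up",   "pFAP_L", "E2", "upstream",   10,   FALSE),
      row("pFAP_L+E1_down", "pFAP_L", "E1", "downstream", 10,   FALSE),
      row("pFAP_L+E2_down", "pFAP_L", "E2", "downstream", 10,   FALSE)),
    "SJCRH30" = rbind(
      row("pFAP_S+E1_up",   "pFAP_S", "E1", "upstream",   2.5,  TRUE),
      row("pFAP_S+E2_up",   "pFAP_S", "E2", "upstream",   58,   TRUE),
      row("pFAP_S+E1_down", "pFAP_S", "E1", "downstream", 2.5,  TRUE),
      row("pFAP_S+E2_down", "pFAP_S", "E2", "downstream", 8.4,  TRUE),
      row("E1_prom", "none", "E1", "promoter_position",   5,    FALSE),
      row("E2_prom", "none", "E2", "promoter_position",   55,   TRUE),
      row("pFAP_L", "pFAP_L", "none", "none",             4,    FALSE),
      row("pFAP_L+E1_up",   "pFAP_L", "E1", "upstream",   10,   FALSE),
      row("pFAP_L+E2_up",   "pFAP_L", "E2", "upstream",   10,   FALSE),
      row("pFAP_L+E1_down", "pFAP_L", "E1", "downstream", 10,   FALSE),
      row("pFAP_L+E2_down", "pFAP_L", "E2", "downstream", 10,   FALSE)),
    "PANC-1" = rbind(
      row("pFAP_S+E1_up",   "pFAP_S", "E1", "upstream",   2.3,  TRUE),
      row("pFAP_S+E2_up",   "pFAP_S", "E2", "upstream",   8.6,  TRUE),
      row("pFAP_S+E1_down", "pFAP_S", "E1", "downstream", 1.3,  TRUE),
      row("pFAP_S+E2_down", "pFAP_S", "E2", "downstream", 2.2,  TRUE),
      row("E1_prom", "none", "E1", "promoter_position",   2,    FALSE),
      row("E2_prom", "none", "E2", "promoter_position",   10,   FALSE),
      row("pFAP_L", "pFAP_L", "none", "none",             4,    FALSE),
      row("pFAP_L+E1_up",   "pFAP_L", "E1", "upstream",   4,    FALSE),
      row("pFAP_L+E2_up",   "pFAP_L", "E2", "upstream",   6,    FALSE),
      row("pFAP_L+E1_down", "pFAP_L", "E1", "downstream", 4,    FALSE),
      row("pFAP_L+E2_down", "pFAP_L", "E2", "downstream", 4,    FALSE)),
    "MIA PaCa-2" = rbind(
      row("pFAP_S+E1_up",   "pFAP_S", "E1", "upstream",   2.5,  TRUE),
      row("pFAP_S+E2_up",   "pFAP_S", "E2", "upstream",   2.5,  TRUE),
      row("pFAP_S+E1_down", "pFAP_S", "E1", "downstream", 2.5,  TRUE),
      row("pFAP_S+E2_down", "pFAP_S", "E2", "downstream", 2.5,  TRUE),
      row("E1_prom", "none", "E1", "promoter_position",   2,    FALSE),
      row("E2_prom", "none", "E2", "promoter_position",   10,   FALSE),
      row("pFAP_L", "pFAP_L", "none", "none",             4,    FALSE),
      row("pFAP_L+E1_up",   "pFAP_L", "E1", "upstream",   12,   FALSE),
      row("pFAP_L+E2_up",   "pFAP_L", "E2", "upstream",   12,   FALSE),
      row("pFAP_L+E1_down", "pFAP_L", "E1", "downstream", 12,   FALSE),
      row("pFAP_L+E2_down", "pFAP_L", "E2", "downstream", 12,   FALSE)))
  out <- rbind(common, per)
  rownames(out) <- NULL
  out
}

checkWellColumns <- function(wells, needActivity = FALSE,
                             needCorrected = FALSE) {
  need <- c("construct", "cell_line", "experiment", "replicate",
            "firefly", "renilla")
  if (needActivity) need <- c(need, "activity")
  if (needCorrected) need <- c(need, "corrected")
  missingCols <- setdiff(need, names(wells))
  if (length(missingCols))
    stop("wells table lacks column(s): ", paste(missingCols, collapse = ", "))
  invisible(wells)
}

#' Per-well Renilla normalization
#'
#' Adds `activity = firefly / renilla` per well: firefly luminescence
#' normalized to the co-transfected Renilla internal control, cancelling
#' transfection-efficiency and lysate-amount differences.
#'
#' @param wells data.frame with columns `construct`, `cell_line`,
#'   `experiment`, `replicate`, `firefly` (>= 0), `renilla` (> 0).
#' @return `wells` with an `activity` column appended.
#' @export
normalizeWells <- function(wells) {
  checkWellColumns(wells)
  if (any(!is.finite(wells$renilla)) || any(wells$renilla <= 0))
    stop("normalizeWells: renilla must be finite and > 0 in every well")
  if (any(!is.finite(wells$firefly)) || any(wells$firefly < 0))
    stop("normalizeWells: firefly must be finite and >= 0")
  wells$activity <- wells$firefly / wells$renilla
  wells
}

#' Subtract promoterless background per experiment
#'
#' Within each (cell line, experiment), the mean activity of the
#' promoterless-vector wells is subtracted from every well's activity and
#' the result floored at 0 (promoterless signal is additive photon
#' background, so correction is subtractive, never a division). The
#' correction never crosses experiments.
#'
#' @param wells output of [normalizeWells()].
#' @param promoterless construct id of the background wells (default
#'   `"promoterless"`).
#' @return `wells` with a `corrected` column appended.
#' @export
backgroundCorrect <- function(wells, promoterless = "promoterless") {
  checkWellColumns(wells, needActivity = TRUE)
  key <- interaction(wells$cell_line, wells$experiment, drop = TRUE)
  isBg <- wells$construct == promoterless
  bgMean <- tapply(wells$activity[isBg], key[isBg], mean)
  missing <- setdiff(levels(key), names(bgMean)[!is.na(bgMean)])
  if (length(missing))
    stop("backgroundCorrect: no promoterless wells for (cell line, experiment): ",
         paste(missing, collapse = "; "))
  wells$corrected <- pmax(wells$activity - as.numeric(bgMean[as.character(key)]), 0)
  wells
}

#' Fold-enhancement of a construct over a reference
#'
#' Per independent experiment, the ratio of the mean background-corrected
#' activity of the test construct to that of the reference construct; the
#' reported fold is the mean of the per-experiment ratios with its s.e.m.
#' Computing the ratio within experiment first cancels experiment-level
#' scale differences. The reference against itself is exactly 1.
#'
#' @param wells output of [backgroundCorrect()].
#' @param construct,reference construct ids to compare.
#' @param cellLine cell line to restrict to.
#' @param method `"per_experiment"` (default, as described above) or
#'   `"pooled"` (single ratio of grand means across all wells).
#' @return list with `fold`, `sem` (NA for `"pooled"`), `n_experiments`,
#'   and `per_experiment` (named vector of per-experiment folds).
#' @export
foldEnhancement <- function(wells, construct, reference, cellLine,
                            method = c("per_experiment", "pooled")) {
  method <- match.arg(method)
  checkWellColumns(wells, needActivity = TRUE, needCorrected = TRUE)
  w <- wells[wells$cell_line == cellLine, , drop = FALSE]
  if (!any(w$construct == construct))
    stop("foldEnhancement: no wells for construct '", construct, "' in ",
         cellLine)
  if (!any(w$construct == reference))
    stop("foldEnhancement: no wells for reference '", reference, "' in ",
         cellLine)
  refAll <- mean(w$corrected[w$construct == reference])
  if (!is.finite(refAll) || refAll <= 0)
    stop("foldEnhancement: reference mean corrected activity is <= 0; ",
         "fold undefined")
  if (method == "pooled") {
    fold <- mean(w$corrected[w$construct == construct]) / refAll
    return(list(fold = fold, sem = NA_real_,
                n_experiments = length(unique(w$experiment)),
                per_experiment = NULL))
  }
  exps <- base::sort(unique(w$experiment[w$construct == construct]))
  perExp <- vapply(exps, function(e) {
    test <- w$corrected[w$construct == construct & w$experiment == e]
    ref <- w$corrected[w$construct == reference & w$experiment == e]
    if (!length(ref))
      stop("foldEnhancement: experiment ", e, " lacks reference wells")
    refMean <- mean(ref)
    if (refMean <= 0)
      stop("foldEnhancement: reference mean corrected activity <= 0 in ",
           "experiment ", e, "; fold undefined")
    mean(test) / refMean
  }, 1.0)
  names(perExp) <- as.character(exps)
  list(fold = mean(perExp),
       sem = if (length(perExp) > 1L) sd(perExp) / sqrt(length(perExp)) else NA_real_,
       n_experiments = length(perExp),
       per_experiment = perExp)
}

#' One-tailed paired or Welch t-test
#'
#' The two significance tests used for reporter comparisons: a paired
#' one-tailed t-test for contrasts within the same cell line and
#' experiment series, and a one-tailed Welch (unequal variance) t-test
#' for contrasts across cell lines. Alternative hypothesis: `a > b`.
#'
#' The degenerate paired case where every difference is identical (zero
#' variance) is resolved by convention rather than erroring: p = 0.5 when
#' the common difference is 0 (symmetric null), p = 0 when positive,
#' p = 1 when negative.
#'
#' @param a,b numeric vectors, `n >= 2` each; for `paired = TRUE` they
#'   must be equal length and matched by experiment index.
#' @param paired logical flag.
#' @return list with `p_value`, `statistic` (t, possibly NA in the
#'   degenerate case), and `test` label.
#' @export
oneTailedTest <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("oneTailedTest: need at least 2 observations per group")
  if (paired && length(a) != length(b))
    stop("oneTailedTest: paired test needs matched groups of equal length")
  label <- if (paired) "paired one-tailed t-test" else
    "Welch one-tailed t-test"
  if (paired) {
    d <- a - b
    if (sd(d) == 0) {
      p <- if (mean(d) == 0) 0.5 else if (mean(d) > 0) 0 else 1
      return(list(p_value = p, statistic = NA_real_, test = label))
    }
    ht <- t.test(a, b, paired = TRUE, alternative = "greater")
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 0.5 else if (mean(a) > mean(b)) 0 else 1
      return(list(p_value = p, statistic = NA_real_, test = label))
    }
    ht <- t.test(a, b, paired = FALSE, var.equal = FALSE,
                 alternative = "greater")
  }
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       test = label)
}

#' Summarize a dual-luciferase assay
#'
#' Full quantification chain per (cell line, construct): Renilla
#' normalization, promoterless background subtraction within experiment,
#' per-experiment mean corrected activity, fold over the reference
#' construct (mean of per-experiment ratios, with s.e.m.), and a paired
#' one-tailed t-test of the construct's per-experiment activities against
#' the reference's (alternative: construct > reference). The reference row
#' reports fold exactly 1 and no p-value; the promoterless row is reported
#' like any other construct.
#'
#' @param wells raw wells data.frame (see [normalizeWells()] for the
#'   required columns), or the path to such a TSV.
#' @param reference reference construct id (default `"pFAP_S"`, the short
#'   FAP promoter alone, whose activity is taken as 1).
#' @param adjust p-value adjustment across constructs within a cell line:
#'   `"none"` (default, matching the original analysis) or `"BH"`
#'   (Benjamini-Hochberg, provided as an extension).
#' @param method fold computation method, see [foldEnhancement()].
#' @return a tidy `data.frame` with one row per (cell_line, construct):
#'   `mean_relative_activity`, `sem`, `n_experiments`, `fold_vs_reference`,
#'   `fold_sem`, `p_value`, `test`.
#' @export
summarizeAssay <- function(wells, reference = "pFAP_S",
                           adjust = c("none", "BH"),
                           method = c("per_experiment", "pooled")) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  if (is.character(wells) && length(wells) == 1L)
    wells <- read.delim(wells, stringsAsFactors = FALSE)
  wells <- backgroundCorrect(normalizeWells(wells))
  out <- list()
  for (cl in base::sort(unique(wells$cell_line))) {
    w <- wells[wells$cell_line == cl, , drop = FALSE]
    if (!any(w$construct == reference))
      stop("summarizeAssay: cell line ", cl, " lacks reference construct '",
           reference, "'")
    perExpAct <- function(construct) {
      sel <- w$construct == construct
      vapply(split(w$corrected[sel], w$experiment[sel]), mean, 1.0)
    }
    refAct <- perExpAct(reference)
    constructs <- base::sort(unique(w$construct))
    rows <- lapply(constructs, function(cs) {
      act <- perExpAct(cs)
      n <- length(act)
      if (cs == reference) {
        fold <- 1; foldSem <- 0; p <- NA_real_; testLabel <- NA_character_
      } else {
        fe <- foldEnhancement(w, cs, reference, cl, method = method)
        fold <- fe$fold; foldSem <- fe$sem
        if (n >= 2L && length(refAct) == n) {
          ht <- oneTailedTest(act, refAct[names(act)], paired = TRUE)
          p <- ht$p_value; testLabel <- ht$test
        } else {
          p <- NA_real_; testLabel <- NA_character_
        }
      }
      data.frame(
        cell_line = cl, construct = cs,
        mean_relative_activity = mean(act),
        sem = if (n > 1L) sd(act) / sqrt(n) else NA_real_,
        n_experiments = n,
        fold_vs_reference = fold, fold_sem = foldSem,
        p_value = p, test = testLabel,
        stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    if (adjust == "BH")
      block$p_adjusted <- p.adjust(block$p_value, method = "BH")
    out[[cl]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
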