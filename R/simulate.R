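#' Simulate a multi-cell-line peak landscape with planted enhancers
#'
#' Emulates the screen's input: one H3K27ac peak set per cell line, with
#' planted enhancer intervals recurring (boundary-jittered) across a
#' chosen number of FAP-positive lines and, for "shared" decoy elements,
#' in FAP-negative lines too, amid Poisson-distributed decoy peaks. No
#' decoy is placed within 1 kb of a clean planted enhancer (one with zero
#' negative support), so recovery of the planted truth is unambiguous.
#' Deterministic given `(parameters, seed)`.
#'
#' @param planted data.frame with columns `chrom`, `start`, `end` (BED
#'   convention), `name`, `support` (number of positive lines carrying
#'   the element), `negative_support` (number of negative lines carrying
#'   it; 0 for a clean enhancer).
#' @param nPositive,nNegative number of positive / negative cell lines
#'   (defaults 9 and 3, the line counts screened in the original design).
#' @param decoyRate decoy peaks per kb per line (default 0.2).
#' @param chromLength chromosome length in bp (default 100000).
#' @param chrom chromosome name (default `"chr2"`, where FAP resides).
#' @param jitter maximum boundary jitter in bp, uniform in
#'   `[-jitter, jitter]` (default 100).
#' @param seed integer seed.
#' @param dir if non-`NULL`, BED files (`pos_01.bed`, ..., `neg_01.bed`,
#'   ...) and `truth.json` are written there.
#' @return list with `positive` and `negative` (lists of
#'   [PeakSet-class]), `truth` (the planted manifest, JSON-serializable)
#'   and `files` (paths written or `NULL`).
#' @export
simulatePeakLandscape <- function(planted,
                                  nPositive = 9L, nNegative = 3L,
                                  decoyRate = 0.2, chromLength = 100000L,
                                  chrom = "chr2", jitter = 100L,
                                  seed = 1L, dir = NULL) {
  stopifnot(is.data.frame(planted),
            all(c("chrom", "start", "end", "name", "support",
                  "negative_support") %in% names(planted)))
  if (any(planted$support > nPositive))
    stop("simulatePeakLandscape: planted support exceeds nPositive")
  if (any(planted$negative_support > nNegative))
    stop("simulatePeakLandscape: planted negative_support exceeds nNegative")
  if (any(planted$start < 0 | planted$end > chromLength |
          planted$end <= planted$start))
    stop("simulatePeakLandscape: planted intervals outside chromosome")

  cleanIdx <- which(planted$negative_support == 0L)
  tooClose <- function(s, e) {
    if (!length(cleanIdx)) return(rep(FALSE, length(s)))
    res <- rep(FALSE, length(s))
    for (i in cleanIdx)
      res <- res | (s < planted$end[i] + 1000 & e > planted$start[i] - 1000)
    res
  }
  with_seed(as.integer(seed), {
    carriers <- lapply(seq_len(nrow(planted)), function(i)
      base::sort(sample.int(nPositive, planted$support[i])))
    negCarriers <- lapply(seq_len(nrow(planted)), function(i)
      base::sort(sample.int(nNegative, planted$negative_support[i])))

    jit <- function(x) x + sample(seq(-jitter, jitter), length(x),
                                  replace = TRUE)
    oneLine <- function(lineIdx, negative) {
      who <- if (negative) negCarriers else carriers
      keep <- vapply(who, function(c) lineIdx %in% c, TRUE)
      s <- planted$start[keep]; e <- planted$end[keep]
      if (length(s)) {
        s <- pmax(jit(s), 0L)
        e <- pmin(jit(e), chromLength)
        bad <- e - s < 50L
        s <- s[!bad]; e <- e[!bad]
      }
      nDecoy <- rpois(1L, decoyRate * chromLength / 1000)
      if (nDecoy > 0) {
        w <- pmax(100L, round(rlnorm(nDecoy, log(400), 0.5)))
        ds <- floor(runif(nDecoy, 0, pmax(chromLength - w, 1)))
        de <- pmin(ds + w, chromLength)
        drop <- tooClose(ds, de)
        ds <- ds[!drop]; de <- de[!drop]
        s <- c(s, ds); e <- c(e, de)
      }
      if (!length(s)) return(GRanges())
      GRanges(chrom, IRanges(as.integer(s) + 1L, as.integer(e)))
    }
    positive <- lapply(seq_len(nPositive), function(i)
      PeakSet(oneLine(i, FALSE), sampleId = sprintf("pos_%02d", i),
              mark = "H3K27ac"))
    negative <- lapply(seq_len(nNegative), function(i)
      PeakSet(oneLine(i, TRUE), sampleId = sprintf("neg_%02d", i),
              mark = "H3K27ac"))
  })
  truth <- list(
    planted = planted,
    n_positive = nPositive, n_negative = nNegative,
    decoy_rate = decoyRate, chrom = chrom, chrom_length = chromLength,
    jitter = jitter, seed = as.integer(seed))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (ps in c(positive, negative)) {
      p <- file.path(dir, paste0(sampleId(ps), ".bed"))
      writeBed(ps, p)
      files <- c(files, p)
    }
    tp <- file.path(dir, "truth.json")
    write_json(truth, tp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, tp)
  }
  list(positive = positive, negative = negative, truth = truth,
       files = files)
}

#' Default planted-enhancer table for screen simulations
#'
#' Two clean distal enhancers carried by all positive lines plus one
#' "shared" element also present in negative lines (which the negative
#' filter must remove) and one proximal promoter-like element, laid out
#' on a 100 kb toy chromosome.
#'
#' @param nPositive,nNegative line counts the supports refer to.
#' @return a `data.frame` suitable for [simulatePeakLandscape()].
#' @export
defaultPlanted <- function(nPositive = 9L, nNegative = 3L) {
  data.frame(
    chrom = "chr2",
    start = c(20000L, 62000L, 80000L, 49000L),
    end = c(20800L, 63000L, 80900L, 49800L),
    name = c("E1", "E2", "shared_decoy", "P_prox"),
    support = c(nPositive, nPositive, nPositive, nPositive),
    negative_support = c(0L, 0L, nNegative, 0L),
    stringsAsFactors = FALSE)
}

#' Simulate a TPM expression table with planted FAP statuses
#'
#' Housekeeping TPMs are drawn lognormally around typical levels; the
#' target gene's TPM is set so that the target / housekeeping-geomean
#' ratio equals the planted ratio for each sample (high for positives,
#' low for negatives, intermediate for indeterminates), with
#' multiplicative lognormal noise. The two anchor samples are placed
#' exactly at the configured anchor ratios (no noise on their ratios), so
#' the anchored classification boundary is sharp.
#'
#' @param nPositive,nNegative,nIndeterminate planted group sizes
#'   (defaults 12 / 5 / 3, echoing a twenty-cell-type compendium).
#' @param ratioHi,ratioLo planted target/housekeeping ratio for positive
#'   and negative samples (defaults 4 and 0.1).
#' @param anchorLo,anchorHi ratios of the negative and positive anchor
#'   samples, named `A549` and `transverse_colon` (defaults 0.25 and 1).
#'   Indeterminate samples are planted at the geometric mid of the
#'   anchors.
#' @param hkMean named TPM means of the four housekeeping genes.
#' @param noiseCv lognormal coefficient of variation (default 0.05).
#' @param nReplicates replicate columns per sample (default 2).
#' @param seed integer seed.
#' @return list with `exprs` (matrix genes x columns), `sampleMap`,
#'   `truth` (planted statuses and ratios).
#' @export
simulateExpressionTable <- function(nPositive = 12L, nNegative = 5L,
                                    nIndeterminate = 3L,
                                    ratioHi = 4, ratioLo = 0.1,
                                    anchorLo = 0.25, anchorHi = 1,
                                    hkMean = c(PSMB2 = 60, PSMB5 = 40,
                                               HPRT1 = 15, GAPDH = 1500),
                                    noiseCv = 0.05, nReplicates = 2L,
                                    seed = 1L) {
  stopifnot(ratioLo < anchorLo, anchorLo < anchorHi, anchorHi <= ratioHi)
  samples <- c(sprintf("pos_%02d", seq_len(nPositive)),
               sprintf("neg_%02d", seq_len(nNegative)),
               sprintf("ind_%02d", seq_len(nIndeterminate)),
               "A549", "transverse_colon")
  status <- c(rep("positive", nPositive), rep("negative", nNegative),
              rep("indeterminate", nIndeterminate),
              "negative", "positive")
  baseRatio <- c(rep(ratioHi, nPositive), rep(ratioLo, nNegative),
                 rep(sqrt(anchorLo * anchorHi), nIndeterminate),
                 anchorLo, anchorHi)
  isAnchor <- samples %in% c("A549", "transverse_colon")
  names(status) <- names(baseRatio) <- samples

  nCol <- length(samples) * nReplicates
  cols <- paste(rep(samples, each = nReplicates),
                sprintf("rep%d", seq_len(nReplicates)), sep = ".")
  genes <- c("FAP", names(hkMean))
  with_seed(as.integer(seed), {
    hk <- sapply(seq_len(nCol), function(j)
      hkMean * rlnormMean1(length(hkMean), noiseCv))
    ratio <- rep(baseRatio, each = nReplicates) *
      ifelse(rep(isAnchor, each = nReplicates), 1,
             rlnormMean1(nCol, noiseCv))
    target <- ratio * apply(hk, 2L, geometricMean)
  })
  exprs <- rbind(FAP = target, hk)
  rownames(exprs) <- genes
  colnames(exprs) <- cols
  sampleMap <- data.frame(column = cols,
                          sample = rep(samples, each = nReplicates),
                          stringsAsFactors = FALSE)
  truth <- list(
    statuses = as.list(status),
    ratios = as.list(baseRatio),
    negative_anchor = "A549", positive_anchor = "transverse_colon",
    ratio_hi = ratioHi, ratio_lo = ratioLo,
    anchor_lo = anchorLo, anchor_hi = anchorHi,
    noise_cv = noiseCv, n_replicates = nReplicates,
    seed = as.integer(seed))
  list(exprs = exprs, sampleMap = sampleMap, truth = truth)
}

#' Simulate dual-luciferase wells with planted construct effects
#'
#' For every construct in the effect table, each well's Renilla signal is
#' drawn lognormally around a plate-typical level; the firefly signal is
#' `renilla * (background + baseActivity * experimentEffect * fold)` with
#' multiplicative lognormal noise. The promoterless construct has fold 0,
#' so its normalized activity is exactly the additive background. An
#' experiment-level lognormal effect (shared by all constructs of one
#' experiment) emulates independent transfection batches; it cancels in
#' per-experiment fold ratios, which is why the pipeline computes folds
#' within experiment. Deterministic given `(parameters, seed)`.
#'
#' @param effects effect table as from [luciferaseEffects()] (columns
#'   `construct` and `fold`; a `promoterless` row with fold 0 is added if
#'   absent).
#' @param cellLine label stamped on the wells.
#' @param nExperiments,nReplicates independent experiments and wells per
#'   construct per experiment (defaults 3 and 3).
#' @param baseActivity corrected activity of the fold-1 reference
#'   construct (default 1).
#' @param background promoterless background as a fraction of
#'   `baseActivity` (default 0.05).
#' @param renillaMean,renillaCv Renilla luminescence level and lognormal
#'   CV (defaults 1e5 and 0.2).
#' @param noiseCv multiplicative measurement noise CV on firefly
#'   (default 0.10).
#' @param experimentCv between-experiment lognormal CV (default 0.2).
#' @param seed integer seed.
#' @return list with `wells` (data.frame: `construct`, `cell_line`,
#'   `experiment`, `replicate`, `firefly`, `renilla`) and `truth`.
#' @export
simulateLuciferase <- function(effects, cellLine = "SJSA-1",
                               nExperiments = 3L, nReplicates = 3L,
                               baseActivity = 1, background = 0.05,
                               renillaMean = 1e5, renillaCv = 0.2,
                               noiseCv = 0.10, experimentCv = 0.2,
                               seed = 1L) {
  stopifnot(is.data.frame(effects),
            all(c("construct", "fold") %in% names(effects)))
  if (!"promoterless" %in% effects$construct)
    effects <- rbind(effects[0, c("construct", "fold")],
                     data.frame(construct = "promoterless", fold = 0),
                     effects[, c("construct", "fold")])
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      experiment = seq_len(nExperiments),
                      construct = effects$construct,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fold <- setNames(effects$fold, effects$construct)[grid$construct]
  nW <- nrow(grid)
  with_seed(as.integer(seed), {
    expEffect <- rlnormMean1(nExperiments, experimentCv)
    renilla <- renillaMean * rlnormMean1(nW, renillaCv)
    signal <- background + baseActivity * expEffect[grid$experiment] * fold
    firefly <- renilla * signal * rlnormMean1(nW, noiseCv)
  })
  wells <- data.frame(
    construct = grid$construct,
    cell_line = cellLine,
    experiment = grid$experiment,
    replicate = grid$replicate,
    firefly = firefly,
    renilla = renilla,
    stringsAsFactors = FALSE)
  truth <- list(
    cell_line = cellLine,
    construct_effects = setNames(as.list(effects$fold), effects$construct),
    n_experiments = nExperiments, n_replicates = nReplicates,
    base_activity = baseActivity, background = background,
    renilla_mean = renillaMean, renilla_cv = renillaCv,
    noise_cv = noiseCv, experiment_cv = experimentCv,
    seed = as.integer(seed))
  list(wells = wells, truth = truth)
}

#' Default planted ChIP-qPCR truth table
#'
#' One row per (cell line, amplicon, sample kind) with the planted
#' per-cycle efficiency (a primer property, shared within amplicon) and
#' starting quantity. Enrichment over the negative-control regions is
#' planted high at the FAP promoter amplicons (P1, P2), at E2 (twice the
#' E1 level) and at the housekeeping promoters in the FAP-positive line,
#' and flat (except housekeeping) in the FAP-negative line.
#'
#' @param inputN0 starting quantity of the input wells (default 1e-6,
#'   relative to a plateau of 1).
#' @param ipBase starting quantity of an unenriched (fold 1) IP well
#'   (default 2e-8).
#' @param iggN0 starting quantity of the IgG mock-IP wells (default 5e-9).
#' @return a `data.frame` with columns `cell_line`, `amplicon`,
#'   `sample_kind`, `efficiency`, `n0`, `enrichment`.
#' @export
qpcrTruthTable <- function(inputN0 = 1e-6, ipBase = 2e-8, iggN0 = 5e-9) {
  amps <- c("P1", "P2", "E1", "E2", "NC1", "NC2", "PSMB2", "PSMB5")
  eff <- c(P1 = 1.95, P2 = 1.90, E1 = 1.85, E2 = 1.92,
           NC1 = 1.88, NC2 = 1.90, PSMB2 = 1.95, PSMB5 = 1.93)
  enr <- list(
    "SJSA-1" = c(P1 = 10, P2 = 10, E1 = 5, E2 = 10,
                 NC1 = 1, NC2 = 1, PSMB2 = 12, PSMB5 = 12),
    "MIA PaCa-2" = c(P1 = 1.5, P2 = 1.5, E1 = 1, E2 = 1,
                     NC1 = 1, NC2 = 1, PSMB2 = 12, PSMB5 = 12))
  rows <- list()
  for (cl in names(enr)) {
    for (a in amps) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, amplicon = a,
        sample_kind = c("IP_H3K27ac", "IP_IgG", "input"),
        efficiency = eff[[a]],
        n0 = c(ipBase * enr[[cl]][[a]], iggN0, inputN0),
        enrichment = c(enr[[cl]][[a]], NA, NA),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate qPCR amplification curves with planted efficiency and n0
#'
#' Each reaction's fluorescence follows a logistic amplification curve
#' whose exponential phase has the planted per-cycle factor and
#' extrapolates to the planted starting quantity:
#' `F(c) = base + plateau / (1 + exp(-k (c - c_mid)))` with
#' `k = log(efficiency)` and `c_mid = log(plateau / n0) / k`, plus
#' additive Gaussian noise. Wells are generated in triplicate.
#' Deterministic given `(parameters, seed)`.
#'
#' @param truth data.frame as from [qpcrTruthTable()] (columns
#'   `cell_line`, `amplicon`, `sample_kind`, `efficiency`, `n0`).
#' @param nCycles number of cycles (default 40).
#' @param plateau plateau fluorescence (default 1).
#' @param baseLevel constant instrument baseline added to every reading
#'   (default 0.02).
#' @param curveNoiseSd additive Gaussian noise, as a fraction of the
#'   plateau (default 0.01).
#' @param nReplicates wells per reaction (default 3).
#' @param seed integer seed.
#' @return list with `curves` (long data.frame `well`, `cycle`,
#'   `fluorescence`), `annotation` (`well`, `amplicon`, `sample_kind`,
#'   `cell_line`) and `truth`.
#' @export
simulateQpcr <- function(truth = qpcrTruthTable(), nCycles = 40L,
                         plateau = 1, baseLevel = 0.02,
                         curveNoiseSd = 0.01, nReplicates = 3L,
                         seed = 1L) {
  stopifnot(all(c("cell_line", "amplicon", "sample_kind", "efficiency",
                  "n0") %in% names(truth)))
  cyc <- seq_len(nCycles)
  rows <- vector("list", nrow(truth) * nReplicates)
  anno <- vector("list", nrow(truth) * nReplicates)
  with_seed(as.integer(seed), {
    idx <- 0L
    for (i in seq_len(nrow(truth))) {
      k <- log(truth$efficiency[i])
      cm <- log(plateau / truth$n0[i]) / k
      clean <- baseLevel + plateau / (1 + exp(-k * (cyc - cm)))
      for (r in seq_len(nReplicates)) {
        idx <- idx + 1L
        well <- sprintf("w%03d", idx)
        noisy <- clean + rnorm(nCycles, 0, curveNoiseSd * plateau)
        rows[[idx]] <- data.frame(well = well, cycle = cyc,
                                  fluorescence = noisy,
                                  stringsAsFactors = FALSE)
        anno[[idx]] <- data.frame(
          well = well,
          amplicon = truth$amplicon[i],
          sample_kind = truth$sample_kind[i],
          cell_line = truth$cell_line[i],
          stringsAsFactors = FALSE)
      }
    }
  })
  list(curves = do.call(rbind, rows),
       annotation = do.call(rbind, anno),
       truth = list(table = truth, n_cycles = nCycles, plateau = plateau,
                    base_level = baseLevel, curve_noise_sd = curveNoiseSd,
                    n_replicates = nReplicates, seed = as.integer(seed)))
}
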