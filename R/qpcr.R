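#' Estimate qPCR amplification efficiency from a raw fluorescence curve
#'
#' Simplified window-of-linearity estimation: after subtracting a baseline
#' (mean fluorescence of configured early cycles; the first two cycles are
#' excluded by default as instrument-settling artifacts), the exponential
#' phase is located as the sliding window of `windowSize` consecutive
#' cycles whose log10-fluorescence gives the best linear fit, restricted
#' to cycles below the plateau. The amplification efficiency is
#' `10^slope` (the per-cycle multiplication factor) and the starting
#' quantity `n0 = 10^intercept`, the regression extrapolated to cycle 0.
#'
#' When the curve has visibly plateaued, an optional logistic plateau
#' compensation is applied before the fit: with plateau level P estimated
#' from the final cycles, the series `y = F / (1 - F / P)` removes the
#' saturation bend of a logistic-shaped curve exactly, so the usable
#' fitting range extends close to the plateau where the signal-to-noise
#' ratio is best. On curves truncated before any plateau the compensation
#' is never triggered and the fit is the plain log-linear regression,
#' which is exact on noiseless exponential data.
#'
#' @param fluor numeric vector of fluorescence readings, one per cycle
#'   (cycle numbers `1:length(fluor)`), at least 15 cycles.
#' @param windowSize number of consecutive cycles in the regression
#'   window (default 5; sensible values 4-6).
#' @param baselineCycles cycles averaged for the baseline (default 3:8).
#' @param minR2 minimum R-squared the best window must reach; below it
#'   the curve is rejected with a "no exponential phase" error
#'   (default 0.99).
#' @param plateauFraction fraction of the (compensated) signal ceiling up
#'   to which cycles are eligible for fitting (default 0.9).
#' @param noiseFloorMult eligibility floor in units of the baseline
#'   standard deviation (default 10): cycles whose baseline-subtracted
#'   signal is below `noiseFloorMult * sd(baseline)` are excluded.
#' @param plateauCompensation apply the logistic compensation when a
#'   plateau is detected (default `TRUE`).
#' @return a list: `efficiency` (per-cycle factor), `n0`, `valid` (TRUE
#'   when efficiency lies in (1, 2.1]), `window` (first and last cycle of
#'   the chosen window), `r_squared`, `slope`, `intercept` (log10 scale),
#'   `baseline`, `plateau` (estimated level, NA if none detected).
#' @examples
#' f <- 0.01 * 2.0^(1:25) # noiseless, truncated before plateau
#' est <- estimateEfficiency(f)
#' est$efficiency # 2.0
#' est$n0         # 0.01
#' @export
estimateEfficiency <- function(fluor, windowSize = 5L, baselineCycles = 3:8,
                               minR2 = 0.99, plateauFraction = 0.9,
                               noiseFloorMult = 10, plateauCompensation = TRUE) {
  n <- length(fluor)
  if (n < 15L)
    stop("estimateEfficiency: need at least 15 cycles, got ", n)
  if (any(!is.finite(fluor)))
    stop("estimateEfficiency: non-finite fluorescence values")
  baselineCycles <- intersect(baselineCycles, seq_len(n))
  baseline <- mean(fluor[baselineCycles])
  noiseSd <- sd(fluor[baselineCycles])
  fb <- fluor - baseline
  top <- max(fb)
  if (!is.finite(top) || top <= 0)
    stop("estimateEfficiency: no exponential phase (no signal above baseline)")

  # plateau: final cycles flat relative to the overall signal swing
  lastIdx <- (n - 2L):n
  plateaued <- (fb[n] - fb[n - 3L]) < 0.05 * top
  plateau <- NA_real_
  y <- fb
  if (plateaued) {
    plateau <- mean(fb[lastIdx])
    if (plateauCompensation && plateau > 0) {
      frac <- pmin(fb / plateau, 0.995)
      y <- ifelse(fb > 0, fb / (1 - frac), fb)
    }
  }

  ceilingLevel <- if (plateaued) plateau else top
  floorLevel <- max(noiseFloorMult * ifelse(is.na(noiseSd), 0, noiseSd),
                    1e-9 * top)
  eligible <- is.finite(y) & y > 0 & fb > floorLevel &
    fb < plateauFraction * ceilingLevel

  # R^2 computed directly (avoids summary.lm warnings on perfect fits)
  r2Of <- function(fit, ly) {
    sstot <- sum((ly - mean(ly))^2)
    if (sstot == 0) return(0)
    1 - sum(stats::residuals(fit)^2) / sstot
  }
  cycles <- seq_len(n)
  best <- NULL
  for (s in seq_len(n - windowSize + 1L)) {
    win <- s:(s + windowSize - 1L)
    if (!all(eligible[win])) next
    ly <- log10(y[win])
    fit <- lm(ly ~ cycles[win])
    r2 <- r2Of(fit, ly)
    if (is.null(best) || r2 > best$r2)
      best <- list(win = win, r2 = r2, coef = coef(fit))
  }
  if (is.null(best) || !is.finite(best$r2) || best$r2 < minR2)
    stop("estimateEfficiency: no exponential phase (no window with R^2 >= ",
         minR2, ")")
  if (!plateaued) {
    # refine the baseline within the chosen window: the initial early-cycle
    # mean overestimates the baseline when amplification is already under
    # way there (short curves, high starting quantity), which bends the
    # log-linear fit; choose the constant that maximizes window linearity
    win <- best$win
    raw <- fluor[win]
    bMax <- min(raw) * 0.999
    if (bMax > 0) {
      r2For <- function(b) {
        v <- raw - b
        if (any(v <= 0)) return(-Inf)
        lv <- log10(v)
        r2Of(lm(lv ~ cycles[win]), lv)
      }
      opt <- stats::optimize(r2For, c(0, bMax), maximum = TRUE, tol = 1e-10)
      cand <- c(0, opt$maximum)
      bBest <- cand[which.max(vapply(cand, r2For, 1.0))]
      lv <- log10(raw - bBest)
      fit <- lm(lv ~ cycles[win])
      best <- list(win = win, r2 = r2Of(fit, lv), coef = coef(fit))
      baseline <- bBest
    }
  }
  slope <- unname(best$coef[2L])
  intercept <- unname(best$coef[1L])
  efficiency <- 10^slope
  list(
    efficiency = efficiency,
    n0 = 10^intercept,
    valid = efficiency > 1 && efficiency <= 2.1,
    window = c(best$win[1L], best$win[windowSize]),
    r_squared = best$r2,
    slope = slope,
    intercept = intercept,
    baseline = baseline,
    plateau = plateau)
}

#' Starting quantity from Cq and efficiency
#'
#' Closed-form quantification for Cq-mode input: the starting quantity
#' that reaches `threshold` after `cq` cycles of amplification at the
#' given per-cycle efficiency, `n0 = threshold / efficiency^cq`.
#'
#' @param cq quantification cycle(s).
#' @param efficiency per-cycle amplification factor in (1, 2.1], e.g. an
#'   amplicon-level mean efficiency.
#' @param threshold fluorescence threshold the Cq refers to (default 1).
#' @return numeric vector of starting quantities.
#' @examples
#' quantifyCq(20, 2) # 2^-20
#' @export
quantifyCq <- function(cq, efficiency, threshold = 1) {
  if (missing(efficiency) || any(is.na(efficiency)))
    stop("quantifyCq: efficiency is required for Cq-mode quantification")
  if (any(efficiency <= 1 | efficiency > 2.1))
    stop("quantifyCq: efficiency must lie in (1, 2.1]")
  threshold / efficiency^cq
}

#' Quantify a plate of qPCR reactions from raw curves
#'
#' Per well, [estimateEfficiency()] fits the exponential phase. Wells of
#' the same amplicon share primer chemistry, so quantification uses the
#' amplicon-level mean efficiency (mean of the valid per-well estimates):
#' a common fluorescence threshold per amplicon is placed inside the
#' fitted windows (geometric mean of the window-centre fitted values),
#' each well's Cq is read off its own regression line at that threshold,
#' and `n0 = threshold / meanEfficiency^Cq`. Ratios of `n0` within an
#' amplicon therefore depend only on Cq differences and the shared mean
#' efficiency.
#'
#' @param curves long-format data.frame with columns `well`, `cycle`,
#'   `fluorescence`.
#' @param annotation data.frame with columns `well`, `amplicon`,
#'   `sample_kind` (one of `IP_H3K27ac`, `IP_IgG`, `input`), `cell_line`.
#' @param ... passed to [estimateEfficiency()].
#' @return a data.frame with one row per well: the annotation columns
#'   plus `efficiency`, `r_squared`, `valid`, `amplicon_efficiency`,
#'   `threshold`, `cq`, `n0` (threshold/Cq mode) and `n0_curve` (the
#'   per-well regression intercept, for cross-mode comparison).
#' @export
quantifyReactions <- function(curves, annotation, ...) {
  stopifnot(all(c("well", "cycle", "fluorescence") %in% names(curves)))
  stopifnot(all(c("well", "amplicon", "sample_kind", "cell_line") %in%
                  names(annotation)))
  if (anyDuplicated(annotation$well))
    stop("quantifyReactions: duplicated wells in annotation")
  unknown <- setdiff(unique(curves$well), annotation$well)
  if (length(unknown))
    stop("quantifyReactions: unannotated well(s): ",
         paste(unknown, collapse = ", "))
  wells <- annotation$well
  fits <- lapply(wells, function(w) {
    sub <- curves[curves$well == w, , drop = FALSE]
    sub <- sub[base::order(sub$cycle), , drop = FALSE]
    tryCatch(estimateEfficiency(sub$fluorescence, ...),
             error = function(e) NULL)
  })
  names(fits) <- wells
  ok <- !vapply(fits, is.null, TRUE)
  res <- annotation
  res$efficiency <- NA_real_
  res$r_squared <- NA_real_
  res$valid <- FALSE
  res$slope_ <- NA_real_
  res$intercept_ <- NA_real_
  res$winmid_ <- NA_real_
  for (i in which(ok)) {
    f <- fits[[i]]
    res$efficiency[i] <- f$efficiency
    res$r_squared[i] <- f$r_squared
    res$valid[i] <- f$valid
    res$slope_[i] <- f$slope
    res$intercept_[i] <- f$intercept
    mid <- mean(f$window)
    res$winmid_[i] <- f$intercept + f$slope * mid # log10 fitted mid value
  }
  ampEff <- tapply(res$efficiency[res$valid], res$amplicon[res$valid], mean)
  res$amplicon_efficiency <- unname(ampEff[res$amplicon])
  thr <- tapply(res$winmid_[res$valid], res$amplicon[res$valid], mean)
  res$threshold <- 10^unname(thr[res$amplicon])
  # Cq: cycle at which the well's own regression line reaches the threshold
  res$cq <- (log10(res$threshold) - res$intercept_) / res$slope_
  res$n0 <- ifelse(res$valid & is.finite(res$amplicon_efficiency),
                   res$threshold / res$amplicon_efficiency^res$cq, NA_real_)
  res$n0_curve <- 10^res$intercept_
  res$slope_ <- res$intercept_ <- res$winmid_ <- NULL
  res
}

#' Percent input
#'
#' ChIP signal as a percentage of the fraction-adjusted input chromatin:
#' the input aliquot represents only `inputFraction` of the chromatin that
#' went into the immunoprecipitation, so its quantity is scaled up before
#' the ratio. Linear in the IP quantity.
#'
#' @param ip starting quantity of the immunoprecipitated sample.
#' @param input starting quantity measured in the input aliquot (> 0).
#' @param inputFraction fraction of the IP chromatin the aliquot
#'   represents, in (0, 1]. No default: the value depends on the wet-lab
#'   aliquoting scheme and must be supplied.
#' @return `100 * ip / (input / inputFraction)`.
#' @examples
#' percentInput(1e-6, 1e-6, 1) # 100
#' @export
percentInput <- function(ip, input, inputFraction) {
  if (missing(inputFraction))
    stop("percentInput: inputFraction must be supplied")
  if (any(inputFraction <= 0 | inputFraction > 1))
    stop("percentInput: inputFraction must be in (0, 1]")
  if (any(!is.finite(input)) || any(input <= 0))
    stop("percentInput: input quantity must be finite and > 0")
  100 * ip / (input / inputFraction)
}

#' ChIP-qPCR enrichment per amplicon
#'
#' Aggregates quantified reactions (triplicate wells averaged) into one
#' row per (cell line, amplicon) with the three quantities of interest:
#' `percent_input` of the H3K27ac IP, `fold_over_igg` (H3K27ac IP over
#' the matched IgG mock IP) and `fold_over_negative_region`
#' (percent-input relative to the mean percent-input of the negative
#' control amplicons). Both normalizations are emitted because a bar
#' chart may plot either.
#'
#' @param quantified output of [quantifyReactions()] (or any data.frame
#'   with columns `amplicon`, `sample_kind`, `cell_line`, `n0`).
#' @param inputFraction see [percentInput()].
#' @param ncAmplicons amplicon labels of the negative control regions
#'   (default `c("NC1", "NC2")`).
#' @return a data.frame with columns `cell_line`, `amplicon`,
#'   `percent_input`, `fold_over_igg`, `fold_over_negative_region`.
#' @export
chipEnrichment <- function(quantified, inputFraction,
                           ncAmplicons = c("NC1", "NC2")) {
  stopifnot(all(c("amplicon", "sample_kind", "cell_line", "n0") %in%
                  names(quantified)))
  out <- list()
  for (cl in base::sort(unique(quantified$cell_line))) {
    q <- quantified[quantified$cell_line == cl, , drop = FALSE]
    amps <- base::sort(unique(q$amplicon))
    meanN0 <- function(amp, kind) {
      v <- q$n0[q$amplicon == amp & q$sample_kind == kind]
      v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else mean(v)
    }
    pin <- vapply(amps, function(a) {
      ip <- meanN0(a, "IP_H3K27ac")
      inp <- meanN0(a, "input")
      if (!is.finite(inp) || inp <= 0)
        stop("chipEnrichment: input control missing or zero for amplicon ",
             a, " in ", cl)
      percentInput(ip, inp, inputFraction)
    }, 1.0)
    figg <- vapply(amps, function(a) {
      ip <- meanN0(a, "IP_H3K27ac")
      igg <- meanN0(a, "IP_IgG")
      if (!is.finite(igg) || igg <= 0)
        stop("chipEnrichment: IgG control missing or zero for amplicon ",
             a, " in ", cl)
      ip / igg
    }, 1.0)
    ncPresent <- intersect(ncAmplicons, amps)
    if (!length(ncPresent))
      stop("chipEnrichment: no negative control amplicon present for ", cl)
    ncMean <- mean(pin[ncPresent])
    if (!is.finite(ncMean) || ncMean <= 0)
      stop("chipEnrichment: negative-control percent input is zero for ", cl)
    out[[cl]] <- data.frame(
      cell_line = cl, amplicon = amps,
      percent_input = unname(pin),
      fold_over_igg = unname(figg),
      fold_over_negative_region = unname(pin / ncMean),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
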