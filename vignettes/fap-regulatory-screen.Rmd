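---
title: "Screening and quantifying cell-specific regulatory elements of the FAP gene"
author: "FAPscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and quantifying cell-specific regulatory elements of the FAP gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FAPscreen)
library(GenomicRanges)
```

# The problem

Fibroblast activation protein (FAP) is a cell-surface serine protease whose
expression is tightly restricted: it appears in activated stromal
fibroblasts (notably cancer-associated fibroblasts), in wound healing, and
in some tumour cells, but is silent in most normal tissue. Its promoter,
however, is active in FAP-negative cell lines too, so promoter sequence
alone cannot explain the specificity. The working model is that distal
enhancers, marked by H3K27ac in FAP-positive cells only, gate the
cell-specific output of the locus.

FAPscreen implements the computational arm of that investigation as one
tested pipeline:

1. an **in-silico enhancer screen** that calls candidate elements as
   regions of maximal H3K27ac peak consensus across FAP-positive cell
   lines, absent from FAP-negative lines, annotated with DNase
   hypersensitivity and transcription-factor (TF) cluster overlap, and
   classified promoter-proximal versus distal;
2. **expression-based cell classification** (housekeeping-normalized FAP
   expression, anchored grouping into positive / negative /
   indeterminate);
3. **TF partitioning** of binding events into promoter-only / both /
   enhancer-only sets, stratified by cell FAP status;
4. **dual-luciferase quantification**: Renilla normalization, promoterless
   background correction, per-experiment fold-enhancement, one-tailed
   paired and Welch t-tests;
5. **ChIP-qPCR quantification**: per-reaction amplification efficiency
   from raw fluorescence curves, starting quantities, percent input and
   enrichment over IgG and negative-region controls.

Every input the pipeline consumes can be produced by a seeded generator
that plants known ground truth, so each stage is validated by parameter
recovery rather than by fixtures.

# The consensus enhancer screen

## Model

Each cell line contributes one merged H3K27ac peak set. `coverageStack()`
partitions the genome into pieces of constant depth, where depth is the
number of lines whose peaks cover a base. `callConsensus()` keeps the
pieces with depth at least `ceiling(minSupportFraction * n_lines)`, closes
gaps up to `mergeGap`, and drops regions narrower than `minWidth`.
`filterByNegatives()` then removes anything overlapping more than
`maxNegativeHits` FAP-negative peak sets.

Coordinates are handled in one internal convention throughout —
`GRanges` (1-based, closed) — with conversion to and from the 0-based
half-open BED convention happening only in `readBed()`/`writeBed()`.
Adjacent intervals merge (peak callers split contiguous signal), and
strand is ignored everywhere: histone marks and DNase clusters are
unstranded.

## Parameters and defaults

* `minSupportFraction = 0.75`. Enhancers drop out of individual lines
  (E1, for example, carries the mark in only three of four browser-track
  cell lines), so requiring every line would be too strict; 0.75 tolerates
  one dropout in four while still demanding broad consensus.
* `maxNegativeHits = 0` (any overlap with any negative line disqualifies,
  regardless of its length — the plainest reading of "absent").
* `proximalWindow = 3000` bp: the conventional promoter territory
  upstream of the start codon; candidates nearer than this to the TSS are
  `proximal`, the rest `distal`. The TSS is supplied in `ScreenConfig`,
  never inferred from annotation tracks.
* `mergeGap = 500` bp, `minWidth = 200` bp: nucleosome-scale gap closing
  and a width floor below a minimal regulatory element.
* Ranking ties break deterministically: support desc, width desc,
  leftmost coordinate.

```{r screen}
sim <- simulatePeakLandscape(defaultPlanted(), seed = 1)
cfg <- ScreenConfig(tss = GRanges("chr2", IRanges(50001, 50001)))
cand <- callConsensus(sim$positive, cfg)
cand <- filterByNegatives(cand, sim$negative, cfg)
classifyProximity(cand, cfg)
```

# Expression-based cell classification

FAP TPM is divided by the geometric mean of four housekeeping genes
(PSMB2, PSMB5, HPRT1, GAPDH) per replicate; replicates collapse by the
median. The denominator uses exactly the four configured genes — a
missing gene is an error, never a three-gene fallback, because silently
changing the denominator breaks cross-sample comparability. Groups are
anchored: samples strictly below the known-negative anchor (A549) are
negative, samples at or above the lowest clearly positive sample
(transverse colon) are positive, the rest indeterminate; each anchor
belongs to its own group. Because only the ordering matters,
classification is invariant under any strictly monotone transform of the
normalized scale. Samples with externally known status but no expression
data (e.g. HL-60, MCF10A in the original compendium) are appended with
provenance via `appendExternalLabels()` and can never overwrite an
expression-derived label.

# Reporter quantification

## Model

Firefly luminescence is normalized per well to the co-transfected Renilla
control (`activity = firefly / renilla`), cancelling transfection
efficiency. The promoterless-vector signal is additive photon background,
so the correction is subtractive — the mean promoterless activity of the
same cell line and experiment is subtracted, floored at zero, and never
shared across experiments. (Whether background subtraction preceded or
followed Renilla normalization in the original workflow is not stated;
here it is applied to normalized activities.) Fold-enhancement of a
construct over the reference (the short promoter `pFAP_S`, activity 1 by
definition) is the per-experiment ratio of mean corrected activities,
averaged over the independent experiments with its s.e.m.; computing the
ratio within experiment first cancels experiment-level scale effects.
The reference against itself is exactly 1.

Contrasts of constructs within a cell line use the paired one-tailed
t-test on per-experiment activities; contrasts across cell lines use the
one-tailed Welch (unequal variance) test. No multiple-testing correction
is applied by default; a Benjamini–Hochberg option exists as an extension
(`summarizeAssay(..., adjust = "BH")`). One numerical convention: when a
paired contrast has zero-variance differences, `t.test()` would error, so
the package returns p = 0.5 for an all-zero difference (the symmetric
null), 0 or 1 for a constant positive or negative one.

At triplicate scale (n = 3 per group) the Welch test is measurably
conservative (type-I error near 0.035 at nominal 0.05) — a known
small-sample property of the Satterthwaite approximation. The package's
calibration experiments therefore run the null at n = 6 per group, where
both tests hold 0.04–0.06; at n = 3 the conservatism only makes
significance claims safer, never laxer.

## Packaged effect tables

`luciferaseEffects()` returns, per cell line, the construct panel with
planted fold effects relative to `pFAP_S`. Rows flagged `anchored = TRUE`
carry the reported effect sizes for that line — e.g. 18x (E1 upstream),
41x (E2 upstream), 3.5x / 6.7x downstream, and 50.6x for E2 placed alone
at the promoter position in SJSA-1; 58x for E2 upstream in SJCRH30.
Effects described only as ranges ("two-to three-fold") are encoded at the
midpoint 2.5; constructs whose activity was described only qualitatively
(E1 at the promoter position, the long-promoter rows) carry plausible
fill-in values flagged `anchored = FALSE` so a full plate can be
simulated.

```{r reporter}
sim <- simulateLuciferase(luciferaseEffects("SJSA-1"), seed = 7)
su <- summarizeAssay(sim$wells)
su[su$construct %in% c("pFAP_S", "pFAP_S+E1_up", "pFAP_S+E2_up"),
   c("construct", "fold_vs_reference", "fold_sem", "p_value")]
```

# ChIP-qPCR quantification

## Efficiency estimation

`estimateEfficiency()` is a deliberately simplified window-of-linearity
method: baseline (mean of cycles 3–8; cycles 1–2 are excluded as
instrument settling) is subtracted, and the exponential phase is the
sliding window of five cycles whose log10 fluorescence fits a line best,
below the plateau; efficiency is `10^slope`, and the starting quantity
`n0 = 10^intercept`. A window must reach R² ≥ 0.99 or the curve is
rejected ("no exponential phase"). Estimated efficiencies outside
(1, 2.1] are flagged invalid. This reproduces the quantification
*contract* of iterative window-of-linearity programs without aiming for
bit-compatibility with any of them.

Two numerical choices are this package's own:

* **Logistic plateau compensation.** Real (and simulated) amplification
  curves bend into a plateau; fitting the raw log signal below a plateau
  threshold leaves a small downward slope bias that compounds into n0
  ratios over the ~5–6 cycle separation of a 50-fold enrichment. When a
  plateau is detected (final cycles flat), the series is transformed to
  `y = F / (1 - F / P)` with P estimated from the final cycles; for a
  logistic curve this removes the bend exactly, so the usable fitting
  range extends into the high signal-to-noise region. Curves truncated
  before any plateau never trigger the transform, so the plain method's
  exactness on clean exponential data is untouched.
* **Baseline refinement.** On short curves with high starting quantity,
  amplification is already under way in the baseline cycles and the
  early-cycle mean overestimates the baseline. For non-plateaued curves
  the baseline constant is refined within the chosen window to maximize
  log-linearity, which restores exactness there too.

## Quantification and enrichment

Wells of one amplicon share primer chemistry, so `quantifyReactions()`
uses the amplicon-level mean efficiency: a common threshold per amplicon
is placed inside the fitted windows, each well's Cq is read off its own
regression line, and `n0 = threshold / meanEfficiency^Cq`. Within an
amplicon, n0 ratios then depend only on Cq differences and the shared
efficiency — the robust quantity for enrichment. `percentInput()` scales
the input aliquot by the `inputFraction` it represents; the aliquoting
scheme does not determine this value uniquely, so it must always be
supplied explicitly. `chipEnrichment()` emits percent input, fold over
IgG, and fold over the mean of the negative-control amplicons — both
normalizations, since either may be the quantity plotted.

```{r qpcr}
sim <- simulateQpcr(seed = 17)
q <- quantifyReactions(sim$curves, sim$annotation)
enr <- chipEnrichment(q, inputFraction = 0.1)
subset(enr, cell_line == "SJSA-1")
```

# What the generators emulate — and what they do not

* `simulatePeakLandscape()`: planted enhancer intervals recur across a
  chosen number of positive lines with uniform ±100 bp boundary jitter
  (imperfect peak alignment across samples), amid Poisson decoys; shared
  decoys also appear in negative lines. Defaults are nine positive and
  three negative lines on a 100 kb chromosome. Not emulated: peak width /
  signal-strength correlation, copy-number artefacts, mappability gaps.
* `simulateExpressionTable()`: lognormal housekeeping TPMs, target set to
  a planted ratio per status group (defaults: positives at 4, negatives
  at 0.1, anchors at 0.25 and 1, twenty samples in five groups with
  duplicate columns, CV 0.05). Anchor ratios are exact by construction.
  Not emulated: batch effects, compositional coupling between genes.
* `simulateLuciferase()`: lognormal Renilla per well, firefly =
  renilla x (background + activity), multiplicative lognormal measurement
  noise (CV 0.10), an experiment-level lognormal effect (CV 0.2) shared
  within an experiment, 3 experiments x 3 replicates. All luminescence
  noise is multiplicative and strictly positive, as in real assays. Not
  emulated: plate-position effects, cytotoxicity of large constructs.
* `simulateQpcr()`: logistic curves parameterized so the exponential
  phase has the planted per-cycle factor and extrapolates to the planted
  n0, plus a constant instrument baseline and additive Gaussian noise at
  1% of plateau, in triplicate. Not emulated: primer-dimer artefacts,
  melt behaviour, inter-run threshold drift.

Every generator is a pure function of `(parameters, seed)`; identical
calls are byte-identical. Passing recovery tests on these simulations
shows the pipeline's arithmetic and inference are correct under the
assumed noise model — it does not certify performance on real tracks or
plates, whose artefacts are listed above as explicitly out of model.

# Problem sizes used in the validation suite

The shipped tests exercise: 500 random interval instances against a
per-base brute-force oracle on a 10 kb toy chromosome; 50 screen seeds
(sensitivity and negative-filter specificity must both be perfect); 50
expression seeds (exact label recovery at ≥ 4x ratio separation, CV
0.05); 100 luciferase seeds per cell line (median recovered fold within
±15% of planted values spanning 1–58x); 10,000 null simulations for test
calibration; and 100 qPCR seeds (planted enrichments 2–50x recovered
within ±20% under 1% plateau noise, and exact efficiency recovery on
noiseless curves at 1.6 / 1.8 / 2.0). These sizes give stable estimates
of each property while keeping the default suite quick to run.

# Known limitations

* The screen operates on peak/cluster BED files; it neither calls peaks
  from signal nor stitches super-enhancers, and does not assign
  enhancers to genes (no chromatin-contact input).
* `readBed()` is strict by design: malformed lines fail loudly with a
  line number rather than being dropped, which is the right behaviour in
  a pipeline but means permissive browser exports may need cleaning.
* Efficiency estimation assumes a single exponential phase; multiphasic
  or heavily inhibited reactions are rejected rather than rescued.
* The anchored expression classifier presumes the two anchor samples are
  correctly chosen; it has no outlier protection if an anchor is wrong.
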