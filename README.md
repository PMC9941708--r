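# FAPscreen

Consensus enhancer screening and assay quantification for the *FAP*
locus.

Fibroblast activation protein (FAP) is a surface serine protease whose
expression is confined to activated fibroblasts (notably
cancer-associated fibroblasts) and a few tumour cell types, yet its
promoter is active even in FAP-negative cells. The cell specificity is
thought to be gated by distal enhancers carrying H3K27ac only in
FAP-positive cells. FAPscreen implements the computational pipeline for
dissecting this: an in-silico screen that nominates candidate enhancers
from multi-cell-line H3K27ac peak sets, expression-based classification
of cell lines by FAP status, transcription-factor partitioning across
promoter and enhancer elements, and quantification of the two validation
assays — dual-luciferase reporters and ChIP-qPCR — together with seeded
synthetic-data generators that plant known ground truth for every stage.

It is written for computational biologists who want a tested, fully
reproducible implementation of these procedures, exercisable end-to-end
without any external data.

## The core methods

**Consensus screen.** Each cell line contributes a merged H3K27ac peak
set. With depth *d(x)* = number of peak sets covering base *x*, candidate
elements are maximal regions with
*d(x) ≥ ⌈f · n⌉* (default *f* = 0.75 over *n* positive lines), after
closing gaps ≤ 500 bp and discarding regions < 200 bp; candidates
overlapping more than *k* (default 0) FAP-negative peak sets are removed.
Candidates are annotated with DNase-cluster overlap and the number of
distinct overlapping TF clusters, and classed proximal/distal by a 3 kb
window around the TSS.

**Expression classification.** Per sample,
*r = median over replicates of TPM(FAP) / geomean(TPM of PSMB2, PSMB5,
HPRT1, GAPDH)*; samples are grouped by two anchors (negative anchor A549,
positive anchor transverse colon): below the negative anchor → negative,
at/above the positive anchor → positive, between → indeterminate.

**Reporter assay.** Per well *activity = firefly / renilla*; the mean
promoterless activity of the same (cell line, experiment) is subtracted
(floored at 0); fold-enhancement is the per-experiment ratio of mean
corrected activities of construct vs the `pFAP_S` reference, averaged
across independent experiments ± s.e.m.; significance by one-tailed
paired (within cell line) or Welch (across cell lines) t-tests.

**ChIP-qPCR.** Per reaction, amplification efficiency *E* = 10^slope of
the best log-linear window of the baseline-subtracted fluorescence curve
(window of linearity, with logistic plateau compensation); starting
quantity *n0 = threshold / Ē^Cq* with the amplicon-level mean efficiency;
percent input = 100·n0(IP)/(n0(input)/inputFraction); enrichment reported
both over IgG and over negative-control amplicons.

## Worked example

Simulate a dual-luciferase plate for the FAP-positive SJSA-1 profile and
quantify it:

```r
library(FAPscreen)
sim <- simulateLuciferase(luciferaseEffects("SJSA-1"), seed = 7)
su <- summarizeAssay(sim$wells)
su[su$construct %in% c("pFAP_S", "pFAP_S+E1_up", "pFAP_S+E2_up", "E2_prom"),
   c("construct", "mean_relative_activity", "fold_vs_reference",
     "fold_sem", "p_value")]
#>     construct mean_relative_activity fold_vs_reference fold_sem p_value
#>       E2_prom                 52.418             47.35   0.4368 0.02564
#>        pFAP_S                  1.103              1.00   0.0000      NA
#>  pFAP_S+E1_up                 18.776             16.96   0.2994 0.02584
#>  pFAP_S+E2_up                 42.856             38.79   0.5377 0.02459
```

The effect table plants E1 upstream at 18-fold, E2 upstream at 41-fold
and E2-as-promoter at 50.6-fold over the short promoter `pFAP_S`
(activity 1 by definition); one simulated three-experiment series
recovers 16.96, 38.79 and 47.35 with p < 0.05 from the paired one-tailed
test — the same inference a wet-lab series would support.

ChIP-qPCR from raw fluorescence curves:

```r
simq <- simulateQpcr(seed = 17)
q <- quantifyReactions(simq$curves, simq$annotation)
subset(chipEnrichment(q, inputFraction = 0.1), cell_line == "SJSA-1")
#>  cell_line amplicon percent_input fold_over_igg fold_over_negative_region
#>     SJSA-1       E1         0.937         19.94                     4.682
#>     SJSA-1       E2         2.070         41.10                    10.343
#>     SJSA-1      NC1         0.202          4.09                     1.008
#>     SJSA-1      NC2         0.199          4.05                     0.992
#>     SJSA-1       P1         1.936         41.34                     9.672
#>     SJSA-1       P2         1.936         38.78                     9.671
#>     SJSA-1    PSMB2         2.322         47.35                    11.599
#>     SJSA-1    PSMB5         2.454         49.19                    12.257
```

The planted truth puts enrichment at 10 for the promoter amplicons and
E2, 5 for E1 (half of E2), 12 for the housekeeping-promoter positive
controls and 1 at the negative controls — recovered here within a few
percent from the simulated curves alone.

The enhancer screen runs from a file manifest
(`runScreen(manifest, config, outDir)`) and writes a candidates BED
(score = supporting line count) plus a JSON report with per-stage counts.
See the vignette (`vignettes/fap-regulatory-screen.Rmd`) for the full
model description, parameter rationale and generator assumptions.

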