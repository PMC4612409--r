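---
title: "Methods: trend-based marker selection and bisulfite amplicon methylation calling"
author: "methmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend-based marker selection and bisulfite amplicon methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmarker)
```

## Scope and model

`methmarker` implements the computational core of a colorectal
methylation-marker study design: genes whose expression changes *gradually*
along the ordered normal → adenoma → carcinoma (CRC) sequence are selected
from stage-labelled log2 expression matrices; the promoter regions of the
candidates are screened for CpG islands; promoter methylation is then
quantified from bisulfite amplicon sequencing reads; and the orthogonal
readouts — miRNA qPCR panels and immunohistochemistry (IHC) protein scores
— are normalised and summarised with the same conventions. A synthetic-data
module generates inputs with planted ground truth for every stage, so the
whole pipeline is exercisable and testable without any external download.

## Trend selection

For each gene the ordinal stage code (normal = 0, adenoma = 1, carcinoma
= 2) is correlated with expression using Kendall rank correlation. Because
the stage variable is massively tied, the tie-corrected **tau-b** variant is
used:

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

with $C$/$D$ the concordant/discordant pair counts, $n_0 = n(n-1)/2$, and
$n_1$, $n_2$ the tied pair counts in the two variables. Tau is rank-based,
so the 0/1/2 coding is immaterial — any strictly increasing recoding gives
the same value (this is tested, not configurable). A constant gene has an
undefined tau; it is reported as 0 with a `degenerate` flag and can never
be selected.

Stage pairs are additionally compared with two-sided **pooled-variance
(Student) t-tests** per gene (Welch available via `var_equal = FALSE`), and
Benjamini–Hochberg correction is applied across genes *within* each
comparison — the standard scope; pooling across comparisons would mix
different null families. Effect size is the difference of group mean log2
intensities (`logfc`).

A gene is selected iff

* `|tau| >= tau_min` (default 0.5),
* BH-adjusted p < `alpha` (default 0.05) in at least one normal-vs-lesion
  comparison, and
* `|logfc| > logfc_min` (default 1) in that same comparison.

One caveat is flagged in the documentation: the selection interval for the
trend statistic is sometimes printed in the source literature of this
design as $-0.5 \le \tau \le 0.5$, which taken literally keeps
*non*-trending genes. This package implements the $|\tau| \ge 0.5$ reading
and exposes `tau_min` so either convention can be applied explicitly.
Similarly, whether the "continuously altering" significance filter refers
to the trend test or the pairwise t-tests is ambiguous in such designs;
both p-values are therefore computed and reported side by side.

The two-way significance pattern of the normal-vs-adenoma and
normal-vs-carcinoma comparisons gives the Venn category (`both`,
`AD_only`, `CRC_only`, `neither`), and `demethylation_screen()` reuses the
same fold-change machinery for the two-condition 5-Aza re-expression
design (a gene is "re-expressed" when treated-minus-control logfc exceeds
the threshold; higher expression after demethylation suggests
methylation silencing).

## CpG island prediction

`predict_islands()` slides a `window` (default 100 bp) by `shift` (default
1) and marks windows with GC% above `min_gc` (50) and
observed/expected CpG ratio above `min_oe` (0.6), where

$$\mathrm{Obs/Exp} = \frac{N_{CG} \times L}{N_C \times N_G}.$$

Overlapping or book-ended marked windows are merged (the simplest
reproducible convention) and merged spans of at least `min_len` (200 bp)
are reported. The reported GC% and Obs/Exp of a span are means over its
contributing marked windows, so every reported span satisfies the
thresholds by construction. `N` bases count toward window length but not
toward any base count. The defaults mirror the conventional island
definition; none are asserted to equal any specific external program's
behaviour, and all are parameters.

## Bisulfite alignment

Bisulfite treatment converts unmethylated cytosine to uracil (read as T
after PCR) while 5-methylcytosine stays C. The aligner therefore never
compares reads against the genomic sequence but against **converted
references**: on the forward reference every non-CpG C becomes T and every
CpG C becomes the wildcard `Y` (matches C or T at full match score); the
reverse reference is the reverse complement treated symmetrically (non-CpG
G → A, CpG-mirror G → `R`). Methylation state thus never penalises the
alignment, and the asymmetric C/T handling lives entirely in the
reference, not in the scoring matrix.

Alignment is local Smith–Waterman with Gotoh's affine-gap three-state
recurrence, scored match +1, mismatch −1, gap open −2, gap extend −1 (all
configurable; a gap of length $L$ costs $open + (L-1) \cdot extend$). These
defaults are a deliberately simple edit-distance-like scheme appropriate
for short amplicon reads; the algorithm, not any particular
parameterisation, is the contract, and parity with any external aligner
binary is not claimed. Both orientations are always tried (amplicon
libraries are generally unstranded); ties go to forward. Traceback is
deterministic: diagonal preferred, then up (gap in the reference), then
left, with the first-encountered maximal cell winning — documented purely
for reproducibility.

The **read filter** keeps reads whose score is at least 80 % of the
maximum attainable score, defined per read as `match × read length` (a
gapless perfect full-length match), making the score fraction
read-length-normalised. The 0.80 boundary is inclusive ("a minimum of
80 %"). The DP implementation is verified against an exhaustive
enumeration oracle over all aligned-column subsets on small instances, and
against an independent reference aligner on wildcard-free instances.

## Methylation calling

At each CpG column of a passing alignment the read base is tallied:
C (or G on the reverse strand) as methylated, T (or A) as unmethylated,
and anything else — including a gap — as `count_other`. Gaps and non-C/T
bases are excluded from the denominator because they signal sequencing
error or misalignment rather than methylation state; 454-style chemistry
is particularly prone to homopolymer indels. The per-site fraction is
`count_C / (count_C + count_T)`, undefined at zero coverage (never an
error). Sites inside primer footprints are excluded from calling because
bisulfite PCR primers are designed over CpG-free stretches and would
otherwise dilute the signal.

Assay-level summaries are unweighted means of the defined site fractions
on the 0–100 percent scale (coverage weighting behind a flag); group
comparisons reuse the pooled-variance t-test, classifying each lesion
group versus the reference as hyper-/hypomethylated/unchanged. The
classification uses the raw per-assay p-value by default, with BH-adjusted
columns always reported and `adjust = TRUE` switching the classification
onto them. Hierarchical clustering of the assay × sample matrix defaults
to Euclidean distance with average linkage and row-mean imputation of
missing cells — none of these are canonical for this design, so all are
parameters; recovering any particular number of marker groups on real
data is explicitly not a contract.

## miRNA Ct normalisation

Raw Ct values are first inverted to an expression-like scale
(`max_cycle − Ct`, default maximum 45 cycles, so higher = more abundant),
then interplate calibration subtracts each plate's calibrator deviation
from the across-plate calibrator mean, and finally each sample is
normalised to its reference miRNA (default `hsa-miR-423-5p`). The
calibrator-before-reference order is fixed by the design; the inversion
commutes with both steps and is placed first so that all downstream
quantities are on the intuitive scale. Mean-centring across plates is a
documented choice — whether any particular historical run used
mean-centring or a designated reference plate is generally not stated, and
the two differ only by a global constant that the reference step removes
anyway. Undetected wells stay missing rather than being imputed at the
maximum cycle; imputation policies vary between labs and silent imputation
is the more dangerous default. Samples without a reference measurement are
flagged and excluded from comparisons.

Differential miRNAs are ranked against a user-supplied miRNA → gene
prediction table by the number of selected genes they target
(deterministic order: count descending, id ascending). Querying any live
prediction database is out of scope; the table is an input.

## IHC Quick-scores

A tissue-microarray core's Q-score is percent positive cells (0–100)
times a single dominant intensity grade (0–3), range 0–300. Scoring one
dominant intensity per core (rather than an H-score-style sum over
intensity bins) is the documented convention here. Group summaries report
mean ± SD per stage and a strict monotone-trend flag across the stage
order.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* the analysis assumes,
with recorded ground truth:

* `gen_staged_expression()` — log2 intensities with per-gene baselines
  drawn from 4–10 (typical normalised microarray range), equal per-stage
  steps for planted genes and Gaussian noise. Defaults (`step_effect`
  1.5, `noise_sd` 1, 10 samples/stage in the acceptance runs) represent a
  clearly-expressed marker panel on a biopsy-scale cohort.
* `gen_bisulfite_reads()` — full-length amplicon reads (amplicon
  sequencing produces no fragmenting) with per-site Bernoulli methylation,
  optional incomplete conversion, substitutions, and indels whose rate is
  multiplied inside homopolymer runs of ≥ 3 bases (threshold and
  multiplier, default 3, are parameters: 454-style chemistry is known to
  err in homopolymers but no canonical rate exists, so defaults are
  exposed rather than asserted as realistic). Insertions duplicate the
  current base and deletions drop it, mimicking homopolymer over/undercall.
* `gen_ct_plates()` — per-miRNA base Ct 22–34, additive plate offsets
  carried by calibrator wells, planted group shifts, Gaussian noise.
* `gen_qscore_cores()` — cores decomposed into a dominant intensity and a
  percent-positive value reproducing a requested group mean.

All generators are deterministic given a seed, restore the caller's RNG
state, and reproduce their parameters exactly at zero noise — properties
the test suite asserts. What they do **not** emulate: probe-level
microarray artefacts and normalisation residue, batch effects,
within-group biological heterogeneity beyond i.i.d. noise, flowgram-level
454 error structure, primer bias, or bisulfite degradation. Passing tests
on synthetic data therefore demonstrate correctness of the computations
and recoverability under the stated error model, not performance on real
tissue data, whose headline numbers depend on cohorts this package does
not ship.

## Numerical and design choices

* Coordinates are 1-based and closed throughout the R interface (the
  native R and Bioconductor convention); BED output converts to 0-based
  half-open.
* Degenerate t-tests follow fixed conventions: identical constant groups
  give p = 1 (t = 0); zero within-group variance with different means
  gives p = 0.
* `bh_adjust()` validates and delegates to the standard step-up
  implementation; tests verify it against an oracle written directly from
  the definition.
* All randomness in `run_pipeline()` flows from one global seed through
  fixed per-stage offsets, and every artifact is plain text with doubles
  serialised at full precision, so a config + seed reproduces the bundle
  byte for byte and any single stage can be re-run from its persisted
  inputs with identical results.
* Problem sizes in the acceptance checks (500 random read/template pairs
  for the aligner oracle, 100 seeded replicates of 500 reads for
  methylation recovery, 20 seeds of a 1000-gene matrix for the trend
  operating characteristics) were chosen as the smallest sizes at which
  the binomial/Monte-Carlo margins are comfortably resolved.

## Worked example

```{r example}
sim <- gen_staged_expression(n_genes = 200, n_per_group = 10,
                             n_trend_up = 5, n_trend_down = 5,
                             step_effect = 1.5, noise_sd = 1, seed = 1)
res <- trend_select(sim$matrix, sim$samples$stage)
table(selected = res$selected)
head(res[res$selected, c("gene", "tau", "q_n_crc", "logfc_n_crc",
                         "direction", "venn")])

tpl <- synthetic_amplicon("demo", length = 80, n_cpg = 3, seed = 2)
reads <- gen_bisulfite_reads(tpl, c(0.1, 0.5, 0.9), n_reads = 200, seed = 3)
calls <- call_cpg_methylation(align_reads(reads$reads, tpl))
calls
```

## Limitations

The pipeline deliberately stops short of: microarray preprocessing from
raw scanner files, genome-scale bisulfite mapping or flowgram-space
alignment, beta-binomial or region-level differential-methylation models,
live target-database queries, and image analysis for IHC. Each of these
has mature dedicated tooling; this package covers the marker-selection and
amplicon-quantification logic that connects them.
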