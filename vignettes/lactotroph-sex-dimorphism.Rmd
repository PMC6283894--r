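---
title: "Methods: sex-dimorphism analysis of lactotroph tumor genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-dimorphism analysis of lactotroph tumor genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactodim)
```

## Scope

Lactotroph (prolactin-secreting) pituitary tumors behave more aggressively
in men than in women, and reduced estrogen-receptor-alpha signaling has been
proposed as a driver of that dimorphism. `lactodim` implements the complete
analysis chain used to interrogate that question in a 30-tumor cohort
(20 men, 10 women): single-channel array preprocessing, men-vs-women
differential expression with a signed fold-change filter, a per-chromosome
enrichment statistic for the deregulated genes, copy-number segmentation
with fixed gain/loss cutoffs, and the intersection of recurrently gained
regions with upregulated genes that yields sex-specific candidate genes.
Because the original array data are not bundled, a synthetic-cohort
generator reproduces the statistical structure of the study so every stage
is exercisable and testable offline; the package also ships the published
per-tumor copy-number event lists, the per-chromosome enrichment table and
the 32-gene candidate table as curated plain-text inputs so that the
printed-table arithmetic can be recomputed exactly.

## Preprocessing

Raw probe intensities are divided by their own array's median, so every
sample has median intensity exactly 1 (`median_normalize()`). This is a
per-sample scale correction only; no cross-array quantile adjustment or
background subtraction is attempted.

The detection threshold is derived from the negative-control probes:
per sample, threshold = mean + `k_sd` x SD of that sample's normalized
control intensities, with the sample SD (n-1 denominator). A probe is
"present" when it strictly exceeds the threshold. The proprietary formula
used by the original array software is unpublished; `k_sd = 2` is this
package's declared stand-in, it is exposed as a parameter and recorded in
the run report. Raising `k_sd` can only convert present calls to absent
ones, never the reverse.

Normalized intensities are converted to log2 with a floor of 2^-10 applied
first, so zero intensities cannot produce `-Inf`. All downstream statistics
operate on this log2 scale.

## Differential expression

Probes are collapsed to genes by the mean of their log2 intensities — the
simplest deterministic rule; it is recorded in the run report. Genes absent
in every sample are dropped before testing; partial absence does not
exclude a gene.

The contrast is the classical pooled-variance Student's t-test (men vs
women, two-sided); Welch's correction is available behind a flag but is not
the default because the equal-variance test is the study's stated method.
The test is computed by a vectorized row-wise implementation validated in
the test suite against `stats::t.test()` to 1e-12. When both groups are
constant and equal the statistic is undefined and p = 1 is returned with a
degeneracy flag; constant but unequal groups give p = 0.

Fold changes follow the signed convention used throughout this literature:
with r = 2^(mean_a − mean_b), the reported value is r when r >= 1 and −1/r
otherwise, so magnitudes are symmetric about +/−1 and no value falls inside
(−1, 1). Fold changes are computed from log2 means (a geometric-mean
ratio), consistent with performing the analysis on the log2 scale; whether
the original analysis used linear or geometric means is not stated, so the
linear alternative is available via `linear_fc = TRUE` and the choice is
logged. A gene is called deregulated when p <= alpha (default 0.05) and
|fold change| >= `fc_min` (default 2). No multiple-testing correction is
applied to this filter, matching the original analysis; a
Benjamini–Hochberg FDR column is emitted for reference only.

## Per-chromosome enrichment

For chromosome lambda the statistic is, in percentage points,

Delta(lambda) = 100 x [ n_dereg(lambda) / N_dereg − G(lambda) / G_total ]

i.e. the chromosome's share of deregulated genes minus its share of all
annotated genes. Both denominators always run over the complete annotation,
so over a complete chromosome selection the deltas sum to zero exactly;
the default output selection is autosomes only (the published table's
convention), over which the sum is generally non-zero — both behaviors are
asserted in the tests. Chromosomes are then ranked by decreasing delta and
annotated with the absolute distance from the median delta. The annotation
(hence every G(lambda)) is always an input; no gene counts are hard-coded.
An optional permutation p-value (resampling deregulated-set labels over the
annotation) is provided as an extension beyond the descriptive statistic.

## Copy number

Probe-level copies are estimated as baseline x tumor/reference against a
normal-pool reference, with baseline 2 on autosomes and sex-adjusted on the
gonosomes (male X = Y = 1; female X = 2; female Y probes are excluded with
a logged count).

Segmentation is exact penalized least-squares changepoint detection: the
sum of within-segment squared errors plus a per-segment penalty is
minimized by an O(n^2) dynamic program. The original study used a
proprietary "genomic segmentation" implementation whose model and penalty
are unpublished; an exact, oracle-testable method is substituted
deliberately, and the test suite verifies it against exhaustive enumeration
of all changepoint configurations on small instances. The default penalty
is 2 x sigma^2 x log(n) with sigma^2 estimated from first differences,
sum(diff(x)^2) / (2(n−1)), which is robust to sparse true level shifts.
Ties are broken toward fewer segments, and segments must contain at least
3 probes (configurable) to suppress single-probe artifacts.

Calling uses the study's fixed cutoffs: gain above 2.7 copies, loss below
1.3, strict inequalities (a segment at exactly 2.7 is neutral). On sex
chromosomes the cutoffs are scaled by baseline/2, e.g. male X gain above
1.35. Segments are labeled with the arm(s) they overlap; a
centromere-spanning segment counts toward both arms. For recurrence
counting, a whole-chromosome event matches both arm-level and
chromosome-level queries, since the printed per-tumor event lists do not
resolve borderline cases; counts are deduplicated per sample.

## Integration and correlation

A candidate gene must be upregulated (fold change >= `fc_min`,
p <= alpha) and have its annotated interval overlap (1-based inclusive,
>= 1 bp) a called gain segment in at least `min_samples` samples of the
chosen subgroup. Whether the original four-gene chromosome-19 finding
required recurrence across all gained tumors or any one of them is not
recoverable, so `min_samples` defaults to 1 and is exposed; an arm-level
fallback exists for coarse probe resolution and the matching mode is
recorded in the output. In noisy runs a segment boundary can overshoot the
centromere by about a probe spacing, which can add near-centromere q-arm
genes supported by a single sample; requiring recurrence across the
subgroup (raising `min_samples`) removes them, and the acceptance script
reports both the full candidate list size and the recovery of the planted
panel.

Correlation panels report Pearson r with the exact t-transform p-value
(t = r sqrt((n−2)/(1−r^2)), n−2 df), matching the magnitude of the
published panel p-values; a permutation option exists for small groups.
Zero-variance genes within a group are reported as missing with a flag
rather than silently dropped.

## The synthetic cohort

The generator's defaults are the study conditions, fixed once:

* 20 men vs 10 women; grade margins 6/1/1/2 (women) and 4/1/8/7 (men)
  across 1a/1b/2a/2b, with two of the seven male grade-2b tumors
  progressing to grade 3 after metastasis. Margins are assigned exactly —
  the seed permutes assignment and drives continuous draws only — because
  the printed cohort counts are conditions, not random quantities.
  Invasiveness derives from grade (2a and above), which reproduces the
  printed invasive counts (15/20 men, 3/10 women).
* ER-alpha immunoreactivity scores are drawn around 3 (men) and 7 (women),
  clamped to 0–12; aggressive tumors get very low scores, emulating the
  receptor-negative aggressive phenotype.
* 55,000 probes including 100 negative controls over a ~19,500-gene
  annotation with realistic per-chromosome gene counts on synthetic
  (rounded) chromosome geometry.
* 140 planted sex-differential genes: a four-gene 19p panel, eleven
  Y-linked genes (log2FC +3), seven X-linked genes, and the remainder
  spread over autosomal q arms in proportion to chromosome gene content
  (no positional preference beyond size); 120 up at log2FC +2, 20 down at
  −2. The study gives no noise magnitude for either platform, so the
  expression noise (homoscedastic Gaussian, SD 0.25 in log2) and the
  copy-number probe noise (SD 0.3) are simulation conveniences chosen so
  that planted effects are comfortably but not trivially detectable at
  n = 20 vs 10; they are not estimates of the real arrays.
* Negative controls are drawn 3 baseline-SDs below the gene-probe
  baseline, so the detection rule separates controls from signal by
  construction.
* A 19p gain at 3.2 copies confined to aggressive males and a chromosome-11
  loss at 1.0 copies in all but one aggressive tumor, emulating the
  recurrent events; copy-number probes are evenly spaced (80 per
  chromosome).
* Correlation structure is planted through shared latent factors. For gene
  pairs the factor loading is b = sigma sqrt(r/(1−r)), which makes the
  pairwise correlation equal the target r in expectation; for the
  ESR1-to-IR-score coupling the loading is sigma r / sqrt(1−r^2), the
  value-versus-observed-factor form. Both identities are verified by
  Monte-Carlo in the tests.

All randomness flows from one master seed through fixed per-stage
sub-seeds; two runs with the same configuration are identical.

What the generator does **not** emulate: batch and spatial array effects,
intensity-dependent (heteroscedastic) noise, probe sequence effects,
real genome coordinates, tumor purity, or allele-specific copy number.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to those real-data
phenomena.

One deliberate small-scale caveat: at toy scale the planted fraction of
the transcriptome is large (about a fifth), so per-sample median scaling
itself shifts the group means; exactness checks of the planted fold
changes are therefore run on the generator's own log2 output, while at the
full 55,000-probe complement (0.7% of genes planted) the normalization
bias is negligible and the full pipeline recovers 140/120/20 exactly.

## Problem sizes and numerical choices

The unit tests run the full study conditions on a reduced complement
(720 genes, 2,000 probes, 40 copy-number probes per chromosome); null
calibration uses 10,000 simulated null genes; segmentation exactness is
verified on instances of up to 50 probes against exhaustive search;
breakpoint recovery uses 100 seeded 40-probe replicates. The analysis
scripts and the acceptance script run the full 55,000-probe conditions.
Comparisons against expected costs use 1e-9 tolerances; segment-cost ties
are broken toward fewer segments; display rounding (2 decimals for delta,
integer percentages) happens only at serialization.

## Known limitations

* The curated event lists are transcriptions of printed tables at the
  resolution printed there; arm- vs chromosome-level ambiguity in
  borderline events is handled by the permissive matching rule above.
* The detection rule and the segmentation model are declared stand-ins for
  unpublished proprietary methods; only the gain/loss cutoffs and the
  normalization convention are reproducible as stated.
* Reproducing the deposited-cohort numerical results (the identity of the
  140 genes, their fold changes, the ESR1 correlations) requires the
  deposited arrays and is out of scope; the synthetic cohort recovers the
  planted analogues instead.
* The functional-category cross-tabulation consumes user-supplied category
  tables; no pathway-analysis scoring is reimplemented.
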