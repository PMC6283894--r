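# lactodim

Sex-dimorphism analysis of lactotroph (prolactin-secreting) pituitary
tumor genomics.

Lactotroph tumors are more aggressive in men than in women, and reduced
estrogen-receptor-alpha (ERα) signaling is a suspected driver. `lactodim`
is an R package plus a numbered analysis workflow that implements the full
chain used to study this in a 30-tumor cohort (20 men, 10 women):

1. **Preprocessing** — median normalization of single-channel array
   intensities to 1 per sample; per-sample detection thresholds from the
   100 negative-control probes (mean + 2 SD); log2 transform.
2. **Differential expression** — pooled-variance Student's *t* (men vs
   women) with the signed fold-change convention
   FC = r if r ≥ 1 else −1/r, r = 2^(mean_M − mean_F),
   and the joint filter *p* ≤ 0.05 and |FC| ≥ 2.
3. **Chromosome enrichment** — per chromosome λ,
   Δ(λ) = 100·[n_dereg(λ)/N_dereg − G(λ)/G_total] (percentage points),
   ranked by distance from the median Δ.
4. **Copy number** — exact penalized least-squares changepoint
   segmentation; gain calls above 2.7 copies, losses below 1.3 (strict,
   baseline-scaled on sex chromosomes); per-group recurrence counts.
5. **Integration** — genes both ≥ 2-fold upregulated and inside
   recurrently gained regions of a subgroup (the male 19p candidates);
   sex-stratified Pearson correlation panels; ERα-protein vs ESR1-mRNA
   correlation; functional category cross-tabulation.

A seeded synthetic-cohort generator reproduces the study's statistical
structure (cohort margins, a planted 140-gene sex signature, a 19p gain
confined to aggressive males, a chromosome-11 loss in most aggressive
tumors, male-restricted correlation panels), so the entire pipeline runs
and is tested without any external data. The published per-tumor
copy-number events, the per-chromosome enrichment table and the 32-gene
candidate table are shipped as curated plain-text tables under
`inst/extdata/` so their arithmetic can be recomputed exactly.

## Worked example

The workflow scripts run the full default conditions (55,000 probes,
20 vs 10 samples) end to end and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # inputs under results/data/
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_chromosome_enrichment.R
Rscript analysis/05_copy_number.R
Rscript analysis/06_integration.R
Rscript analysis/07_cohort_summary.R
```

Selected output from a run with the default seed:

```
deregulated genes: 140 (120 up in men, 20 down) of 19452 tested
published cohort table: median delta 0.53%; furthest from it: chr19 (0.80), chr3 (0.77), chr2 (0.75), chr5 (0.73)
synthetic cohort: 19p gain in 7/7 aggressive males; chr11 loss in 8/9 aggressive tumors
published CGH table: 19p gain in 3 tumors (all aggressive males); chr11 loss in 5/6 aggressive tumors
CTAG2 aggressiveness panel: mean r 0.82 in men, -0.11 in women
ESR1 mRNA vs ER-alpha IR score: r = 0.754 (p = 1.53e-06, n = 30)
invasive tumors: 15/20 men (75%), 3/10 women (30%)
```

Reading it: the planted 140-gene signature (120 up / 20 down) is recovered
exactly at full scale; the curated enrichment table ranks chromosome 19
furthest above the median Δ; the planted 19p gain is confined to aggressive
males and the chromosome-11 loss appears in all but one aggressive tumor,
while the curated 13-tumor table gives the published 3 and 5/6 counts; the
CTAG2 correlation panel is strong only in men; and the cohort table
reproduces the 75%/30% invasiveness split from the grade margins.

The same computations are available programmatically, e.g.:

```r
library(lactodim)
ranked <- rank_by_median_distance(curated_chrom_delta())
attr(ranked, "median_delta")   # 0.53
head(ranked, 1)                # chr19, delta 0.80

ct <- curated_cna_event_table()
count_recurrence(ct$events, ct$samples,
                 function(s) s$sex == "M" & s$grade %in% c("2b", "2b->3"),
                 "19", "p", "gain")$count   # 3
```

`run_pipeline(pipeline_config(seed = 1), "out")` runs every stage in one
call and writes a JSON run report with all thresholds and headline counts.

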