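#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 30-tumor cohort under the default study
# conditions (20 men / 10 women, 55,000 probes with 100 negative controls,
# planted 140-gene sex signature, 19p gain in aggressive males, chr11 loss
# in all-but-one aggressive tumor) and write the four pipeline inputs.
suppressPackageStartupMessages(library(lactodim))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1
out <- "results/data"

cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg, out)

cat("cohort:", nrow(ds$cohort), "tumors —",
    sum(ds$cohort$sex == "M"), "men,", sum(ds$cohort$sex == "F"), "women\n")
print(table(ds$cohort$sex, ds$cohort$grade))
cat("expression:", nrow(ds$expression$intensities), "probes x",
    ncol(ds$expression$intensities), "samples;",
    length(ds$expression$negative_control_probes), "negative controls\n")
cat("annotation:", nrow(ds$annotation), "genes;  copy-number probes:",
    nrow(ds$copynumber$probes), "\n")
cat("inputs written under", out, "\n")
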