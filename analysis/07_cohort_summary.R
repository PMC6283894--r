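#!/usr/bin/env Rscript
# Stage 7: per-sex clinical summary of the cohort (mean +/- SE for
# continuous variables, counts and integer percentages for categorical
# ones) and a compact JSON run summary.
suppressPackageStartupMessages(library(lactodim))

samples <- read_sample_sheet("results/data/sample_sheet.tsv")
tab <- cohort_table(samples)
print(tab)
inv <- tab$categorical[tab$categorical$variable == "invasive", ]
cat(sprintf("invasive tumors: %d/%d men (%d%%), %d/%d women (%d%%)\n",
            inv$count[inv$sex == "M"], inv$denominator[inv$sex == "M"],
            inv$percent[inv$sex == "M"],
            inv$count[inv$sex == "F"], inv$denominator[inv$sex == "F"],
            inv$percent[inv$sex == "F"]))
utils::write.table(tab$continuous, "results/cohort_continuous.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tab$categorical, "results/cohort_categorical.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/cohort_continuous.tsv and cohort_categorical.tsv\n")
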