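#!/usr/bin/env Rscript
# Stage 3: men-vs-women differential expression. A gene is deregulated
# when the pooled-variance t-test gives p <= 0.05 and the signed fold
# change reaches 2-fold; probes are collapsed to genes by the mean of
# their log2 intensities.
suppressPackageStartupMessages(library(lactodim))

dat <- "results/data"
em <- read_expression(file.path(dat, "expression.tsv"))
pm <- utils::read.delim(file.path(dat, "probe_map.tsv"))
em <- attach_probe_map(em, stats::setNames(pm$symbol, pm$probe_id))
samples <- read_sample_sheet(file.path(dat, "sample_sheet.tsv"))

nm <- median_normalize(em)
de <- select_deregulated(log2_transform(nm), samples,
                         detection = detection_call(nm))
cnt <- attr(de, "counts")
cat(sprintf("deregulated genes: %d (%d up in men, %d down) of %d tested\n",
            cnt[["deregulated"]], cnt[["up"]], cnt[["down"]], nrow(de)))
top <- de[de$deregulated, ]
top <- top[order(-abs(top$fold_change)), ]
cat("strongest fold changes:\n")
print(utils::head(top[, c("symbol", "fold_change", "p_value", "direction")], 8),
      row.names = FALSE, digits = 4)
utils::write.table(as.data.frame(de), "results/de_results.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/de_results.tsv\n")
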