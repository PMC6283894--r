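#!/usr/bin/env Rscript
# Stage 4: per-chromosome enrichment of the deregulated genes. For each
# chromosome, delta = 100 * (share of deregulated genes - share of all
# annotated genes); chromosomes are ranked by distance of delta from the
# median. The same ranking is applied to the curated published table.
suppressPackageStartupMessages(library(lactodim))

de <- utils::read.delim("results/de_results.tsv")
ann <- read_annotation("results/data/annotation.tsv")

enr <- rank_by_median_distance(
  delta_statistic(de$symbol[de$deregulated], ann, "autosomes"))
cat(sprintf("synthetic cohort: median delta %.2f%%, top chromosome chr%s at %.2f%%\n",
            attr(enr, "median_delta"), enr$chromosome[1], enr$delta_percent[1]))
enr$delta_percent <- round(enr$delta_percent, 2)
enr$distance_from_median <- round(enr$distance_from_median, 2)
utils::write.table(enr, "results/chrom_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cur <- rank_by_median_distance(curated_chrom_delta())
cat(sprintf("published cohort table: median delta %.2f%%; furthest from it: chr%s (%.2f), chr%s (%.2f), chr%s (%.2f), chr%s (%.2f)\n",
            attr(cur, "median_delta"),
            cur$chromosome[1], cur$delta_percent[1],
            cur$chromosome[2], cur$delta_percent[2],
            cur$chromosome[3], cur$delta_percent[3],
            cur$chromosome[4], cur$delta_percent[4]))
cat("wrote results/chrom_enrichment.tsv\n")
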