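#!/usr/bin/env Rscript
# Stage 6: intersect upregulated genes with recurrently gained regions of
# the aggressive-male subgroup; sex-stratified correlation panels; ESR1
# vs ER-alpha IR correlation; category cross-tabulation of candidates.
suppressPackageStartupMessages(library(lactodim))

dat <- "results/data"
em <- read_expression(file.path(dat, "expression.tsv"))
pm <- utils::read.delim(file.path(dat, "probe_map.tsv"))
em <- attach_probe_map(em, stats::setNames(pm$symbol, pm$probe_id))
samples <- read_sample_sheet(file.path(dat, "sample_sheet.tsv"))
ann <- read_annotation(file.path(dat, "annotation.tsv"))
de <- utils::read.delim("results/de_results.tsv")
segs <- utils::read.delim("results/segment_calls.tsv",
                          colClasses = c(chromosome = "character"))
lg <- log2_transform(median_normalize(em))

agg_m <- function(s) s$sex == "M" & s$grade %in% c("2b", "2b->3")
cand <- gained_region_candidates(de, segs, ann, samples, agg_m)
cat("gained-and-upregulated candidates (aggressive males):\n")
print(cand[, c("symbol", "chromosome", "arm", "fold_change", "n_supporting")],
      row.names = FALSE, digits = 4)
utils::write.table(cand, "results/integration_candidates.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

panel <- c("ADAMTS6", "AURKB", "CCNB1", "CENPE", "PTTG1")
men <- pearson_panel(lg, samples, "CTAG2", panel,
                     group = function(s) s$sex == "M")
women <- pearson_panel(lg, samples, "CTAG2", panel,
                       group = function(s) s$sex == "F")
cat(sprintf("CTAG2 aggressiveness panel: mean r %.2f in men, %.2f in women\n",
            mean(men$pearson_r), mean(women$pearson_r)))
utils::write.table(rbind(cbind(group = "M", men), cbind(group = "F", women)),
                   "results/correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

coll <- collapse_probes(lg)
esr1 <- era_esr1_correlation(
  samples$era_ir_score[match(colnames(coll$values), samples$sample_id)],
  coll$values["ESR1", ])
cat(sprintf("ESR1 mRNA vs ER-alpha IR score: r = %.3f (p = %.2e, n = %d)\n",
            esr1$r, esr1$p_value, esr1$n))

maps <- curated_category_maps()
cross <- category_crosstab(curated_gene_categories()[, 1:4],
                           maps$oncology, maps$pituitary)
cat(sprintf("curated candidate table: %d/%d genes in the oncology x pituitary cross subset\n",
            sum(cross$in_cross_subset), nrow(cross)))
utils::write.table(cross, "results/category_crosstab.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/integration_candidates.tsv, correlations.tsv, category_crosstab.tsv\n")
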