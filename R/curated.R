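# Curated results tables from the published 30-tumor lactotroph cohort,
# shipped as plain-text transcriptions (not computed by this package) so
# that the printed-table arithmetic can be recomputed from them.

#' Per-tumor chromosome gain/loss events of the 13-tumor CGH subcohort
#'
#' Transcription of the published per-tumor event lists: sample, sex,
#' grade, clinical behavior tags, and semicolon-separated gain/loss tokens
#' (`"19p"`, `"11"`, ...). Use [curated_cna_event_table()] for the parsed
#' event rows.
#'
#' @return data.frame with columns sample_id, sex, grade,
#'   clinical_behavior, gains, losses.
#' @export
curated_cna_cohort <- function() {
  path <- system.file("extdata", "cohort_cna_events.tsv", package = "lactodim",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character())
  df$gains[is.na(df$gains)] <- ""
  df$losses[is.na(df$losses)] <- ""
  df
}

#' Parsed event table of the 13-tumor CGH subcohort
#'
#' @return list with `samples` (a validated sample sheet for the 13 tumors;
#'   invasiveness derived from grade) and `events` (event rows suitable for
#'   [count_recurrence()]).
#' @export
curated_cna_event_table <- function() {
  df <- curated_cna_cohort()
  samples <- data.frame(sample_id = df$sample_id, sex = df$sex,
                        grade = df$grade,
                        invasive = df$grade %in% c("2a", "2b", "2b->3"),
                        era_ir_score = NA_integer_,
                        tumor_size_mm = NA_real_,
                        clinical_behavior = df$clinical_behavior,
                        stringsAsFactors = FALSE)
  samples <- validate_sample_sheet(samples)
  events <- list()
  for (i in seq_len(nrow(df))) {
    events[[length(events) + 1]] <-
      parse_event_tokens(df$sample_id[i],
                         strsplit(df$gains[i], ";")[[1]], "gain")
    events[[length(events) + 1]] <-
      parse_event_tokens(df$sample_id[i],
                         strsplit(df$losses[i], ";")[[1]], "loss")
  }
  list(samples = samples, events = do.call(rbind, events))
}

#' Published per-chromosome enrichment of deregulated genes
#'
#' Transcription of the printed 22-autosome table: deregulated-gene counts
#' and delta percentages (chromosome share of deregulated genes minus
#' share of all genes, in percentage points).
#'
#' @return data.frame: chromosome, n_deregulated, delta_percent.
#' @export
curated_chrom_delta <- function() {
  path <- system.file("extdata", "chrom_delta_observed.tsv",
                      package = "lactodim", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$chromosome <- normalize_chrom(df$chromosome)
  df
}

#' Published candidate-gene table with functional category marks
#'
#' Transcription of the 32-gene cross-list table: signed expression fold
#' change, p-value, chromosome, and 0/1 membership marks for six oncology
#' categories and four pituitary-function categories.
#'
#' @return data.frame; mark columns are 0/1 integers.
#' @export
curated_gene_categories <- function() {
  path <- system.file("extdata", "candidate_gene_categories.tsv",
                      package = "lactodim", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Long-format category maps from the curated candidate table
#'
#' @return list with `oncology` and `pituitary` data.frames (symbol,
#'   category) as consumed by [category_crosstab()].
#' @export
curated_category_maps <- function() {
  df <- curated_gene_categories()
  onc_cols <- c("angiogenesis", "cell_growth_and_proliferation",
                "cell_death_and_survival", "cell_morphology",
                "cellular_movement", "development")
  pit_cols <- c("endocrine_system", "estrogen_signaling",
                "pituitary_tumors", "sexual_dimorphism")
  to_long <- function(cols) {
    do.call(rbind, lapply(cols, function(cl) {
      hit <- df$symbol[df[[cl]] == 1]
      if (!length(hit)) return(NULL)
      data.frame(symbol = hit, category = cl, stringsAsFactors = FALSE)
    }))
  }
  list(oncology = to_long(onc_cols), pituitary = to_long(pit_cols))
}
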