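#' Default pipeline configuration
#'
#' Thresholds default to the study's values: detection k_sd 2, alpha 0.05,
#' 2-fold minimum change, gain above 2.7 copies, loss below 1.3 copies.
#'
#' @param seed master seed for the synthetic stage.
#' @param sim `sim_config` (or list of overrides for [sim_config()]).
#' @param k_sd detection-threshold multiplier.
#' @param alpha differential-expression p cutoff.
#' @param fc_min minimum fold-change magnitude.
#' @param gain_cutoff,loss_cutoff copy-number call cutoffs at baseline 2.
#' @param penalty segmentation penalty (NULL = per-profile default).
#' @param min_seg_size minimum probes per segment.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = NULL, k_sd = 2, alpha = 0.05,
                            fc_min = 2, gain_cutoff = 2.7, loss_cutoff = 1.3,
                            penalty = NULL, min_seg_size = 3) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  structure(list(seed = seed, sim = sim, k_sd = k_sd, alpha = alpha,
                 fc_min = fc_min, gain_cutoff = gain_cutoff,
                 loss_cutoff = loss_cutoff, penalty = penalty,
                 min_seg_size = min_seg_size),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys are [pipeline_config()] arguments; the `sim` key holds
#' [sim_config()] arguments.
#'
#' @param path YAML (.yml/.yaml) or JSON path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  do.call(pipeline_config, cfg)
}

stage_log <- function(stage, quiet) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulate -> normalize -> detect -> log2 -> differential expression ->
#' chromosome enrichment -> copy-number segmentation and calling ->
#' recurrence -> gained-region integration -> correlation panels -> cohort
#' summary. Every intermediate table is written under `out_dir`, plus a
#' JSON run report recording the seed, thresholds and headline counts. Any
#' stage failure aborts with the stage name.
#'
#' @param config `pipeline_config` (or path understood by
#'   [read_pipeline_config()]).
#' @param out_dir output directory.
#' @param quiet suppress stage logging to stderr.
#' @return invisible list with all stage results and the report.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("lactodim")),
                 seed = config$seed,
                 thresholds = list(k_sd = config$k_sd, alpha = config$alpha,
                                   fc_min = config$fc_min,
                                   gain_cutoff = config$gain_cutoff,
                                   loss_cutoff = config$loss_cutoff,
                                   min_seg_size = config$min_seg_size,
                                   probe_collapse = "mean of log2 intensities",
                                   fold_change = "geometric (log2 means)"))
  run_stage <- function(stage, expr) {
    stage_log(stage, quiet)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  data <- run_stage("simulate", simulate_dataset(config$sim, out_dir))
  report$simulate <- list(n_samples = nrow(data$cohort),
                          n_male = sum(data$cohort$sex == "M"),
                          n_female = sum(data$cohort$sex == "F"),
                          n_probes = nrow(data$expression$intensities),
                          n_controls = length(data$expression$negative_control_probes),
                          n_genes = nrow(data$annotation))

  norm <- run_stage("normalize", median_normalize(data$expression))
  det <- run_stage("detect", detection_call(norm, k_sd = config$k_sd))
  lg <- run_stage("log2", log2_transform(norm))
  write_expression(norm, file.path(out_dir, "expression_normalized.tsv"))
  utils::write.table(
    data.frame(probe_id = rownames(det$present), det$present + 0,
               check.names = FALSE),
    file.path(out_dir, "detection.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report$normalize <- list(median_check = max(abs(
    apply(norm$intensities, 2, stats::median) - 1)))
  report$detect <- list(k_sd = config$k_sd,
                        fraction_present = mean(det$present))

  de <- run_stage("de", select_deregulated(lg, data$cohort,
                                           alpha = config$alpha,
                                           fc_min = config$fc_min,
                                           detection = det))
  utils::write.table(as.data.frame(de), file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- attr(de, "counts")
  report$de <- as.list(cnt)

  dereg <- de$symbol[de$deregulated]
  enr <- run_stage("chrom-enrich", {
    if (!length(dereg)) stop("no deregulated genes")
    rank_by_median_distance(
      delta_statistic(dereg, data$annotation, "autosomes"))
  })
  enr_out <- enr
  enr_out$delta_percent <- round(enr_out$delta_percent, 2)
  utils::write.table(enr_out, file.path(out_dir, "chrom_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$chrom_enrich <- list(median_delta = attr(enr, "median_delta"),
                              top_chromosome = enr$chromosome[1],
                              top_delta = enr$delta_percent[1])

  segs <- run_stage("cna-segment", {
    s <- segment_profiles(data$copynumber, data$cohort,
                          penalty = config$penalty,
                          min_size = config$min_seg_size)
    call_segments(s, config$gain_cutoff, config$loss_cutoff)
  })
  write_seg(segs, file.path(out_dir, "segments.seg"))
  utils::write.table(segs, file.path(out_dir, "segment_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  events <- segments_to_events(segs)
  groups <- list(aggressive_male = function(s) s$sex == "M" &
                   s$grade %in% c("2b", "2b->3"),
                 aggressive = function(s) s$grade %in% c("2b", "2b->3"),
                 male = function(s) s$sex == "M",
                 female = function(s) s$sex == "F")
  rec <- recurrence_by_group(events, data$cohort, groups, level = "arm")
  utils::write.table(rec, file.path(out_dir, "recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gain19p <- count_recurrence(events, data$cohort, groups$aggressive_male,
                              "19", "p", "gain")
  loss11 <- count_recurrence(events, data$cohort, groups$aggressive,
                             "11", NULL, "loss")
  report$cna <- list(n_segments = nrow(segs),
                     n_gain = sum(segs$call == "gain"),
                     n_loss = sum(segs$call == "loss"),
                     gain_19p_aggressive_male = gain19p$count,
                     loss_chr11_aggressive = loss11$count)

  cand <- run_stage("integrate", gained_region_candidates(
    de, segs, data$annotation, data$cohort,
    subgroup = groups$aggressive_male, alpha = config$alpha,
    fc_min = config$fc_min))
  utils::write.table(cand, file.path(out_dir, "integration_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$integrate <- list(n_candidates = nrow(cand),
                           candidates = cand$symbol)

  corr <- run_stage("correlate", {
    pcs <- config$sim$planted_correlations
    do.call(rbind, lapply(pcs, function(pc) {
      rbind(
        cbind(group = "M", pearson_panel(lg, data$cohort, pc$anchor, pc$panel,
                                         group = function(s) s$sex == "M")),
        cbind(group = "F", pearson_panel(lg, data$cohort, pc$anchor, pc$panel,
                                         group = function(s) s$sex == "F")))
    }))
  })
  utils::write.table(corr, file.path(out_dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  esr1 <- run_stage("correlate-esr1", {
    coll <- collapse_probes(lg)
    if ("ESR1" %in% rownames(coll$values)) {
      era_esr1_correlation(
        data$cohort$era_ir_score[match(colnames(coll$values),
                                       data$cohort$sample_id)],
        coll$values["ESR1", ])
    } else NULL
  })
  report$correlate <- list(esr1_ir_r = esr1$r %||% NA_real_)

  summ <- run_stage("summarize", cohort_table(data$cohort))
  utils::write.table(summ$continuous,
                     file.path(out_dir, "cohort_continuous.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$categorical,
                     file.path(out_dir, "cohort_categorical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$summarize <- list(
    men_invasive_percent = summ$categorical$percent[
      summ$categorical$variable == "invasive" & summ$categorical$sex == "M"],
    women_invasive_percent = summ$categorical$percent[
      summ$categorical$variable == "invasive" & summ$categorical$sex == "F"])

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = data, normalized = norm, detection = det,
                 log2 = lg, de = de, enrichment = enr, segments = segs,
                 events = events, recurrence = rec, candidates = cand,
                 correlations = corr, esr1 = esr1, summary = summ,
                 report = report))
}
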