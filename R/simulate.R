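#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults encode
#' the 30-tumor study conditions: 20 men vs 10 women; 55,000 probes with
#' 100 negative controls; grade margins of 6/1/1/2 (women) and 4/1/8/7
#' (men) across 1a/1b/2a/2b, with 2 of the 7 male grade-2b tumors
#' progressing to grade 3 after metastasis; mean ER-alpha immunoreactivity
#' scores near 7 (women) and 3 (men); 140 planted sex-differential genes
#' (120 up in men at log2FC +2 including four on 19p, seven on X and
#' eleven on Y; 20 down at -2); homoscedastic log2 noise SD 0.25; a 19p
#' gain (3.2 copies) confined to aggressive males and a chromosome-11 loss
#' (1.0 copies) in all but one aggressive sample; a male-restricted
#' correlation panel around CTAG2 (target r 0.8) and an ESR1 ~ ER-alpha IR
#' coupling (target r 0.8).
#'
#' @param seed master RNG seed.
#' @param n_male,n_female group sizes.
#' @param n_probes,n_controls probe counts (controls included in
#'   `n_probes`).
#' @param gene_counts named per-chromosome gene counts for the annotation.
#' @param planted_de data.frame symbol, chromosome, arm, log2fc; NULL for
#'   the default 140-gene panel, or an empty data.frame for a null cohort.
#' @param noise_sd_log2 expression noise SD on the log2 scale.
#' @param baseline_intensity_log2 mean gene-probe baseline (log2).
#' @param baseline_sd_log2 SD of per-gene baselines (log2).
#' @param control_offset_sd how many baseline SDs below the gene baseline
#'   the negative-control intensities sit (default 3).
#' @param planted_segments list of lists(group=, chromosome=, arm=, copies=);
#'   `group` is a predicate name (see Details) or function.
#' @param cna_noise_sd copy-number probe noise SD.
#' @param cna_probes_per_chrom copy-number probes per chromosome.
#' @param planted_correlations list of lists(anchor=, panel=, r=, group=).
#' @param esr1_ir_r target Pearson r between ESR1 log2 expression and the
#'   ER-alpha IR score (NA to disable).
#'
#' @details Named group predicates: `"aggressive_male"` (grade 2b/2b->3
#'   men), `"aggressive"` (grade 2b/2b->3), `"aggressive_but_one"`
#'   (aggressive samples minus the last one, emulating recurrence in most
#'   but not all), `"male"`, `"female"`, `"all"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_male = 20, n_female = 10,
                       n_probes = 55000, n_controls = 100,
                       gene_counts = default_gene_counts(),
                       planted_de = NULL,
                       noise_sd_log2 = 0.25,
                       baseline_intensity_log2 = 6,
                       baseline_sd_log2 = 1,
                       control_offset_sd = 3,
                       planted_segments = NULL,
                       cna_noise_sd = 0.3,
                       cna_probes_per_chrom = 80,
                       planted_correlations = NULL,
                       esr1_ir_r = 0.8) {
  if (n_controls >= n_probes) stop("n_controls must be below n_probes")
  if (is.null(planted_de)) planted_de <- default_planted_de()
  if (is.null(planted_segments)) {
    planted_segments <- list(
      list(group = "aggressive_male", chromosome = "19", arm = "p", copies = 3.2),
      list(group = "aggressive_but_one", chromosome = "11", arm = NULL, copies = 1.0)
    )
  }
  if (is.null(planted_correlations)) {
    planted_correlations <- list(
      list(anchor = "CTAG2",
           panel = c("ADAMTS6", "AURKB", "CCNB1", "CENPE", "PTTG1"),
           r = 0.8, group = "male")
    )
  }
  for (pc in planted_correlations) {
    if (abs(pc$r) > 1) stop("target correlation magnitude above 1")
  }
  structure(list(seed = seed, n_male = n_male, n_female = n_female,
                 n_probes = n_probes, n_controls = n_controls,
                 gene_counts = gene_counts, planted_de = planted_de,
                 noise_sd_log2 = noise_sd_log2,
                 baseline_intensity_log2 = baseline_intensity_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 control_offset_sd = control_offset_sd,
                 planted_segments = planted_segments,
                 cna_noise_sd = cna_noise_sd,
                 cna_probes_per_chrom = cna_probes_per_chrom,
                 planted_correlations = planted_correlations,
                 esr1_ir_r = esr1_ir_r),
            class = "sim_config")
}

#' Default panel of planted sex-differential genes
#'
#' 140 genes: four 19p candidates (CRB3, FAM138F, MATK, STAP2) at log2FC
#' +2; eleven Y-linked genes at +3 (male-specific expression); seven
#' X-linked genes at +2 (CTAG2 and its aggressiveness panel among the
#' autosomal entries); 98 further upregulated autosomal genes at +2 and 20
#' downregulated at -2, spread over the autosomes (chromosome 19p is
#' avoided by the spread so the gained-region intersection is exactly the
#' planted 19p panel).
#'
#' @return data.frame: symbol, chromosome, arm, log2fc.
#' @export
default_planted_de <- function() {
  named <- rbind(
    data.frame(symbol = c("CRB3", "FAM138F", "MATK", "STAP2"),
               chromosome = "19", arm = "p", log2fc = 2),
    data.frame(symbol = c("DDX3Y", "EIF1AY", "KDM5D", "NLGN4Y", "PRKY",
                          "RPS4Y1", "RPS4Y2", "TTTY14", "TXLNGY", "USP9Y",
                          "ZFY"),
               chromosome = "Y", arm = "q", log2fc = 3),
    data.frame(symbol = c("FGF13", "VEGFD", "CTAG2", "SLC6A8", "DDX3P1",
                          "FRMPD4", "TMEM35A"),
               chromosome = "X", arm = "q", log2fc = 2),
    data.frame(symbol = c("ADAMTS6", "AURKB", "CCNB1", "CENPE", "PTTG1"),
               chromosome = c("5", "17", "5", "4", "5"),
               arm = "q", log2fc = 2),
    data.frame(symbol = "ESR1", chromosome = "6", arm = "q", log2fc = 0)
  )
  # spread the remaining up/down genes over autosomal q arms in proportion
  # to chromosome gene content (no chromosomal preference beyond size); the
  # q-arm restriction keeps 19p clear so the gained-region intersection is
  # exactly the named panel
  alloc <- function(n) {
    w <- default_gene_counts()[AUTOSOMES]
    rep(AUTOSOMES, diff(c(0, round(cumsum(w) / sum(w) * n))))
  }
  n_up_left <- 120 - sum(named$log2fc > 0)
  up <- data.frame(symbol = sprintf("SIMUP%03d", seq_len(n_up_left)),
                   chromosome = alloc(n_up_left), arm = "q", log2fc = 2)
  down <- data.frame(symbol = sprintf("SIMDN%03d", 1:20),
                     chromosome = alloc(20), arm = "q", log2fc = -2)
  out <- rbind(named, up, down)
  rownames(out) <- NULL
  out
}

# resolve a named group predicate into a logical vector over the cohort
resolve_group <- function(group, samples) {
  if (is.function(group)) return(group(samples))
  if (is.logical(group)) return(group)
  aggressive <- samples$grade %in% c("2b", "2b->3")
  switch(group,
    all = rep(TRUE, nrow(samples)),
    male = samples$sex == "M",
    female = samples$sex == "F",
    aggressive = aggressive,
    aggressive_male = aggressive & samples$sex == "M",
    aggressive_but_one = {
      v <- aggressive
      idx <- which(v)
      if (length(idx)) v[idx[length(idx)]] <- FALSE
      v
    },
    stop("unknown group predicate: ", group)
  )
}

#' Simulate the clinical cohort
#'
#' Clinical margins (grade distribution, tumor-size bins, metastasis tags)
#' are assigned exactly at their configured counts -- the seed only permutes
#' which sample gets which value and drives the continuous draws.
#' Invasiveness derives from grade (2a and above are invasive by the
#' grading's definition), which reproduces the cohort's printed invasive
#' counts (15/20 men, 3/10 women) from the grade margins. ER-alpha IR
#' scores are drawn lower in men (mean 3) than women (mean 7); aggressive
#' women get very low scores, emulating the ER-alpha-negative aggressive
#' female tumors.
#'
#' @param config `sim_config`.
#' @return `sample_sheet` data.frame with extra columns age, mitotic_count,
#'   ki67_pct, p53_pct.
#' @export
simulate_cohort <- function(config) {
  if (config$n_male < 1 || config$n_female < 1) {
    stop("need at least one sample of each sex")
  }
  with_seed(derive_seed(config$seed, 101), {
    build_sex <- function(n, grade_margin, size_bins, ir_mean, age_mean, sex) {
      grades <- rep(names(grade_margin), grade_margin)
      grades <- c(grades, rep("1a", max(0, n - length(grades))))[1:n]
      grades <- sample(grades)
      # metastasis: for men, 2 of the grade-2b tumors progress to grade 3
      behavior <- rep("", n)
      if (sex == "M") {
        b2 <- which(grades == "2b")
        if (length(b2) >= 2) {
          prog <- b2[1:2]
          grades[prog] <- "2b->3"
          behavior[prog] <- "recurrence;metastasis;death"
        }
      }
      behavior[grades == "2b"] <- "recurrence"
      sizes <- numeric(n)
      bins <- rep(names(size_bins), size_bins)
      bins <- c(bins, rep("mid", max(0, n - length(bins))))[1:n]
      bins <- sample(bins)
      sizes[bins == "micro"] <- round(stats::runif(sum(bins == "micro"), 5, 9))
      sizes[bins == "mid"] <- round(stats::runif(sum(bins == "mid"), 11, 38))
      sizes[bins == "macro"] <- round(stats::runif(sum(bins == "macro"), 42, 70))
      ir <- pmin(12, pmax(0, round(stats::rnorm(n, ir_mean, 2))))
      ir[grades %in% c("2b", "2b->3")] <-
        pmin(ir[grades %in% c("2b", "2b->3")], 1)  # aggressive tumors: low ER-alpha
      data.frame(
        sample_id = NA_character_, sex = sex, grade = grades,
        invasive = grades %in% c("2a", "2b", "2b->3"),
        era_ir_score = as.integer(ir),
        tumor_size_mm = sizes,
        clinical_behavior = behavior,
        age = round(stats::rnorm(n, age_mean, 8)),
        mitotic_count = pmax(0, round(stats::rnorm(
          n, ifelse(grades %in% c("2b", "2b->3"), 6, 1), 2))),
        ki67_pct = round(pmax(0.1, stats::rnorm(
          n, ifelse(grades %in% c("2b", "2b->3"), 3, 0.8), 0.8)), 1),
        p53_pct = round(pmax(0, stats::rnorm(n, 0.5, 0.3)), 1),
        stringsAsFactors = FALSE)
    }
    women <- build_sex(config$n_female,
                       c("1a" = 6, "1b" = 1, "2a" = 1, "2b" = 2),
                       c(micro = 3, mid = 7, macro = 0),
                       ir_mean = 7, age_mean = 35, sex = "F")
    men <- build_sex(config$n_male,
                     c("1a" = 4, "1b" = 1, "2a" = 8, "2b" = 7),
                     c(micro = 1, mid = 13, macro = 6),
                     ir_mean = 3, age_mean = 51, sex = "M")
    out <- rbind(men, women)
    out$sample_id <- sprintf("T%02d", seq_len(nrow(out)))
    validate_sample_sheet(out)
  })
}

#' Simulate a gene annotation
#'
#' Places `gene_counts[chr]` genes per chromosome at evenly spaced
#' positions over the synthetic chromosome geometry, assigns p/q arms from
#' the centromere position, and substitutes planted symbols for the first
#' generated genes on their requested chromosome arm.
#'
#' @param config `sim_config`.
#' @return `gene_annotation` data.frame.
#' @export
simulate_annotation <- function(config) {
  geom <- chrom_geometry()
  rows <- list()
  for (chr in names(config$gene_counts)) {
    n <- config$gene_counts[[chr]]
    if (n < 1) next
    len <- geom$length_mb[geom$chromosome == chr] * 1e6
    starts <- floor(seq(1e5, len - 2e5, length.out = n))
    rows[[chr]] <- data.frame(
      symbol = sprintf("G%s_%04d", chr, seq_len(n)),
      chromosome = chr,
      arm = position_arm(rep(chr, n), starts, geom),
      start = as.integer(starts),
      end = as.integer(starts + 1e4),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  pd <- config$planted_de
  for (i in seq_len(nrow(pd))) {
    slot <- which(ann$chromosome == pd$chromosome[i] & ann$arm == pd$arm[i] &
                    startsWith(ann$symbol, "G"))
    if (!length(slot)) {
      stop("no annotation slot on ", pd$chromosome[i], pd$arm[i],
           " for planted gene ", pd$symbol[i])
    }
    ann$symbol[slot[1]] <- pd$symbol[i]
  }
  validate_annotation(ann)
}

# latent-factor coupling: value = lambda * z + e, with cor(value, z) = r
# in expectation when e ~ N(0, sigma) and lambda = sigma * r / sqrt(1-r^2)
latent_coupling <- function(z, r, sigma) {
  if (sigma == 0 || abs(r) >= 1) return(z * r)
  lambda <- sigma * r / sqrt(1 - r^2)
  lambda * z
}

# coupling for PAIRS of genes sharing the factor: with both genes built as
# b*z + e, cor(gene_a, gene_b) = b^2 / (b^2 + sigma^2) = r when
# b = sigma * sqrt(r / (1 - r)); r must be in [0, 1)
latent_coupling_pair <- function(z, r, sigma) {
  if (r < 0) stop("pairwise latent planting needs a non-negative target r")
  if (sigma == 0 || r >= 1) return(z * sqrt(r))
  b <- sigma * sqrt(r / (1 - r))
  b * z
}

#' Simulate a raw probe-level expression matrix
#'
#' Per-gene log2 baselines are normal around the configured baseline; the
#' planted sex effect splits +/- half the log2 fold change between men and
#' women (so the group log2-mean difference equals the planted value
#' exactly in the noise-free limit); homoscedastic Gaussian noise is added
#' in log2 space; negative controls are drawn `control_offset_sd` baseline
#' SDs below the gene baseline. Correlation structure is planted through a
#' shared latent factor per (anchor, panel, group), and ESR1 is coupled to
#' the cohort's ER-alpha IR scores at the configured target r.
#'
#' @param config `sim_config`.
#' @param cohort sample sheet from [simulate_cohort()].
#' @param annotation annotation from [simulate_annotation()].
#' @return raw `expr_matrix` with probe-to-gene map and controls.
#' @export
simulate_expression <- function(config, cohort, annotation) {
  if (!nrow(cohort)) stop("empty cohort")
  pd <- config$planted_de
  miss <- setdiff(pd$symbol, annotation$symbol)
  if (length(miss)) stop("planted symbol(s) absent from annotation: ",
                         paste(miss, collapse = ", "))
  with_seed(derive_seed(config$seed, 202), {
    n_s <- nrow(cohort)
    genes <- annotation$symbol
    n_g <- length(genes)
    base <- stats::rnorm(n_g, config$baseline_intensity_log2,
                         config$baseline_sd_log2)
    effect <- stats::setNames(rep(0, n_g), genes)
    effect[pd$symbol] <- pd$log2fc
    is_m <- cohort$sex == "M"
    half <- ifelse(is_m, 0.5, -0.5)
    sigma <- config$noise_sd_log2
    vals <- matrix(base, n_g, n_s) +
      outer(unname(effect), half) +
      matrix(stats::rnorm(n_g * n_s, 0, sigma), n_g, n_s)
    rownames(vals) <- genes
    colnames(vals) <- cohort$sample_id
    # planted correlation structure via shared latent factors
    for (pc in config$planted_correlations) {
      members <- resolve_group(pc$group, cohort)
      gset <- intersect(c(pc$anchor, pc$panel), genes)
      if (length(gset) < 2 || sum(members) < 3) next
      z <- stats::rnorm(sum(members))
      for (g in gset) {
        vals[g, members] <- vals[g, members] +
          latent_coupling_pair(z, pc$r, sigma)
      }
    }
    # ESR1 coupled to the ER-alpha IR score
    if (!is.na(config$esr1_ir_r) && "ESR1" %in% genes &&
        !all(is.na(cohort$era_ir_score))) {
      ir <- cohort$era_ir_score
      if (stats::sd(ir, na.rm = TRUE) > 0) {
        z <- (ir - mean(ir, na.rm = TRUE)) / stats::sd(ir, na.rm = TRUE)
        z[is.na(z)] <- 0
        vals["ESR1", ] <- vals["ESR1", ] +
          latent_coupling(z, config$esr1_ir_r, sigma)
      }
    }
    # spread genes over the gene-probe complement (round robin); probe
    # offsets are per-probe constants and cancel in group contrasts
    n_gene_probes <- config$n_probes - config$n_controls
    if (n_gene_probes < n_g) {
      # fewer probes than genes: keep the first n_gene_probes genes
      gene_idx <- seq_len(n_gene_probes)
    } else {
      gene_idx <- rep(seq_len(n_g), length.out = n_gene_probes)
    }
    probe_ids <- sprintf("P%06d", seq_len(n_gene_probes))
    probe_offset <- stats::rnorm(n_gene_probes, 0, 0.1)
    pv <- vals[gene_idx, , drop = FALSE] + probe_offset
    rownames(pv) <- probe_ids
    ctrl_ids <- sprintf("NEG_%03d", seq_len(config$n_controls))
    mu_ctrl <- config$baseline_intensity_log2 -
      config$control_offset_sd * config$baseline_sd_log2
    cv <- matrix(stats::rnorm(config$n_controls * n_s, mu_ctrl, sigma),
                 config$n_controls, n_s,
                 dimnames = list(ctrl_ids, cohort$sample_id))
    raw <- 2^rbind(pv, cv)
    expr_matrix(raw,
                probe_to_gene = stats::setNames(genes[gene_idx], probe_ids),
                negative_control_probes = ctrl_ids,
                scale = "raw")
  })
}

#' Simulate probe-level copy-number profiles
#'
#' Evenly spaced probes per chromosome at sex-appropriate baselines
#' (autosomes 2; male X/Y 1; female X 2, female Y excluded as NA) with
#' Gaussian noise; probes inside a planted segment for matching samples
#' sit at the planted copy level instead.
#'
#' @param config `sim_config`.
#' @param cohort sample sheet.
#' @return `copy_profiles`.
#' @export
simulate_cna_profiles <- function(config, cohort) {
  geom <- chrom_geometry()
  for (ps in config$planted_segments) {
    if (!(normalize_chrom(ps$chromosome) %in% CHROM_LEVELS)) {
      stop("planted segment on unknown chromosome ", ps$chromosome)
    }
    if (normalize_chrom(ps$chromosome) == "Y") {
      members <- resolve_group(ps$group, cohort)
      if (any(cohort$sex[members] == "F")) {
        stop("planted Y segment targets a female sample")
      }
    }
  }
  with_seed(derive_seed(config$seed, 303), {
    n_pp <- config$cna_probes_per_chrom
    probes <- do.call(rbind, lapply(CHROM_LEVELS, function(chr) {
      len <- geom$length_mb[geom$chromosome == chr] * 1e6
      data.frame(probe_id = sprintf("CN_%s_%03d", chr, seq_len(n_pp)),
                 chromosome = chr,
                 position = as.integer(floor(seq(1e5, len - 1e5,
                                                 length.out = n_pp))),
                 stringsAsFactors = FALSE)
    }))
    n_s <- nrow(cohort)
    copies <- matrix(NA_real_, nrow(probes), n_s,
                     dimnames = list(probes$probe_id, cohort$sample_id))
    arm <- position_arm(probes$chromosome, probes$position, geom)
    for (j in seq_len(n_s)) {
      base <- baseline_copies(probes$chromosome, cohort$sex[j])
      level <- base
      for (ps in config$planted_segments) {
        members <- resolve_group(ps$group, cohort)
        if (!members[j]) next
        hit <- probes$chromosome == normalize_chrom(ps$chromosome)
        if (!is.null(ps$arm)) hit <- hit & arm == ps$arm
        level[hit] <- ps$copies
      }
      noise <- stats::rnorm(nrow(probes), 0, config$cna_noise_sd)
      copies[, j] <- ifelse(is.na(level), NA, level + noise)
    }
    copy_profiles(probes, copies)
  })
}

#' Generate and write a full synthetic dataset
#'
#' Runs [simulate_cohort()], [simulate_annotation()],
#' [simulate_expression()] and [simulate_cna_profiles()] and writes the
#' four input TSVs (sample sheet, annotation, expression, copy number)
#' plus a probe-map TSV into `out_dir`.
#'
#' @param config `sim_config`.
#' @param out_dir output directory (created if absent).
#' @return invisible list of the in-memory objects.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  annotation <- simulate_annotation(config)
  em <- simulate_expression(config, cohort, annotation)
  cp <- simulate_cna_profiles(config, cohort)
  write_sample_sheet(cohort, file.path(out_dir, "sample_sheet.tsv"))
  utils::write.table(as.data.frame(annotation),
                     file.path(out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(em, file.path(out_dir, "expression.tsv"))
  utils::write.table(
    data.frame(probe_id = names(em$probe_to_gene),
               symbol = unname(em$probe_to_gene)),
    file.path(out_dir, "probe_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_copynumber(cp, file.path(out_dir, "copynumber.tsv"))
  invisible(list(cohort = cohort, annotation = annotation,
                 expression = em, copynumber = cp))
}
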