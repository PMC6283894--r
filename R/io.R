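#' Expression matrix container
#'
#' Lightweight container for probe-level array intensities: a numeric
#' probe x sample matrix together with the probe-to-gene map, the set of
#' negative-control probe ids, and the processing scale (`"raw"`,
#' `"normalized"` or `"log2"`).
#'
#' @param intensities numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param probe_to_gene named character vector mapping probe id -> gene
#'   symbol; probes without a gene (e.g. controls) are simply absent.
#' @param negative_control_probes character vector of control probe ids.
#' @param scale one of `"raw"`, `"normalized"`, `"log2"`.
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(intensities, probe_to_gene = character(),
                        negative_control_probes = character(),
                        scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix")
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(intensities))) {
    dup <- rownames(intensities)[duplicated(rownames(intensities))]
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (scale != "log2" && any(intensities < 0)) {
    stop("negative intensities on scale '", scale, "'")
  }
  if (length(negative_control_probes)) {
    miss <- setdiff(negative_control_probes, rownames(intensities))
    if (length(miss)) stop("control probes absent from matrix: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    if (length(intersect(negative_control_probes, names(probe_to_gene)))) {
      stop("negative-control probes must not map to genes")
    }
  }
  if (length(probe_to_gene)) {
    miss <- setdiff(names(probe_to_gene), rownames(intensities))
    if (length(miss)) stop("mapped probes absent from matrix: ",
                           paste(utils::head(miss, 5), collapse = ", "))
  }
  structure(
    list(intensities = intensities,
         probe_to_gene = probe_to_gene,
         negative_control_probes = unique(negative_control_probes),
         scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [scale=%s, %d controls, %d mapped probes]\n",
              nrow(x$intensities), ncol(x$intensities), x$scale,
              length(x$negative_control_probes), length(x$probe_to_gene)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$intensities)

#' Read a probe x sample expression TSV
#'
#' First column holds probe ids, header row holds sample ids, body is
#' numeric. Probes whose id starts with `control_prefix` become the
#' negative-control set. The probe-to-gene map, if any, is attached
#' separately (see [attach_probe_map()]).
#'
#' @param path TSV path.
#' @param control_prefix prefix identifying negative-control probes
#'   (default `"NEG_"`).
#' @return `expr_matrix` on the raw scale.
#' @export
read_expression <- function(path, control_prefix = "NEG_") {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3) stop("cohort error: need at least 2 sample columns")
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  body <- raw[, -1, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(probe_ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !(body[[j]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' at row %d (probe %s), column '%s'",
                   body[[j]][bad[1]], bad[1], probe_ids[bad[1]], colnames(body)[j]))
    }
    mat[, j] <- v
  }
  if (any(is.na(mat))) stop("parse error: missing intensity values")
  controls <- probe_ids[startsWith(probe_ids, control_prefix)]
  if (!length(controls)) {
    warning("no negative-control probes found with prefix '", control_prefix, "'")
  }
  expr_matrix(mat, negative_control_probes = controls, scale = "raw")
}

#' Attach a probe-to-gene map to an expression matrix
#'
#' @param em `expr_matrix`.
#' @param probe_to_gene named character vector (probe id -> gene symbol).
#' @return `expr_matrix` with the map attached.
#' @export
attach_probe_map <- function(em, probe_to_gene) {
  expr_matrix(em$intensities, probe_to_gene = probe_to_gene,
              negative_control_probes = em$negative_control_probes,
              scale = em$scale)
}

#' Write an expression matrix as TSV
#' @param em `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(probe_id = rownames(em$intensities),
                   em$intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Columns: `symbol`, `chromosome`, `arm`, `start`, `end` (1-based
#' inclusive). Chromosome tokens may carry a `"chr"` prefix; arms are
#' `"p"`/`"q"`.
#'
#' @param path TSV path.
#' @return data.frame of class `gene_annotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("symbol", "chromosome", "arm", "start", "end")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  validate_annotation(df[need])
}

#' Validate (and normalize) a gene annotation table
#' @param df data.frame with columns symbol, chromosome, arm, start, end.
#' @return the validated data.frame, class `gene_annotation`.
#' @export
validate_annotation <- function(df) {
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({normalize_chrom(df$chromosome[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("annotation line %d: unknown chromosome '%s'",
                          i, df$chromosome[i]))
    if (!(df$arm[i] %in% c("p", "q"))) {
      stop(sprintf("annotation line %d: arm must be 'p' or 'q', got '%s'",
                   i, df$arm[i]))
    }
    if (is.na(df$start[i]) || is.na(df$end[i]) || df$start[i] > df$end[i]) {
      stop(sprintf("annotation line %d: start > end for %s", i, df$symbol[i]))
    }
  }
  df$chromosome <- normalize_chrom(df$chromosome)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyDuplicated(df$symbol)) {
    stop("duplicate gene symbol(s): ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a clinical sample sheet TSV
#'
#' Columns: `sample_id`, `sex` (M/F), `grade` (1a, 1b, 2a, 2b, 2b->3),
#' `invasive` (TRUE/FALSE), `era_ir_score` (integer 0-12, empty = missing),
#' `tumor_size_mm` (positive, empty = missing), `clinical_behavior`
#' (free-text tags, semicolon-separated; grade 2b->3 requires a
#' "metastasis" tag). Extra columns (age, proliferation markers) pass
#' through untouched.
#'
#' @param path TSV path.
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("sample_id", "sex", "grade", "invasive")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (!("clinical_behavior" %in% colnames(df))) df$clinical_behavior <- NA_character_
  if (!("era_ir_score" %in% colnames(df))) df$era_ir_score <- NA_integer_
  if (!("tumor_size_mm" %in% colnames(df))) df$tumor_size_mm <- NA_real_
  df$invasive <- as.logical(df$invasive)
  validate_sample_sheet(df)
}

#' Validate a clinical sample sheet
#' @param df sample-sheet data.frame.
#' @return validated data.frame, class `sample_sheet`.
#' @export
validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    if (!(df$sex[i] %in% c("M", "F"))) {
      stop(sprintf("sample sheet line %d: sex must be M or F, got '%s'", i, df$sex[i]))
    }
    if (!(df$grade[i] %in% GRADE_LEVELS)) {
      stop(sprintf("sample sheet line %d: unknown grade token '%s'", i, df$grade[i]))
    }
    if (!is.na(df$era_ir_score[i]) &&
        (df$era_ir_score[i] < 0 || df$era_ir_score[i] > 12)) {
      stop(sprintf("sample sheet line %d: era_ir_score outside [0, 12]", i))
    }
    if (!is.na(df$tumor_size_mm[i]) && df$tumor_size_mm[i] <= 0) {
      stop(sprintf("sample sheet line %d: tumor_size_mm must be positive", i))
    }
    if (df$grade[i] == "2b->3" &&
        !grepl("metastasis", df$clinical_behavior[i] %||% "")) {
      tags <- df$clinical_behavior[i]
      if (is.na(tags) || !grepl("metastasis", tags)) {
        stop(sprintf("sample sheet line %d: grade 2b->3 requires a 'metastasis' tag", i))
      }
    }
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet TSV
#' @param samples sample-sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a probe-level copy-number TSV
#'
#' Columns: `probe_id`, `chromosome`, `position`, then one numeric column
#' per sample. Probes must be position-sorted within each chromosome.
#'
#' @param path TSV path.
#' @return `copy_profiles` object: list with `probes` (data.frame probe_id,
#'   chromosome, position) and `copies` (probe x sample matrix; NA marks
#'   excluded probes such as Y probes of female samples).
#' @export
read_copynumber <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("probe_id", "chromosome", "position")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("copy-number table missing column(s): ",
                         paste(miss, collapse = ", "))
  probes <- data.frame(probe_id = df$probe_id,
                       chromosome = normalize_chrom(df$chromosome),
                       position = as.integer(df$position),
                       stringsAsFactors = FALSE)
  copies <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  storage.mode(copies) <- "double"
  rownames(copies) <- probes$probe_id
  copy_profiles(probes, copies)
}

#' Copy-number profile container
#' @param probes data.frame with probe_id, chromosome, position.
#' @param copies probe x sample numeric matrix (rows match `probes`).
#' @return object of class `copy_profiles`.
#' @export
copy_profiles <- function(probes, copies) {
  if (nrow(probes) != nrow(copies)) stop("probe/copies row mismatch")
  # positions strictly increasing within each chromosome
  for (chr in unique(probes$chromosome)) {
    pos <- probes$position[probes$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("probes not strictly position-sorted on chromosome ", chr)
    }
  }
  structure(list(probes = probes, copies = copies), class = "copy_profiles")
}

#' Write probe-level copy numbers as TSV
#' @param cp `copy_profiles`.
#' @param path output path.
#' @export
write_copynumber <- function(cp, path) {
  df <- data.frame(cp$probes, cp$copies, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called segments in IGV SEG format
#'
#' Columns `Sample, Chromosome, Start, End, Num_Probes, Segment_Mean` with
#' `Segment_Mean = log2(mean_copies / baseline)` at 6 decimal places.
#' Refuses overlapping segments within one sample/chromosome.
#'
#' @param segments segment data.frame (see [segment_profiles()]); must carry
#'   a `baseline` column.
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  check_segment_overlap(segments)
  sm <- round(log2(segments$mean_copies / segments$baseline), 6)
  out <- data.frame(Sample = segments$sample_id,
                    Chromosome = segments$chromosome,
                    Start = segments$start,
                    End = segments$end,
                    Num_Probes = segments$n_probes,
                    Segment_Mean = sprintf("%.6f", sm))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_segment_overlap <- function(segments) {
  key <- paste(segments$sample_id, segments$chromosome)
  for (k in unique(key)) {
    s <- segments[key == k, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments for ", k, "; refusing to write")
    }
  }
  invisible(TRUE)
}

#' Read an IGV SEG file
#'
#' @param path SEG path.
#' @param samples optional sample sheet; when given, `mean_copies` is
#'   reconstructed as `baseline * 2^Segment_Mean` with the sex-appropriate
#'   baseline (autosomes 2; male X/Y 1; female X 2).
#' @return segment data.frame.
#' @export
read_seg <- function(path, samples = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(sample_id = df$Sample,
                    chromosome = normalize_chrom(df$Chromosome),
                    start = as.integer(df$Start),
                    end = as.integer(df$End),
                    n_probes = as.integer(df$Num_Probes),
                    segment_mean = as.numeric(df$Segment_Mean),
                    stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    sex <- samples$sex[match(out$sample_id, samples$sample_id)]
    out$baseline <- baseline_copies(out$chromosome, sex)
    out$mean_copies <- out$baseline * 2^out$segment_mean
  }
  out
}

#' Expected baseline copy number for a chromosome given sex
#'
#' Autosomes 2; male X and Y 1; female X 2; female Y has no baseline (NA).
#'
#' @param chromosome character vector of bare chromosome tokens.
#' @param sex character vector, "M"/"F".
#' @return numeric vector of baseline copies.
#' @export
baseline_copies <- function(chromosome, sex) {
  base <- rep(2, length(chromosome))
  base[chromosome %in% c("X", "Y") & sex == "M"] <- 1
  base[chromosome == "Y" & sex == "F"] <- NA_real_
  base
}
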