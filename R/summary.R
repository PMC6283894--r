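#' Per-sex cohort summary table
#'
#' Continuous variables are summarized as mean, standard error (SD/sqrt(n))
#' and median per sex; categorical variables as counts with integer
#' percentages of the sex group. Missing values are excluded from their own
#' variable's denominator only. A single observation leaves the SE missing.
#'
#' @param samples sample sheet (extra columns age, mitotic_count, ki67_pct,
#'   p53_pct are summarized when present).
#' @return list of class `cohort_summary` with `continuous` and
#'   `categorical` data.frames and `n` (per-sex sizes).
#' @export
cohort_table <- function(samples) {
  if (!nrow(samples)) stop("empty cohort")
  sexes <- c("F", "M")
  n_by <- vapply(sexes, function(s) sum(samples$sex == s), integer(1))
  cont_vars <- intersect(c("age", "tumor_size_mm", "era_ir_score",
                           "mitotic_count", "ki67_pct", "p53_pct"),
                         colnames(samples))
  cont <- do.call(rbind, lapply(cont_vars, function(v) {
    do.call(rbind, lapply(sexes, function(s) {
      x <- samples[[v]][samples$sex == s]
      x <- x[!is.na(x)]
      n <- length(x)
      data.frame(variable = v, sex = s, n = n,
                 mean = if (n) mean(x) else NA_real_,
                 se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
                 median = if (n) stats::median(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  size_bin <- function(x) {
    ifelse(is.na(x), NA,
           ifelse(x < 10, "<10mm", ifelse(x <= 40, "10-40mm", ">40mm")))
  }
  cat_rows <- list()
  add_cat <- function(variable, level, member) {
    for (s in sexes) {
      in_sex <- samples$sex == s
      denom <- sum(in_sex & !is.na(member))
      cnt <- sum(in_sex & member, na.rm = TRUE)
      cat_rows[[length(cat_rows) + 1]] <<- data.frame(
        variable = variable, level = level, sex = s,
        count = cnt, denominator = denom,
        percent = if (denom) round(100 * cnt / denom) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if ("tumor_size_mm" %in% colnames(samples)) {
    bins <- size_bin(samples$tumor_size_mm)
    for (b in c("<10mm", "10-40mm", ">40mm")) add_cat("size_bin", b, bins == b)
  }
  add_cat("invasive", "invasive", samples$invasive)
  for (g in GRADE_LEVELS) add_cat("grade", g, samples$grade == g)
  add_cat("metastasis", "metastasis",
          grepl("metastasis", samples$clinical_behavior %||% ""))
  out <- list(continuous = cont, categorical = do.call(rbind, cat_rows),
              n = n_by)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d women, %d men\n", x$n[["F"]], x$n[["M"]]))
  print(x$continuous, digits = 3)
  print(x$categorical)
  invisible(x)
}

#' Correlation between ER-alpha IR scores and ESR1 expression
#'
#' Pearson r and two-sided p (t transform) between per-sample
#' immunoreactivity scores and ESR1 log2 expression.
#'
#' @param ir_scores integer IR scores (0-12), one per sample.
#' @param esr1_log2 ESR1 log2 expression, same order.
#' @return list with `r`, `p_value`, `n`.
#' @export
era_esr1_correlation <- function(ir_scores, esr1_log2) {
  if (length(ir_scores) != length(esr1_log2)) {
    stop("ir_scores and esr1_log2 lengths differ")
  }
  if (sum(is.finite(ir_scores) & is.finite(esr1_log2)) < 3) {
    stop("need at least 3 paired observations")
  }
  r <- pearson_r_p(ir_scores, esr1_log2)
  list(r = r$r, p_value = r$p_value, n = r$n)
}
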