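#' Signed fold change from log2 group means
#'
#' With ratio `r = 2^(mean_a - mean_b)`, returns `r` when `r >= 1` and
#' `-1/r` otherwise, so magnitudes are symmetric about +/-1 and no value
#' falls in (-1, 1). A ratio of exactly 1 is reported as +1.
#'
#' @param mean_a_log2,mean_b_log2 finite log2 group means (vectorized).
#' @return signed fold change(s).
#' @export
signed_fold_change <- function(mean_a_log2, mean_b_log2) {
  r <- 2^(mean_a_log2 - mean_b_log2)
  ifelse(r >= 1, r, -1 / r)
}

#' Pooled-variance two-sample t-test (scalar)
#'
#' Two-sided Student's t-test with equal-variance pooling. When both groups
#' are constant and equal the statistic is undefined; p = 1 is returned with
#' a `degenerate` flag. Constant but unequal groups give p = 0.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
student_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  res <- row_t_test(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1),
                    welch = welch)
  list(t = res$t[1], df = res$df[1], p_value = res$p_value[1],
       degenerate = res$degenerate[1])
}

# Vectorized two-sample t across matrix rows (genes). Pooled variance by
# default (the classical Student's test); Welch behind a flag.
row_t_test <- function(a, b, welch = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  }
  diff <- ma - mb
  tt <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  # zero pooled variance: equal means -> no evidence (p = 1); unequal -> p = 0
  p[degen & diff == 0] <- 1
  tt[degen & diff == 0] <- 0
  p[degen & diff != 0] <- 0
  tt[degen & diff != 0] <- sign(diff[degen & diff != 0]) * Inf
  list(t = tt, df = df, p_value = p, degenerate = degen,
       mean_a = ma, mean_b = mb)
}

#' Collapse probe-level log2 intensities to genes
#'
#' Gene value per sample = mean of the gene's probes' log2 intensities.
#' Optionally returns per-gene presence (a gene is present in a sample if
#' any of its probes is present).
#'
#' @param em log2 `expr_matrix` with a probe-to-gene map.
#' @param detection optional `detection_result` at probe level.
#' @return list with `values` (gene x sample matrix) and `present`
#'   (gene x sample logical, or NULL).
#' @export
collapse_probes <- function(em, detection = NULL) {
  map <- em$probe_to_gene
  if (!length(map)) stop("expression matrix has no probe-to-gene map")
  probes <- names(map)
  genes <- unique(unname(map))
  f <- factor(unname(map), levels = genes)
  sub <- em$intensities[probes, , drop = FALSE]
  values <- rowsum(sub, f) / as.vector(table(f))
  present <- NULL
  if (!is.null(detection)) {
    pp <- detection$present[probes, , drop = FALSE]
    present <- rowsum(pp + 0, f) > 0
  }
  list(values = values, present = present)
}

#' Two-group differential expression with the signed fold-change filter
#'
#' Collapses probes to genes, contrasts the two sexes (group A = men,
#' group B = women by default), and calls a gene deregulated when the
#' Student's t-test p-value is <= `alpha` and the signed fold change has
#' magnitude >= `fc_min`. Genes absent in every sample (per the detection
#' result) are dropped before testing; partial absence does not exclude.
#' A Benjamini-Hochberg FDR column is included for reference but never
#' drives the filter.
#'
#' @param em log2 `expr_matrix` with probe-to-gene map.
#' @param samples sample sheet covering the matrix columns.
#' @param alpha p-value threshold (default 0.05).
#' @param fc_min minimum fold-change magnitude (default 2).
#' @param detection optional probe-level `detection_result`.
#' @param group_a,group_b levels of `sex` contrasted (defaults M vs F).
#' @param welch use Welch's t instead of pooled-variance Student's t.
#' @param linear_fc compute fold change from linear-scale group means
#'   instead of log2 means (geometric default).
#' @return data.frame of class `de_result` with one row per tested gene:
#'   symbol, mean_log2_a, mean_log2_b, fold_change, p_value, fdr,
#'   deregulated, direction; attribute `counts` holds (deregulated, up,
#'   down) totals.
#' @export
select_deregulated <- function(em, samples, alpha = 0.05, fc_min = 2,
                               detection = NULL, group_a = "M", group_b = "F",
                               welch = FALSE, linear_fc = FALSE) {
  if (em$scale != "log2") stop("differential expression requires log2 data")
  ids <- colnames(em$intensities)
  sex <- samples$sex[match(ids, samples$sample_id)]
  if (any(is.na(sex))) stop("samples missing from sheet: ",
                            paste(ids[is.na(sex)], collapse = ", "))
  ia <- which(sex == group_a); ib <- which(sex == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("contrast error: each sex group needs at least 2 samples")
  }
  coll <- collapse_probes(em, detection)
  g <- coll$values
  if (!is.null(coll$present)) {
    keep <- rowSums(coll$present) > 0
    g <- g[keep, , drop = FALSE]
  }
  if (!nrow(g)) stop("no genes present in any sample")
  tt <- row_t_test(g[, ia, drop = FALSE], g[, ib, drop = FALSE], welch = welch)
  if (linear_fc) {
    la <- rowMeans(2^g[, ia, drop = FALSE])
    lb <- rowMeans(2^g[, ib, drop = FALSE])
    fc <- signed_fold_change(log2(la), log2(lb))
  } else {
    fc <- signed_fold_change(tt$mean_a, tt$mean_b)
  }
  dereg <- tt$p_value <= alpha & abs(fc) >= fc_min
  direction <- rep("none", nrow(g))
  direction[dereg & fc >= fc_min] <- "up"
  direction[dereg & fc <= -fc_min] <- "down"
  out <- data.frame(symbol = rownames(g),
                    mean_log2_a = tt$mean_a,
                    mean_log2_b = tt$mean_b,
                    fold_change = fc,
                    p_value = tt$p_value,
                    fdr = stats::p.adjust(tt$p_value, method = "BH"),
                    deregulated = dereg,
                    direction = direction,
                    degenerate = tt$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(deregulated = sum(dereg),
                           up = sum(direction == "up"),
                           down = sum(direction == "down"))
  class(out) <- c("de_result", "data.frame")
  out
}

#' Re-test one gene on a filtered cohort
#'
#' Signed fold change and Student's t p-value for a single gene after
#' restricting the cohort with `include` (a logical vector over the sample
#' sheet, or a predicate function of it). Used for subgroup re-analyses
#' such as excluding the aggressive female tumors from the ESR1 contrast.
#'
#' @param em log2 `expr_matrix`.
#' @param samples sample sheet.
#' @param gene gene symbol.
#' @param include logical vector or predicate `function(samples) -> logical`.
#' @param group_a,group_b contrast levels (defaults M vs F).
#' @return list with `fold_change`, `p_value`, `n_a`, `n_b`.
#' @export
subgroup_contrast <- function(em, samples, gene, include = NULL,
                              group_a = "M", group_b = "F") {
  if (is.function(include)) include <- include(samples)
  if (is.null(include)) include <- rep(TRUE, nrow(samples))
  kept <- samples[include, , drop = FALSE]
  coll <- collapse_probes(em)
  if (!(gene %in% rownames(coll$values))) stop("unknown gene: ", gene)
  ids <- colnames(coll$values)
  keep_cols <- ids %in% kept$sample_id
  v <- coll$values[gene, keep_cols]
  sex <- kept$sex[match(ids[keep_cols], kept$sample_id)]
  a <- v[sex == group_a]; b <- v[sex == group_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("subgroup predicate leaves fewer than 2 samples in a group")
  }
  st <- student_t(a, b)
  list(fold_change = signed_fold_change(mean(a), mean(b)),
       p_value = st$p_value, n_a = length(a), n_b = length(b))
}
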