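#' Genes both upregulated and inside recurrently gained regions
#'
#' Intersects the upregulated gene list (fold change >= `fc_min`, p <=
#' `alpha`) with called gain segments of a sample subgroup: a gene is a
#' candidate when its annotated interval overlaps (1-based inclusive,
#' >= 1 bp) a gain segment in at least `min_samples` subgroup samples.
#' With `arm_fallback` a gain anywhere on the gene's chromosome arm also
#' counts (for coarse probe resolution); the matching mode is recorded in
#' the output.
#'
#' @param de `de_result` table.
#' @param segments called segment data.frame.
#' @param annotation `gene_annotation`.
#' @param samples sample sheet.
#' @param subgroup logical vector over `samples` or predicate function.
#' @param min_samples minimum supporting samples (default 1).
#' @param alpha,fc_min thresholds (defaults 0.05, 2).
#' @param arm_fallback match at arm level instead of interval level.
#' @return data.frame: symbol, chromosome, arm, fold_change, p_value,
#'   n_supporting, supporting (semicolon-joined sample ids), match_mode;
#'   sorted by decreasing fold change.
#' @export
gained_region_candidates <- function(de, segments, annotation, samples,
                                     subgroup, min_samples = 1,
                                     alpha = 0.05, fc_min = 2,
                                     arm_fallback = FALSE) {
  if (is.function(subgroup)) subgroup <- subgroup(samples)
  members <- samples$sample_id[subgroup]
  gains <- segments[segments$call == "gain" &
                      segments$sample_id %in% members, , drop = FALSE]
  up <- de[de$p_value <= alpha & de$fold_change >= fc_min, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(up))) {
    sym <- up$symbol[i]
    a <- annotation[annotation$symbol == sym, , drop = FALSE]
    if (!nrow(a)) {
      warning("no annotation for DE gene ", sym, "; skipped")
      next
    }
    if (arm_fallback) {
      arm_hit <- gains$chromosome == a$chromosome &
        (gains$arm_label == a$arm | gains$arm_label == "pq")
      supp <- unique(gains$sample_id[arm_hit])
      mode <- "arm"
    } else {
      hit <- gains$chromosome == a$chromosome &
        gains$start <= a$end & gains$end >= a$start
      supp <- unique(gains$sample_id[hit])
      mode <- "interval"
    }
    if (length(supp) < min_samples) next
    rows[[length(rows) + 1]] <- data.frame(
      symbol = sym, chromosome = a$chromosome, arm = a$arm,
      fold_change = up$fold_change[i], p_value = up$p_value[i],
      n_supporting = length(supp),
      supporting = paste(sort(supp), collapse = ";"),
      match_mode = mode, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(symbol = character(), chromosome = character(),
                      arm = character(), fold_change = numeric(),
                      p_value = numeric(), n_supporting = integer(),
                      supporting = character(), match_mode = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pearson r with a two-sided p-value from the exact t transform
# (t = r * sqrt((n-2)/(1-r^2)), n-2 df). Zero variance -> NA with flag.
pearson_r_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(r = r, p_value = p, n = n, degenerate = FALSE)
}

#' Group-stratified Pearson correlations of an anchor gene with a panel
#'
#' Pearson r and two-sided p (t transform, n-2 df) between `anchor` and
#' each panel gene, restricted to the samples selected by `group`.
#' A zero-variance gene within the group yields NA with a degenerate flag.
#'
#' @param em log2 `expr_matrix` with probe-to-gene map.
#' @param samples sample sheet.
#' @param anchor anchor gene symbol.
#' @param panel character vector of panel gene symbols.
#' @param group logical vector over `samples`, predicate function, or NULL
#'   for all samples.
#' @param n_perm if > 0, adds a permutation p-value (two-sided) per pair.
#' @param seed RNG seed for permutations.
#' @return data.frame: gene_a, gene_b, n, pearson_r, p_value, degenerate.
#' @export
pearson_panel <- function(em, samples, anchor, panel, group = NULL,
                          n_perm = 0, seed = 1) {
  coll <- collapse_probes(em)
  genes <- rownames(coll$values)
  miss <- setdiff(c(anchor, panel), genes)
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  if (is.function(group)) group <- group(samples)
  if (is.null(group)) group <- rep(TRUE, nrow(samples))
  members <- samples$sample_id[group]
  cols <- colnames(coll$values) %in% members
  if (sum(cols) < 3) stop("group needs at least 3 samples")
  xa <- coll$values[anchor, cols]
  rows <- lapply(panel, function(g) {
    xb <- coll$values[g, cols]
    r <- pearson_r_p(xa, xb)
    out <- data.frame(gene_a = anchor, gene_b = g, n = r$n,
                      pearson_r = r$r, p_value = r$p_value,
                      degenerate = r$degenerate, stringsAsFactors = FALSE)
    if (n_perm > 0 && !r$degenerate) {
      out$perm_p <- with_seed(seed, {
        exceed <- sum(vapply(seq_len(n_perm), function(i) {
          abs(pearson_r_p(xa, sample(xb))$r) >= abs(r$r)
        }, logical(1)))
        (exceed + 1) / (n_perm + 1)
      })
    }
    out
  })
  do.call(rbind, rows)
}

#' Cross-tabulate genes against two category lists
#'
#' Marks each gene's membership in every category of two user-supplied
#' category maps (e.g. oncology processes vs. normal/pathological pituitary
#' functions) and flags the cross-list subset: genes with at least one mark
#' in EACH map. Unmapped genes simply get empty marks.
#'
#' @param gene_table data.frame with columns `symbol`, `fold_change`,
#'   `p_value` (extra columns pass through).
#' @param oncology_map,pituitary_map data.frames with columns `symbol`,
#'   `category`.
#' @return `gene_table` with one logical column per category (prefixed by
#'   map name) and `in_cross_subset`.
#' @export
category_crosstab <- function(gene_table, oncology_map, pituitary_map) {
  maps <- list(oncology = oncology_map, pituitary = pituitary_map)
  out <- gene_table
  any_mark <- list()
  for (mname in names(maps)) {
    m <- maps[[mname]]
    cats <- unique(m$category)
    hits <- matrix(FALSE, nrow(out), length(cats),
                   dimnames = list(NULL, paste0(mname, ": ", cats)))
    for (k in seq_along(cats)) {
      members <- m$symbol[m$category == cats[k]]
      hits[, k] <- out$symbol %in% members
    }
    out <- cbind(out, as.data.frame(hits, check.names = FALSE))
    any_mark[[mname]] <- rowSums(hits) > 0
  }
  out$in_cross_subset <- any_mark$oncology & any_mark$pituitary
  out
}
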