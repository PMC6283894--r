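#' Per-chromosome enrichment of deregulated genes (delta statistic)
#'
#' For chromosome lambda, Delta(lambda) in percentage points is
#' `100 * (n_deregulated(lambda) / N_deregulated - G(lambda) / G_total)`:
#' the chromosome's share of deregulated genes minus its share of all
#' annotated genes. Both denominators run over the complete annotation
#' (all chromosomes), regardless of which chromosomes are selected for
#' output, so over a complete selection the deltas sum to zero.
#'
#' @param deregulated character vector of deregulated gene symbols.
#' @param annotation `gene_annotation` covering every deregulated symbol.
#' @param chromosomes `"autosomes"` (default; sex chromosomes excluded from
#'   the output rows), `"all"`, or an explicit character vector.
#' @return data.frame of class `chrom_enrichment`: chromosome,
#'   n_deregulated, n_genes, delta_percent (full precision; round at
#'   serialization only).
#' @export
delta_statistic <- function(deregulated, annotation, chromosomes = "autosomes") {
  deregulated <- unique(deregulated)
  if (!length(deregulated)) stop("no deregulated genes")
  miss <- setdiff(deregulated, annotation$symbol)
  if (length(miss)) {
    stop("deregulated symbol(s) missing from annotation: ",
         paste(miss, collapse = ", "))
  }
  if (identical(chromosomes, "autosomes")) {
    sel <- AUTOSOMES
  } else if (identical(chromosomes, "all")) {
    sel <- unique(annotation$chromosome)
  } else {
    sel <- normalize_chrom(chromosomes)
  }
  sel <- sel[sel %in% annotation$chromosome]
  g_total <- nrow(annotation)
  n_total <- length(deregulated)
  chrom_of <- annotation$chromosome[match(deregulated, annotation$symbol)]
  rows <- lapply(sel, function(chr) {
    g_chr <- sum(annotation$chromosome == chr)
    n_chr <- sum(chrom_of == chr)
    data.frame(chromosome = chr, n_deregulated = n_chr, n_genes = g_chr,
               delta_percent = 100 * (n_chr / n_total - g_chr / g_total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("chrom_enrichment", "data.frame")
  out
}

#' Rank chromosomes by distance of delta from the median
#'
#' Computes the median of the supplied `delta_percent` values (even count:
#' mean of the two middle values), sorts rows by decreasing delta, and
#' attaches each row's absolute distance from the median.
#'
#' @param rows data.frame with a `delta_percent` column (e.g. from
#'   [delta_statistic()] or a published enrichment table).
#' @return the sorted data.frame with a `distance_from_median` column;
#'   attribute `median_delta` holds the median.
#' @export
rank_by_median_distance <- function(rows) {
  if (!nrow(rows)) stop("empty enrichment table")
  med <- stats::median(rows$delta_percent)
  out <- rows[order(-rows$delta_percent), , drop = FALSE]
  out$distance_from_median <- abs(out$delta_percent - med)
  rownames(out) <- NULL
  attr(out, "median_delta") <- med
  out
}

#' Permutation p-values for chromosome enrichment
#'
#' Optional extension beyond the descriptive delta statistic: resamples
#' deregulated-set labels uniformly over the annotation and reports, per
#' chromosome, the fraction of resamples with a delta at least as large as
#' observed (one-sided, enrichment).
#'
#' @param deregulated deregulated gene symbols.
#' @param annotation `gene_annotation`.
#' @param n_perm number of resamples (default 1000).
#' @param chromosomes selection passed to [delta_statistic()].
#' @param seed RNG seed.
#' @return the [delta_statistic()] table with a `perm_p` column.
#' @export
delta_permutation_p <- function(deregulated, annotation, n_perm = 1000,
                                chromosomes = "autosomes", seed = 1) {
  obs <- delta_statistic(deregulated, annotation, chromosomes)
  k <- length(unique(deregulated))
  with_seed(seed, {
    exceed <- numeric(nrow(obs))
    for (i in seq_len(n_perm)) {
      perm <- sample(annotation$symbol, k)
      d <- delta_statistic(perm, annotation, obs$chromosome)
      exceed <- exceed + (d$delta_percent >= obs$delta_percent)
    }
    obs$perm_p <- (exceed + 1) / (n_perm + 1)
  })
  obs
}
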