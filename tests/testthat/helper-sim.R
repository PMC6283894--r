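# Shared small-scale simulation settings: the full study conditions
# (20 vs 10 samples, planted 140-gene panel, 19p gain, chr11 loss) on a
# reduced probe/gene complement so unit tests stay fast.

small_gene_counts <- function(per_chrom = 30) {
  stats::setNames(rep(per_chrom, 24), c(as.character(1:22), "X", "Y"))
}

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_probes = 2000, n_controls = 60,
             gene_counts = small_gene_counts(),
             cna_probes_per_chrom = 40, ...)
}

# null cohort: no planted effects, no correlation structure
null_config <- function(seed = 1, n_genes = 2000, ...) {
  empty <- data.frame(symbol = character(), chromosome = character(),
                      arm = character(), log2fc = numeric(),
                      stringsAsFactors = FALSE)
  sim_config(seed = seed, n_probes = n_genes + 100, n_controls = 100,
             gene_counts = stats::setNames(rep(ceiling(n_genes / 22), 22),
                                           as.character(1:22)),
             planted_de = empty, planted_correlations = list(),
             esr1_ir_r = NA, ...)
}

noise_free_config <- function(seed = 1) {
  small_config(seed = seed, noise_sd_log2 = 0, cna_noise_sd = 0,
               planted_correlations = list(), esr1_ir_r = NA)
}

sim_small_dataset <- function(seed = 1, config = small_config(seed)) {
  cohort <- simulate_cohort(config)
  annotation <- simulate_annotation(config)
  em <- simulate_expression(config, cohort, annotation)
  list(config = config, cohort = cohort, annotation = annotation, em = em)
}

aggressive_male <- function(s) s$sex == "M" & s$grade %in% c("2b", "2b->3")
aggressive <- function(s) s$grade %in% c("2b", "2b->3")

# exhaustive penalized least-squares segmentation over <= 3 segments
brute_force_segment <- function(x, penalty, min_size = 3) {
  n <- length(x)
  m <- min(min_size, n)
  sse <- function(i, j) sum((x[i:j] - mean(x[i:j]))^2)
  best <- list(cost = sse(1, n) + penalty, bounds = c(1))
  if (n >= 2 * m) {
    for (b in m:(n - m)) {
      cost <- sse(1, b) + sse(b + 1, n) + 2 * penalty
      if (cost < best$cost - 1e-12) best <- list(cost = cost, bounds = c(1, b + 1))
    }
  }
  if (n >= 3 * m) {
    for (b1 in m:(n - 2 * m)) {
      for (b2 in (b1 + m):(n - m)) {
        cost <- sse(1, b1) + sse(b1 + 1, b2) + sse(b2 + 1, n) + 3 * penalty
        if (cost < best$cost - 1e-12) {
          best <- list(cost = cost, bounds = c(1, b1 + 1, b2 + 1))
        }
      }
    }
  }
  best
}

segment_cost <- function(x, seg, penalty) {
  tot <- nrow(seg) * penalty
  for (k in seq_len(nrow(seg))) {
    xx <- x[seg$start_idx[k]:seg$end_idx[k]]
    tot <- tot + sum((xx - mean(xx))^2)
  }
  tot
}
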