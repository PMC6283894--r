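mk_em <- function(mat, controls = character()) {
  rownames(mat) <- rownames(mat) %||% sprintf("P%d", seq_len(nrow(mat)))
  colnames(mat) <- colnames(mat) %||% sprintf("S%d", seq_len(ncol(mat)))
  expr_matrix(mat, negative_control_probes = controls, scale = "raw")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("median normalization divides by the column median and is idempotent", {
  em <- mk_em(matrix(c(1, 2, 3), ncol = 1))
  nm <- median_normalize(em)
  expect_equal(unname(nm$intensities[, 1]), c(0.5, 1, 1.5))
  expect_equal(nm$scale, "normalized")
  again <- median_normalize(nm)
  expect_equal(again$intensities, nm$intensities)

  # order-independence across samples: each column is scaled on its own
  m <- matrix(runif(30, 1, 10), 10, 3)
  em3 <- mk_em(m)
  nm3 <- median_normalize(em3)
  swapped <- median_normalize(mk_em(m[, c(3, 1, 2)]))
  expect_equal(unname(swapped$intensities[, 2]), unname(nm3$intensities[, 1]))

  withr::with_seed(1, {
    big <- mk_em(matrix(rexp(1001 * 5, 0.1), 1001, 5))
  })
  med <- apply(median_normalize(big)$intensities, 2, stats::median)
  expect_true(all(abs(med - 1) < 1e-12))

  zero <- mk_em(matrix(0, 3, 2))
  expect_error(median_normalize(zero), "median")
})

test_that("detection threshold is mean + k_sd * SD of the sample's controls", {
  m <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5 + 1e-9, 0.3), 6, 1)
  rownames(m) <- c("NEG_1", "NEG_2", "NEG_3", "P1", "P2", "P3")
  colnames(m) <- "S1"
  em <- expr_matrix(m, negative_control_probes = paste0("NEG_", 1:3),
                    scale = "normalized")
  det <- detection_call(em, k_sd = 5)
  expect_equal(unname(det$threshold_per_sample), 0.5)  # zero-variance controls
  expect_false(det$present["P1", 1])   # exactly at threshold -> absent
  expect_true(det$present["P2", 1])    # epsilon above -> present

  m2 <- matrix(c(0.1, 0.2, 0.3, 1), 4, 1,
               dimnames = list(c("NEG_1", "NEG_2", "NEG_3", "P1"), "S1"))
  em2 <- expr_matrix(m2, negative_control_probes = paste0("NEG_", 1:3),
                     scale = "normalized")
  det2 <- detection_call(em2, k_sd = 2)
  expect_equal(unname(det2$threshold_per_sample), 0.2 + 2 * sd(c(0.1, 0.2, 0.3)))
  expect_equal(unname(det2$threshold_per_sample), 0.4)

  no_ctrl <- expr_matrix(m2[4, , drop = FALSE], scale = "normalized")
  expect_error(detection_call(no_ctrl), "threshold")
})

test_that("detection is monotone in k_sd and separates signal from controls", {
  # a null cohort isolates the 3-SD control/gene separation the generator
  # constructs (planted down-shifts would mix a true effect into the rate)
  cfg <- null_config(seed = 2, n_genes = 2000)
  co <- simulate_cohort(cfg)
  em <- simulate_expression(cfg, co, simulate_annotation(cfg))
  nm <- median_normalize(em)
  d1 <- detection_call(nm, k_sd = 1)
  d2 <- detection_call(nm, k_sd = 2)
  d4 <- detection_call(nm, k_sd = 4)
  # raising k_sd never converts absent -> present
  expect_true(all(d2$present[!d1$present] == FALSE))
  expect_true(all(d4$present[!d2$present] == FALSE))
  ctrl <- nm$negative_control_probes
  gene <- names(nm$probe_to_gene)
  expect_gte(mean(d2$present[gene, ]), 0.99)
  expect_gte(mean(!d2$present[ctrl, ]), 0.95)
})

test_that("log2 transform floors zeros and preserves order", {
  m <- matrix(c(1, 4, 0, 8), 4, 1,
              dimnames = list(paste0("P", 1:4), "S1"))
  em <- expr_matrix(m, scale = "normalized")
  lg <- log2_transform(em, floor = 2^-10)
  expect_equal(unname(lg$intensities[, 1]), c(0, 2, -10, 3))
  expect_equal(lg$scale, "log2")
  # strict monotonicity above the floor
  x <- sort(runif(50, 2^-9, 100))
  emx <- expr_matrix(matrix(x, dimnames = list(paste0("P", 1:50), "S1")),
                     scale = "normalized")
  expect_true(all(diff(log2_transform(emx)$intensities[, 1]) > 0))
  expect_error(log2_transform(em, floor = 0), "positive")
  expect_error(log2_transform(mk_em(m)), "normalized")
})
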