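test_that("signed fold change follows the sign-folded ratio convention", {
  expect_equal(signed_fold_change(3, 1), 4)
  expect_equal(signed_fold_change(1, 3), -4)
  expect_equal(signed_fold_change(2, 2), 1)
  # never returns a value in (-1, 1)
  withr::with_seed(4, {
    a <- rnorm(200); b <- rnorm(200)
  })
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})

test_that("fold-change label swap is exactly antisymmetric away from 1", {
  withr::with_seed(4, {
    a <- rnorm(200); b <- rnorm(200)
  })
  fc <- signed_fold_change(a, b)
  rev <- signed_fold_change(b, a)
  off1 <- abs(fc) > 1
  expect_equal(rev[off1], -fc[off1])
  expect_true(all(rev[!off1] == 1 & fc[!off1] == 1))
})

test_that("pooled t-test matches the classical oracle and handles degeneracy", {
  expect_equal(student_t(c(1, 2, 3), c(2, 3, 4))$p_value, 0.2878641,
               tolerance = 1e-6)
  # cross-check against stats::t.test on random draws
  withr::with_seed(9, {
    for (i in 1:20) {
      a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = runif(1))
      expect_equal(student_t(a, b)$p_value,
                   t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
      expect_equal(student_t(a, b, welch = TRUE)$p_value,
                   t.test(a, b)$p.value, tolerance = 1e-12)
    }
  })
  ident <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)

  flat <- student_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(flat$p_value, 1)
  expect_true(flat$degenerate)

  sep <- student_t(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(sep$p_value, 0)
  withr::with_seed(2, {
    jit <- student_t(rnorm(4, 0, 1e-6), rnorm(4, 1, 1e-6))
  })
  expect_lt(jit$p_value, 1e-4)

  expect_error(student_t(1, c(1, 2)), "at least 2")
})

test_that("deregulation filter recovers planted genes and respects thresholds", {
  ds <- sim_small_dataset(seed = 1)
  nm <- median_normalize(ds$em)
  det <- detection_call(nm)
  lg <- log2_transform(nm)
  de <- select_deregulated(lg, ds$cohort, detection = det)
  cnt <- attr(de, "counts")
  expect_true(abs(cnt[["up"]] - 120) <= 5)
  expect_true(abs(cnt[["down"]] - 20) <= 5)
  expect_equal(cnt[["deregulated"]], cnt[["up"]] + cnt[["down"]])

  # antitone in fc_min and alpha: stricter thresholds give subsets
  de4 <- select_deregulated(lg, ds$cohort, detection = det, fc_min = 4)
  expect_true(all(de4$symbol[de4$deregulated] %in% de$symbol[de$deregulated]))
  de01 <- select_deregulated(lg, ds$cohort, detection = det, alpha = 0.01)
  expect_true(all(de01$symbol[de01$deregulated] %in% de$symbol[de$deregulated]))

  # swapping group labels negates fold changes, preserves p-values
  sw <- select_deregulated(lg, ds$cohort, detection = det,
                           group_a = "F", group_b = "M")
  m <- match(de$symbol, sw$symbol)
  off1 <- abs(de$fold_change) > 1
  expect_equal(sw$fold_change[m][off1], -de$fold_change[off1])
  expect_equal(sw$p_value[m], de$p_value)

  single_sex <- ds$cohort[ds$cohort$sex == "M", ]
  expect_error(select_deregulated(lg, single_sex), "missing|contrast")
})

test_that("noise-free planted data yields exact fold changes", {
  cfg <- noise_free_config()
  co <- simulate_cohort(cfg)
  em <- simulate_expression(cfg, co, simulate_annotation(cfg))
  # on the generator's own log2 scale (at this toy scale one fifth of the
  # transcriptome is planted, so per-sample median scaling would itself
  # shift the group means; at the full 55k complement it does not)
  lg <- expr_matrix(log2(em$intensities), probe_to_gene = em$probe_to_gene,
                    negative_control_probes = em$negative_control_probes,
                    scale = "log2")
  de <- select_deregulated(lg, co)
  planted <- cfg$planted_de[abs(cfg$planted_de$log2fc) > 0, ]
  m <- match(planted$symbol, de$symbol)
  expect_equal(de$fold_change[m],
               ifelse(planted$log2fc > 0, 2^planted$log2fc,
                      -2^(-planted$log2fc)),
               tolerance = 1e-9)
})

test_that("all-null cohorts pass the joint filter at most rarely", {
  cfg <- null_config(seed = 13, n_genes = 10000)
  co <- simulate_cohort(cfg)
  em <- simulate_expression(cfg, co, simulate_annotation(cfg))
  lg <- log2_transform(median_normalize(em))
  de <- select_deregulated(lg, co)
  expect_lte(mean(de$deregulated), 0.06)
})

test_that("subgroup contrasts agree with the full filter and move with exclusions", {
  ds <- sim_small_dataset(seed = 6)
  lg <- log2_transform(median_normalize(ds$em))
  de <- select_deregulated(lg, ds$cohort)
  sc <- subgroup_contrast(lg, ds$cohort, "MATK", include = NULL)
  row <- de[de$symbol == "MATK", ]
  expect_equal(sc$fold_change, row$fold_change)
  expect_equal(sc$p_value, row$p_value)

  # plant a male-subgroup-restricted effect: excluding the affected male
  # subgroup moves |FC| toward 1
  lg2 <- lg
  coll_gene <- "SIMUP002"
  affected <- ds$cohort$sample_id[aggressive_male(ds$cohort)]
  probes <- names(lg2$probe_to_gene)[lg2$probe_to_gene == coll_gene]
  lg2$intensities[probes, affected] <- lg2$intensities[probes, affected] + 4
  fc_all <- subgroup_contrast(lg2, ds$cohort, coll_gene)$fold_change
  fc_excl <- subgroup_contrast(lg2, ds$cohort, coll_gene,
                               include = function(s) !aggressive_male(s))$fold_change
  expect_lt(abs(fc_excl), abs(fc_all))

  expect_error(subgroup_contrast(lg, ds$cohort, "NOPE"), "unknown gene")
  one_f <- function(s) s$sex == "M" | seq_len(nrow(s)) == which(s$sex == "F")[1]
  expect_error(subgroup_contrast(lg, ds$cohort, "MATK", include = one_f),
               "fewer than 2")
})
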