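test_that("cohort generator reproduces the study margins deterministically", {
  co <- simulate_cohort(small_config(seed = 3))
  expect_equal(nrow(co), 30)
  expect_equal(sum(co$sex == "M"), 20)
  expect_equal(sum(co$sex == "F"), 10)
  tab <- table(co$sex, co$grade)
  expect_equal(unname(tab["F", c("1a", "1b", "2a", "2b")]), c(6L, 1L, 1L, 2L))
  expect_equal(unname(tab["M", c("1a", "1b", "2a", "2b", "2b->3")]),
               c(4L, 1L, 8L, 5L, 2L))
  # metastasis tag present exactly on the progressed male tumors
  expect_equal(sum(grepl("metastasis", co$clinical_behavior)), 2)
  expect_true(all(co$grade[grepl("metastasis", co$clinical_behavior)] == "2b->3"))
  # ER-alpha IR scores lower in men on average
  expect_lt(mean(co$era_ir_score[co$sex == "M"]),
            mean(co$era_ir_score[co$sex == "F"]))

  expect_identical(co, simulate_cohort(small_config(seed = 3)))
  expect_error(simulate_cohort(small_config(n_male = 0)), "at least one")
})

test_that("expression generator plants exact group differences and is seeded", {
  cfg <- noise_free_config()
  co <- simulate_cohort(cfg)
  ann <- simulate_annotation(cfg)
  em <- simulate_expression(cfg, co, ann)
  # exactness is a property of the generator's output: check on the raw
  # log2 values (per-sample median scaling is examined elsewhere)
  lg <- expr_matrix(log2(em$intensities), probe_to_gene = em$probe_to_gene,
                    negative_control_probes = em$negative_control_probes,
                    scale = "log2")
  coll <- collapse_probes(lg)
  m <- co$sample_id[co$sex == "M"]; f <- co$sample_id[co$sex == "F"]
  for (g in c("CRB3", "MATK", "SIMUP001")) {
    ratio <- 2^(mean(coll$values[g, m]) - mean(coll$values[g, f]))
    expect_equal(ratio, 4, tolerance = 1e-9)  # planted log2FC = 2
  }
  expect_equal(2^(mean(coll$values["SIMDN001", m]) -
                    mean(coll$values["SIMDN001", f])), 0.25, tolerance = 1e-9)
  # an unplanted gene has zero true difference
  unplanted <- setdiff(rownames(coll$values), cfg$planted_de$symbol)[1]
  expect_equal(mean(coll$values[unplanted, m]),
               mean(coll$values[unplanted, f]), tolerance = 1e-9)

  cfg2 <- small_config(seed = 11)
  co2 <- simulate_cohort(cfg2)
  em_a <- simulate_expression(cfg2, co2, simulate_annotation(cfg2))
  em_b <- simulate_expression(cfg2, co2, simulate_annotation(cfg2))
  expect_identical(em_a$intensities, em_b$intensities)

  # controls sit stochastically below gene probes
  ctrl <- em_a$intensities[em_a$negative_control_probes, ]
  genes <- em_a$intensities[names(em_a$probe_to_gene), ]
  expect_lt(mean(log2(ctrl)), mean(log2(genes)) - 2)

  bad <- cfg2
  bad$planted_de$symbol[1] <- "NOT_IN_ANNOTATION"
  ann2 <- simulate_annotation(cfg2)
  expect_error(simulate_expression(bad, co2, ann2), "absent from annotation")
})

test_that("default full-scale conditions give 55,000 probes with 100 controls", {
  cfg <- sim_config(seed = 2)
  co <- simulate_cohort(cfg)
  em <- simulate_expression(cfg, co, simulate_annotation(cfg))
  expect_equal(nrow(em$intensities), 55000)
  expect_equal(length(em$negative_control_probes), 100)
  expect_equal(ncol(em$intensities), 30)
})

test_that("copy-number generator respects sex baselines and planted segments", {
  cfg <- noise_free_config()
  co <- simulate_cohort(cfg)
  cp <- simulate_cna_profiles(cfg, co)
  arm <- lactodim:::position_arm(cp$probes$chromosome, cp$probes$position)
  p19 <- cp$probes$chromosome == "19" & arm == "p"
  males <- co$sample_id[co$sex == "M"]
  females <- co$sample_id[co$sex == "F"]
  agg_m <- co$sample_id[aggressive_male(co)]
  # 19p gain confined to aggressive males; female profiles flat at 2
  expect_true(all(cp$copies[p19, agg_m] == 3.2))
  expect_true(all(cp$copies[p19, females] == 2))
  # sex baselines on X and Y
  xp <- cp$probes$chromosome == "X"
  yp <- cp$probes$chromosome == "Y"
  expect_true(all(cp$copies[xp, males] == 1))
  expect_true(all(cp$copies[xp, females] == 2))
  expect_true(all(is.na(cp$copies[yp, females])))
  expect_true(all(cp$copies[yp, males] == 1))

  expect_identical(simulate_cna_profiles(cfg, co)$copies, cp$copies)

  bad <- cfg
  bad$planted_segments <- list(list(group = "all", chromosome = "Y",
                                    arm = NULL, copies = 2))
  expect_error(simulate_cna_profiles(bad, co), "female")
})

test_that("null t-test rejection rate is calibrated near alpha", {
  cfg <- null_config(seed = 5, n_genes = 10000)
  co <- simulate_cohort(cfg)
  em <- simulate_expression(cfg, co, simulate_annotation(cfg))
  lg <- log2_transform(median_normalize(em))
  de <- select_deregulated(lg, co, alpha = 0.05, fc_min = 1)
  rate <- mean(de$p_value <= 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})
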